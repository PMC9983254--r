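#' Construct an ordered set of 3D marker positions in one coordinate frame
#'
#' A `point_set` is the basic container of the package: an ordered sequence of
#' 3D positions (mm) recorded in a single named coordinate frame, typically
#' either the optical tracker frame (`"ARAMIS"`) or the robot world frame
#' (`"ROBOT"`). Optional per-sample orientation angles (degrees) are carried
#' through I/O as metadata but never enter any transformation computation.
#'
#' @param points numeric matrix with `n >= 1` rows and 3 columns (x, y, z in
#'   mm), or a length-3 vector for a single sample.
#' @param frame frame label, e.g. `"ARAMIS"` or `"ROBOT"`.
#' @param pose_index integer vector of 1-based pose indices, unique within the
#'   recording. Defaults to `1:n`.
#' @param orientation optional `n x 3` matrix of rotation angles
#'   (alpha, beta, gamma, degrees); metadata only.
#' @param zeroed logical; `TRUE` only for sets produced by [zero_shift()].
#' @param anchor the 3-vector subtracted when the set was zeroed (recorded iff
#'   `zeroed`).
#' @return an object of class `point_set`.
#' @seealso [zero_shift()], [estimate_transform()], [apply_transform()]
#' @export
point_set <- function(points, frame, pose_index = NULL, orientation = NULL,
                      zeroed = FALSE, anchor = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have 3 columns (x, y, z)")
  n <- nrow(points)
  if (n < 1L) stop("no samples")
  if (!all(is.finite(points))) stop("position components must be finite")
  if (is.null(pose_index)) pose_index <- seq_len(n)
  pose_index <- as.integer(pose_index)
  if (length(pose_index) != n) stop("pose_index length must match point count")
  if (anyDuplicated(pose_index)) stop("pose_index must be unique within a recording")
  if (any(pose_index < 1L)) stop("pose_index must be >= 1")
  if (!is.null(orientation)) {
    orientation <- as.matrix(orientation)
    if (nrow(orientation) != n || ncol(orientation) != 3L)
      stop("orientation must be an n x 3 matrix")
  }
  if (zeroed) {
    if (is.null(anchor) || length(anchor) != 3L)
      stop("a zeroed point_set must record its 3-vector anchor")
    if (any(abs(points[1L, ]) > 0))
      stop("first point of a zeroed set must be exactly (0,0,0)")
  } else if (!is.null(anchor)) {
    stop("anchor is recorded iff the set is zeroed")
  }
  structure(
    list(points = points, frame = as.character(frame)[1L],
         pose_index = pose_index, orientation = orientation,
         zeroed = isTRUE(zeroed),
         anchor = if (zeroed) as.numeric(anchor) else NULL),
    class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d samples in frame '%s'%s\n", nrow(x$points),
              x$frame, if (x$zeroed) " (zeroed)" else ""))
  invisible(x)
}

#' @export
length.point_set <- function(x) nrow(x$points)

as_point_matrix <- function(x) {
  if (inherits(x, "point_set")) x$points
  else if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L)
  else as.matrix(x)
}

#' Shift a point set so its first sample becomes the zero point
#'
#' Subtracts the first recorded sample from every sample, the translation step
#' of the two-step frame-transformation estimate. The subtracted anchor is kept
#' so the affine transform can be reassembled later.
#'
#' @param points a non-zeroed [point_set()] with `n >= 1` samples.
#' @return a zeroed `point_set` whose first point is (0,0,0), with `anchor` set
#'   to the original first sample.
#' @export
zero_shift <- function(points) {
  stopifnot(inherits(points, "point_set"))
  if (points$zeroed) stop("point set is already zeroed")
  n <- nrow(points$points)
  if (n < 1L) stop("no samples")
  anchor <- points$points[1L, ]
  shifted <- sweep(points$points, 2L, anchor)
  shifted[1L, ] <- 0  # exact zero, no roundoff residue
  point_set(shifted, frame = points$frame, pose_index = points$pose_index,
            orientation = points$orientation, zeroed = TRUE, anchor = anchor)
}

cond_3x3 <- function(m) {
  d <- svd(m, nu = 0L, nv = 0L)$d
  if (min(d) == 0) Inf else max(d) / min(d)
}

#' Estimate the linear map between two zeroed coordinate recordings
#'
#' Solves `T = R %*% t(A) %*% solve(A %*% t(A))` where `A` (source) and `R`
#' (target) are the 3 x n matrices of zeroed coordinates -- the unconstrained
#' least-squares estimate of the 3 x 3 map taking zeroed source coordinates to
#' zeroed target coordinates. No orthogonality is imposed by default; for
#' noise-free data of a true rigid motion the estimate is orthogonal anyway.
#'
#' @param target zeroed [point_set()] in the target frame (e.g. robot world).
#' @param source zeroed [point_set()] in the source frame (e.g. optical), same
#'   number of points in matching order.
#' @param min_n minimum number of poses accepted (default 4; 3 suffices
#'   generically but gives no conditioning margin).
#' @param cond_limit condition-number bound on `A %*% t(A)` above which the
#'   geometry is rejected as degenerate (default 1e12).
#' @param orthogonalize if `TRUE`, project the estimate onto the nearest
#'   rotation (polar decomposition via SVD) after solving. Off by default: the
#'   published estimator is the plain least-squares map.
#' @return a `frame_transform` with fields `linear_map` (3 x 3),
#'   `source_anchor`/`target_anchor` (the first samples removed by zeroing),
#'   `source_frame`, `target_frame`, `direction` and `residual_rms` (mm).
#' @export
estimate_transform <- function(target, source, min_n = 4L, cond_limit = 1e12,
                               orthogonalize = FALSE) {
  stopifnot(inherits(target, "point_set"), inherits(source, "point_set"))
  if (!source$zeroed || !target$zeroed) stop("both point sets must be zeroed")
  n <- nrow(source$points)
  if (nrow(target$points) != n) stop("source and target must have equal n")
  if (n < min_n) stop(sprintf("need at least %d poses, got %d", min_n, n))
  A <- t(source$points)   # 3 x n
  R <- t(target$points)
  AAt <- A %*% t(A)
  if (cond_3x3(AAt) > cond_limit)
    stop("degenerate calibration geometry: A.A^T is (near-)singular")
  map <- R %*% t(A) %*% solve(AAt)
  if (orthogonalize) {
    s <- svd(map)
    map <- s$u %*% t(s$v)
    if (det(map) < 0) {  # keep a proper rotation
      s$v[, 3L] <- -s$v[, 3L]
      map <- s$u %*% t(s$v)
    }
  }
  res <- R - map %*% A
  frame_transform(map,
                  source_anchor = source$anchor, target_anchor = target$anchor,
                  source_frame = source$frame, target_frame = target$frame,
                  residual_rms = sqrt(mean(colSums(res^2))))
}

#' Assemble a frame transform from its parts
#'
#' @param linear_map finite 3 x 3 matrix.
#' @param source_anchor,target_anchor 3-vectors: the first calibration sample
#'   in each frame, i.e. the points identified by the translation step.
#' @param source_frame,target_frame frame labels.
#' @param residual_rms root-mean-square calibration residual (mm).
#' @return a `frame_transform` object. Points `p` in the source frame map to
#'   `target_anchor + linear_map %*% (p - source_anchor)`.
#' @export
frame_transform <- function(linear_map, source_anchor, target_anchor,
                            source_frame, target_frame, residual_rms = NA_real_) {
  linear_map <- as.matrix(linear_map)
  if (!all(dim(linear_map) == c(3L, 3L)) || !all(is.finite(linear_map)))
    stop("linear_map must be a finite 3 x 3 matrix")
  structure(
    list(linear_map = linear_map,
         source_anchor = as.numeric(source_anchor),
         target_anchor = as.numeric(target_anchor),
         source_frame = as.character(source_frame)[1L],
         target_frame = as.character(target_frame)[1L],
         direction = paste0(source_frame, "->", target_frame),
         residual_rms = as.numeric(residual_rms)),
    class = "frame_transform")
}

#' @export
print.frame_transform <- function(x, ...) {
  cat(sprintf("<frame_transform> %s (residual RMS %.4g mm)\n",
              x$direction, x$residual_rms))
  print(x$linear_map)
  invisible(x)
}

#' Invert a frame transform
#'
#' @param transform a `frame_transform` with an invertible linear map.
#' @return the transform in the opposite direction: inverse map, anchors and
#'   frames swapped. Composing a transform with its inverse is the identity to
#'   well below 1e-9.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "frame_transform"))
  if (cond_3x3(transform$linear_map) > 1e12) stop("linear map is (near-)singular")
  frame_transform(solve(transform$linear_map),
                  source_anchor = transform$target_anchor,
                  target_anchor = transform$source_anchor,
                  source_frame = transform$target_frame,
                  target_frame = transform$source_frame,
                  residual_rms = transform$residual_rms)
}

#' Map a point set into the transform's target frame
#'
#' Each point becomes `target_anchor + linear_map %*% (p - source_anchor)`.
#'
#' @param transform a `frame_transform`.
#' @param points a [point_set()] whose frame matches the transform's source
#'   frame, or a bare `n x 3` matrix (frame check skipped).
#' @return the transformed points; a `point_set` in the target frame when the
#'   input was one, otherwise a matrix.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "frame_transform"))
  is_ps <- inherits(points, "point_set")
  if (is_ps && !identical(points$frame, transform$source_frame))
    stop(sprintf("frame mismatch: points are in '%s', transform expects '%s'",
                 points$frame, transform$source_frame))
  p <- as_point_matrix(points)
  out <- sweep(p, 2L, transform$source_anchor) %*% t(transform$linear_map)
  out <- sweep(out, 2L, transform$target_anchor, "+")
  if (!is_ps) return(out)
  point_set(out, frame = transform$target_frame, pose_index = points$pose_index,
            orientation = points$orientation)
}
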