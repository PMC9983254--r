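#' Bundle the three calibration inputs
#'
#' The calibration pipeline consumes (1) the commanded robot calibration poses
#' (robot world frame), (2) the same poses as measured by the optical tracker
#' (optical frame), and (3) a manually recorded joint trajectory (optical
#' frame). Robot and optical pose lists must pair up one-to-one by pose index.
#'
#' @param robot_poses [point_set()] in the robot world frame.
#' @param optical_poses [point_set()] in the optical frame, same `n` and
#'   matching `pose_index` as `robot_poses`.
#' @param manual_trajectory [point_set()] in the optical frame with at least 4
#'   samples of the joint motion (may be `NULL` if only origin reconstruction
#'   is wanted).
#' @return an object of class `calibration_inputs`.
#' @export
calibration_inputs <- function(robot_poses, optical_poses,
                               manual_trajectory = NULL) {
  stopifnot(inherits(robot_poses, "point_set"),
            inherits(optical_poses, "point_set"))
  if (nrow(robot_poses$points) != nrow(optical_poses$points))
    stop(sprintf("pose count mismatch: %d robot poses vs %d optical poses",
                 nrow(robot_poses$points), nrow(optical_poses$points)))
  if (!identical(robot_poses$pose_index, optical_poses$pose_index))
    stop("robot and optical pose indices do not match")
  if (!is.null(manual_trajectory)) {
    stopifnot(inherits(manual_trajectory, "point_set"))
    if (nrow(manual_trajectory$points) < 4L)
      stop("manual trajectory needs at least 4 samples")
    if (!identical(manual_trajectory$frame, optical_poses$frame))
      stop("manual trajectory must be recorded in the optical frame")
  }
  structure(list(robot_poses = robot_poses, optical_poses = optical_poses,
                 manual_trajectory = manual_trajectory),
            class = "calibration_inputs")
}

#' Total least-squares plane through 3D points
#'
#' Fits the plane minimising the sum of squared orthogonal distances (smallest
#' principal direction of the centred points). Used to reconstruct the robot's
#' YZ and XZ calibration planes from the mapped pose measurements.
#'
#' @param points [point_set()] or matrix, `n >= 3`, not collinear.
#' @param label optional tag, e.g. `"YZ"` or `"XZ"`.
#' @return a `plane_fit`: `unit_normal` (largest component made positive),
#'   `offset` (so the plane is `{p : n . p = offset}`), `rms_residual` (mm) and
#'   `label`.
#' @export
fit_plane <- function(points, label = NULL) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 3L) stop("need at least 3 points for a plane")
  ctr <- colMeans(pts)
  centred <- sweep(pts, 2L, ctr)
  s <- svd(centred, nu = 0L)
  if (s$d[2L] <= 1e-9 * max(s$d[1L], 1))
    stop("degenerate plane geometry: points are (near-)collinear")
  normal <- s$v[, 3L]
  k <- which.max(abs(normal))
  if (normal[k] < 0) normal <- -normal  # deterministic sign convention
  structure(
    list(unit_normal = normal,
         offset = sum(normal * ctr),
         rms_residual = sqrt(mean((centred %*% normal)^2)),
         label = label),
    class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit>%s normal (%.4f, %.4f, %.4f), offset %.4f, RMS %.4g mm\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$unit_normal[1], x$unit_normal[2], x$unit_normal[3],
              x$offset, x$rms_residual))
  invisible(x)
}

# line of intersection of two planes: list(point, direction (unit))
plane_intersection <- function(p1, p2, parallel_limit = 0.999) {
  n1 <- p1$unit_normal; n2 <- p2$unit_normal
  if (abs(sum(n1 * n2)) > parallel_limit)
    stop("calibration planes are (near-)parallel")
  d <- cross3(n1, n2)
  d <- d / vnorm(d)
  # min-norm point on both planes: zero component along the line direction
  pt <- solve(rbind(n1, n2, d), c(p1$offset, p2$offset, 0))
  list(point = as.numeric(pt), direction = d)
}

closest_point_on_line <- function(line, q) {
  line$point + sum((q - line$point) * line$direction) * line$direction
}

#' Reconstruct the robot world origin and report its deviation
#'
#' The robot's vertical axis is reconstructed as the intersection line of the
#' two calibration planes fitted to the optically measured poses after mapping
#' them into robot world coordinates. The commanded poses define the reference:
#' the intersection line of the commanded planes, pinned at `z = 0`, is where
#' the reconstruction would land with perfect data. The returned 3-vector is
#' the difference (closest point on the reconstructed axis minus the reference
#' point) expressed in robot world coordinates, so its ideal value is
#' `(0, 0, 0)` and each component is the per-axis origin deviation.
#'
#' @param yz,xz `plane_fit`s of the two calibration planes in robot world
#'   coordinates, or `NULL` to fit them from `measured` mapped through
#'   `transform` using `split`.
#' @param commanded [point_set()] of commanded robot poses (robot frame).
#' @param measured [point_set()] of the same poses measured optically.
#' @param transform `frame_transform` from the optical to the robot frame.
#' @param split list with integer index vectors `yz` and `xz` assigning poses
#'   to the two planes; defaults to the stage-II schedule (first 5 poses on
#'   YZ, the remainder on XZ).
#' @return 3-vector of per-axis origin deviations (mm).
#' @export
reconstruct_origin <- function(yz = NULL, xz = NULL, commanded, measured,
                               transform, split = NULL) {
  stopifnot(inherits(commanded, "point_set"), inherits(measured, "point_set"),
            inherits(transform, "frame_transform"))
  n <- nrow(commanded$points)
  if (is.null(split)) {
    if (n < 8L) stop("default plane schedule needs at least 8 poses")
    split <- list(yz = 1:5, xz = 6:n)
  }
  if (is.null(yz) || is.null(xz)) {
    mapped <- apply_transform(transform, measured)$points
    if (is.null(yz)) yz <- fit_plane(mapped[split$yz, , drop = FALSE], "YZ")
    if (is.null(xz)) xz <- fit_plane(mapped[split$xz, , drop = FALSE], "XZ")
  }
  cmd_yz <- fit_plane(commanded$points[split$yz, , drop = FALSE], "YZ")
  cmd_xz <- fit_plane(commanded$points[split$xz, , drop = FALSE], "XZ")
  ref_line <- plane_intersection(cmd_yz, cmd_xz)
  # pin the commanded reference at z = 0 (the robot world origin height);
  # fall back to the min-norm point when the axis is horizontal
  ref <- if (abs(ref_line$direction[3L]) > 1e-8) {
    ref_line$point - (ref_line$point[3L] / ref_line$direction[3L]) * ref_line$direction
  } else ref_line$point
  rec_line <- plane_intersection(yz, xz)
  as.numeric(closest_point_on_line(rec_line, ref) - ref)
}

#' Tool centre point from a robust sphere fit
#'
#' Maps the fitted joint rotation centre (sphere centre, optical frame) into
#' robot world coordinates, where it becomes the robot's tool centre point.
#' Refused when the trajectory failed the sphericity check, because a fixed
#' TCP/tool-length reproduction is only meaningful for ball joints; pass
#' `override = TRUE` to proceed anyway, or use the trajectory method.
#'
#' @param report `robust_fit_report` fitted on the optical-frame trajectory.
#' @param transform `frame_transform` from the optical to the robot frame.
#' @param override bypass the sphericity gate.
#' @return TCP as a 3-vector in robot world coordinates (mm).
#' @export
compute_tcp <- function(report, transform, override = FALSE) {
  stopifnot(inherits(report, "robust_fit_report"),
            inherits(transform, "frame_transform"))
  if (!report$spherical && !override)
    stop("trajectory not sphere-like; use the trajectory method (or override)")
  as.numeric(apply_transform(transform, matrix(report$final$center, ncol = 3L)))
}

#' Length of tool from TCP and flange centre
#'
#' The tool length is the distance between the tool centre point (the joint
#' rotation centre) and the centre of the robot flange, minus any mounted
#' force-torque sensor length that the robot controller accounts for
#' separately.
#'
#' @param tcp 3-vector, robot world frame (mm).
#' @param flange_center 3-vector, robot world frame (mm).
#' @param sensor_offset length (mm) of hardware between flange and tool chain
#'   to subtract (default 0).
#' @return tool length in mm.
#' @export
compute_lot <- function(tcp, flange_center, sensor_offset = 0) {
  lot <- vnorm(as.numeric(tcp) - as.numeric(flange_center)) - sensor_offset
  if (lot < 0) stop("sensor offset exceeds TCP-to-flange distance")
  lot
}

#' Transform a manually recorded trajectory into robot world coordinates
#'
#' The trajectory method of motion reproduction: every optical sample is mapped
#' through the estimated frame transform, preserving order and count. No
#' sphericity requirement applies -- this route works for any joint shape.
#'
#' @param manual [point_set()] in the optical frame.
#' @param transform `frame_transform` from the optical to the robot frame.
#' @return a `point_set` in the robot world frame.
#' @export
transform_trajectory <- function(manual, transform) {
  stopifnot(inherits(manual, "point_set"))
  apply_transform(transform, manual)
}

#' Reproduce a trajectory as fixed-tool-length motion about the TCP
#'
#' Projects each trajectory point radially onto the sphere of radius `lot`
#' centred at `tcp` -- how a robot with a fixed tool length reproduces the
#' angular path of the recorded motion. For a perfect ball joint this leaves
#' the trajectory unchanged.
#'
#' @param tcp 3-vector, robot world frame (mm).
#' @param lot tool length (mm).
#' @param trajectory [point_set()] or matrix in the robot world frame.
#' @return same container type as `trajectory`, radially projected.
#' @export
reproduce_sphere_motion <- function(tcp, lot, trajectory) {
  pts <- as_point_matrix(trajectory)
  rel <- sweep(pts, 2L, as.numeric(tcp))
  r <- sqrt(rowSums(rel^2))
  if (any(r == 0)) stop("trajectory passes through the TCP")
  out <- sweep(rel * (lot / r), 2L, as.numeric(tcp), "+")
  if (!inherits(trajectory, "point_set")) return(out)
  point_set(out, frame = trajectory$frame, pose_index = trajectory$pose_index,
            orientation = trajectory$orientation)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full three-stage calibration pipeline
#'
#' Composes the pipeline: zero-shift both calibration pose sets and estimate
#' the optical-to-robot transform; reconstruct the robot world origin from the
#' two calibration planes; then, depending on `method`, fit the joint sphere
#' robustly and derive TCP and tool length (`"tcp_lot"`, ball joints only), or
#' simply transform the manual trajectory (`"trajectory"`, any joint). The
#' transformed trajectory is produced in both modes.
#'
#' @param inputs a [calibration_inputs()].
#' @param method `"tcp_lot"` or `"trajectory"`.
#' @param k_sd,iterations,sphericity_tol,max_combinations robust-fit settings,
#'   see [fit_sphere_robust()].
#' @param sensor_offset force-torque sensor length (mm) subtracted from the
#'   tool length, see [compute_lot()].
#' @param flange_center optional flange centre (robot frame). When `NULL` (the
#'   default) the tracked marker is taken to sit at the flange attachment
#'   point, so the tool length is the fitted sphere radius minus
#'   `sensor_offset`.
#' @param override_sphericity bypass the ball-joint gate of the TCP method.
#' @param min_n,cond_limit transform-estimation guards, see
#'   [estimate_transform()].
#' @param plane_split pose-to-plane assignment for origin reconstruction, see
#'   [reconstruct_origin()].
#' @param seed seed for the (only potentially stochastic) combination
#'   subsampling; the pipeline is bit-reproducible for fixed inputs and seed.
#' @return a `calibration_result`: `transform`, `tcp`, `lot`,
#'   `origin_deviation`, `trajectory_robot`, `sphere_report`, `method`.
#' @export
run_calibration <- function(inputs, method = c("tcp_lot", "trajectory"),
                            k_sd = 1, iterations = 4L, sphericity_tol = 5,
                            max_combinations = 200000L, sensor_offset = 0,
                            flange_center = NULL, override_sphericity = FALSE,
                            min_n = 4L, cond_limit = 1e12, plane_split = NULL,
                            seed = 1L) {
  stopifnot(inherits(inputs, "calibration_inputs"))
  method <- match.arg(method)
  if (is.null(inputs$manual_trajectory))
    stop(sprintf("method '%s' requires the manual trajectory input", method))

  tr <- stage("transform", {
    estimate_transform(zero_shift(inputs$robot_poses),
                       zero_shift(inputs$optical_poses),
                       min_n = min_n, cond_limit = cond_limit)
  })
  origin_dev <- stage("origin", {
    tryCatch(reconstruct_origin(commanded = inputs$robot_poses,
                                measured = inputs$optical_poses,
                                transform = tr, split = plane_split),
             error = function(e) {
               warning(sprintf("origin reconstruction skipped: %s",
                               conditionMessage(e)), call. = FALSE)
               rep(NA_real_, 3L)
             })
  })
  trajectory_robot <- stage("trajectory", {
    transform_trajectory(inputs$manual_trajectory, tr)
  })

  sphere_report <- NULL
  tcp <- rep(NA_real_, 3L)
  lot <- NA_real_
  if (method == "tcp_lot") {
    sphere_report <- stage("spherefit", {
      fit_sphere_robust(inputs$manual_trajectory, k_sd = k_sd,
                        iterations = iterations,
                        sphericity_tol = sphericity_tol,
                        max_combinations = max_combinations, seed = seed)
    })
    tcp <- stage("tcp", compute_tcp(sphere_report, tr, override_sphericity))
    lot <- stage("lot", {
      if (is.null(flange_center)) {
        l <- sphere_report$final$radius - sensor_offset
        if (l <= 0) stop("sensor offset exceeds the fitted sphere radius")
        l
      } else compute_lot(tcp, flange_center, sensor_offset)
    })
  }

  structure(
    list(transform = tr, tcp = tcp, lot = lot,
         origin_deviation = origin_dev,
         trajectory_robot = trajectory_robot,
         sphere_report = sphere_report,
         method = method),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> method '%s'\n", x$method))
  cat(sprintf("  transform residual RMS: %.4g mm\n", x$transform$residual_rms))
  if (!any(is.na(x$origin_deviation)))
    cat(sprintf("  origin deviation (mm): %.4f %.4f %.4f\n",
                x$origin_deviation[1], x$origin_deviation[2],
                x$origin_deviation[3]))
  if (x$method == "tcp_lot")
    cat(sprintf("  TCP (mm): %.2f %.2f %.2f | LOT: %.2f mm\n",
                x$tcp[1], x$tcp[2], x$tcp[3], x$lot))
  cat(sprintf("  transformed trajectory: %d samples in frame '%s'\n",
              nrow(x$trajectory_robot$points), x$trajectory_robot$frame))
  invisible(x)
}
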