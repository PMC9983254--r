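#' Sphere parameters of a ball-joint trajectory
#'
#' Centre and radius of the sphere `(x-x_m)^2 + (y-y_m)^2 + (z-z_m)^2 = R^2`
#' traced by a marker moving about a ball joint. The centre is the joint
#' rotation centre (the robot's tool centre point once mapped into robot world
#' coordinates); the radius is the marker-to-centre distance, i.e. the
#' effective tool length.
#'
#' @param center 3-vector (mm).
#' @param radius positive scalar (mm).
#' @return an object of class `sphere_params`.
#' @export
sphere_params <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite 3-vector")
  radius <- as.numeric(radius)
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  structure(list(center = center, radius = radius), class = "sphere_params")
}

#' @export
print.sphere_params <- function(x, ...) {
  cat(sprintf("<sphere_params> center (%.4f, %.4f, %.4f) mm, radius %.4f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

sphere_design <- function(pts) {
  list(K = cbind(1, pts), rhs = -rowSums(pts^2))
}

p_to_sphere <- function(p) {
  center <- -p[2:4] / 2
  r2 <- sum(center^2) - p[1]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  sphere_params(center, sqrt(r2))
}

#' Direct algebraic least-squares sphere fit
#'
#' Linearises the sphere equation into `p1 + p2*x + p3*y + p4*z =
#' -(x^2+y^2+z^2)` and solves the resulting `n x 4` system through its normal
#' equations (the pseudo-inverse solution), then back-substitutes to centre and
#' radius. Fast, but sensitive to ill conditioning and gross outliers -- see
#' [fit_sphere_robust()] for the combinatorial alternative.
#'
#' @param points a [point_set()] or `n x 3` matrix, `n >= 4`, not coplanar.
#' @param cond_limit conditioning bound on the normal-equation matrix
#'   `K'K` (default 1e12); coplanar rings and other degenerate geometries are
#'   rejected rather than silently solved.
#' @return a [sphere_params()].
#' @export
fit_sphere_linear <- function(points, cond_limit = 1e12) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 4L) stop("need at least 4 points for a sphere fit")
  d <- sphere_design(pts)
  sv <- svd(d$K, nu = 0L, nv = 0L)$d
  # cond(K'K) = cond(K)^2
  if (min(sv) == 0 || (max(sv) / min(sv))^2 > cond_limit)
    stop("degenerate geometry: points are (near-)coplanar")
  p <- solve(crossprod(d$K), crossprod(d$K, d$rhs))
  s <- p_to_sphere(as.numeric(p))
  if (is.null(s)) stop("degenerate geometry: non-positive squared radius")
  s
}

#' Enumerate all four-point index combinations
#'
#' All `choose(n, 4)` quadruples of measurement indices in lexicographic
#' order, the combination sweep of the robust sphere fit. When the count
#' exceeds `max_combinations` a uniform seeded subsample is returned instead
#' (deterministic for a given seed), keeping the sweep tractable for long
#' recordings.
#'
#' @param n number of measurements, `n >= 4`.
#' @param max_combinations cap on the number of quadruples (default 200000).
#' @param seed RNG seed used only when subsampling kicks in.
#' @return integer matrix with 4 columns, one quadruple per row.
#' @export
enumerate_4pt_combinations <- function(n, max_combinations = 200000L, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 4L) stop("need n >= 4 measurements")
  total <- choose(n, 4)
  if (total <= max_combinations) return(t(combn(n, 4L)))
  # deterministic uniform subsample: draw index quadruples, drop duplicates
  with_seed(seed, {
    draw <- function(m) {
      q <- matrix(sample.int(n, 4L * m, replace = TRUE), m, 4L)
      q <- q[apply(q, 1L, anyDuplicated) == 0L, , drop = FALSE]
      t(apply(q, 1L, sort))
    }
    q <- draw(ceiling(max_combinations * 1.1))
    while (nrow(unique(q)) < max_combinations)
      q <- rbind(q, draw(ceiling(max_combinations * 0.1)))
    q <- unique(q)[seq_len(max_combinations), , drop = FALSE]
    q[do.call(order, as.data.frame(q)), , drop = FALSE]
  })
}

#' Exact sphere through four points
#'
#' Solves the 4 x 4 linearised sphere system exactly for one quadruple.
#' Degeneracy (coplanar points, non-positive squared radius) is reported via
#' `valid = FALSE`, never as an error, so sweeps over all combinations cannot
#' abort mid-way.
#'
#' @param points 4 x 3 matrix (or `point_set` of 4 samples).
#' @param combination optional 4-vector of source indices, recorded verbatim.
#' @return an object of class `four_point_fit` with fields `combination`, `p`
#'   (the solved coefficient 4-vector, `NA` when invalid), `sphere`
#'   ([sphere_params()] or `NULL`) and `valid`.
#' @export
fit_sphere_4pt <- function(points, combination = 1:4) {
  pts <- as_point_matrix(points)
  if (nrow(pts) != 4L) stop("exactly 4 points required")
  d <- sphere_design(pts)
  p <- tryCatch(as.numeric(solve(d$K, d$rhs)), error = function(e) NULL)
  sphere <- if (!is.null(p) && all(is.finite(p))) p_to_sphere(p) else NULL
  structure(
    list(combination = as.integer(combination),
         p = if (is.null(p)) rep(NA_real_, 4L) else p,
         sphere = sphere, valid = !is.null(sphere)),
    class = "four_point_fit")
}

#' Robust sphere fit via four-point combinations and sigma-threshold rejection
#'
#' Fits the exact sphere through every four-point combination of the
#' measurements, then repeatedly prunes the ensemble: at each iteration the
#' mean and population standard deviation of each fitted parameter (`x_m`,
#' `y_m`, `z_m`, `R`) are computed over the surviving fits and every fit for
#' which any parameter deviates from its mean by more than `k_sd` standard
#' deviations is removed. Iteration stops at `iterations` rounds, on a fixed
#' point, or when a further cut would leave fewer than two survivors. The
#' final sphere is the arithmetic mean of the surviving parameters; their
#' standard deviations measure how sphere-like the trajectory is.
#'
#' @param points [point_set()] or matrix, `n >= 5` so that more than one
#'   quadruple exists.
#' @param k_sd rejection threshold in standard deviations (default 1).
#' @param iterations maximum number of threshold applications (default 4).
#' @param sphericity_tol tolerance (mm) on the largest parameter SD below which
#'   the trajectory is declared sphere-like (default 5 mm: exact four-point
#'   solves amplify marker noise roughly tenfold, so a genuine ball joint
#'   sampled at 0.1 mm noise shows ensemble SDs of 1-2 mm, while even mildly
#'   aspherical joints show tens of mm); see [assess_sphericity()].
#' @param max_combinations,seed passed to [enumerate_4pt_combinations()].
#' @return a `robust_fit_report`: `combinations` (m x 4), `params` (m x 4
#'   matrix of `x_m, y_m, z_m, R`, `NA` rows for invalid quadruples),
#'   `survivor_mask_per_iteration` (list of logical masks over the m fits,
#'   non-increasing in count), `iterations_run`, `final` ([sphere_params()]),
#'   `param_sd` (population SDs of the surviving parameters), `spherical`,
#'   `tolerance_used`.
#' @export
fit_sphere_robust <- function(points, k_sd = 1, iterations = 4L,
                              sphericity_tol = 5, max_combinations = 200000L,
                              seed = 1L) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 5L) stop("need n >= 5 measurements (more than one quadruple)")
  if (k_sd <= 0) stop("k_sd must be positive")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")

  combos <- enumerate_4pt_combinations(n, max_combinations, seed)
  raw <- .fit_quadruples(pts, combos)
  valid <- raw[, 5L] == 1
  if (!any(valid)) stop("no solvable quadruples")
  params <- raw[, 1:4, drop = FALSE]
  params[!valid, ] <- NA_real_
  colnames(params) <- c("x_m", "y_m", "z_m", "R")

  mask <- valid
  masks <- list()
  iter <- 0L
  for (it in seq_len(iterations)) {
    mu <- colMeans(params[mask, , drop = FALSE])
    sd <- apply(params[mask, , drop = FALSE], 2L, pop_sd)
    keep <- mask
    dev <- abs(sweep(params, 2L, mu))
    over <- sweep(dev, 2L, k_sd * sd, ">")
    keep[mask] <- !apply(over[mask, , drop = FALSE], 1L, any)
    if (sum(keep) < 2L) break           # a further cut would gut the ensemble
    changed <- !identical(keep, mask)
    mask <- keep
    masks[[length(masks) + 1L]] <- mask
    iter <- it
    if (!changed) break                  # fixed point reached
  }
  if (length(masks) == 0L) masks <- list(mask)

  surv <- params[mask, , drop = FALSE]
  final_mu <- colMeans(surv)
  final_sd <- apply(surv, 2L, pop_sd)
  final <- p_to_sphere(c(sum(final_mu[1:3]^2) - final_mu[4L]^2,
                         -2 * final_mu[1:3]))
  if (is.null(final)) stop("no solvable quadruples")
  structure(
    list(combinations = combos, params = params,
         survivor_mask_per_iteration = masks,
         iterations_run = iter,
         n_survivors = sum(mask),
         final = final,
         param_sd = final_sd,
         spherical = max(final_sd) <= sphericity_tol,
         tolerance_used = sphericity_tol,
         k_sd = k_sd),
    class = "robust_fit_report")
}

#' @export
print.robust_fit_report <- function(x, ...) {
  cat(sprintf(paste0("<robust_fit_report> %d/%d quadruples survive after %d ",
                     "iteration(s)\n"),
              x$n_survivors, nrow(x$params), x$iterations_run))
  cat(sprintf("  center (%.4f, %.4f, %.4f) mm, radius %.4f mm\n",
              x$final$center[1], x$final$center[2], x$final$center[3],
              x$final$radius))
  cat(sprintf("  parameter SDs: %.4f %.4f %.4f %.4f mm -> %s (tol %.3g mm)\n",
              x$param_sd[1], x$param_sd[2], x$param_sd[3], x$param_sd[4],
              if (x$spherical) "sphere-like" else "NOT sphere-like",
              x$tolerance_used))
  invisible(x)
}

#' Decide whether a trajectory is sphere-like
#'
#' The trajectory is accepted as a ball-joint motion when none of the four
#' fitted parameters (`x_m`, `y_m`, `z_m`, `R`) varies across the surviving
#' four-point fits by more than `tol`. The tolerance is the caller's to choose:
#' it depends on the positional tolerance of the joint test that follows.
#'
#' @param report a `robust_fit_report` from [fit_sphere_robust()].
#' @param tol tolerance in mm.
#' @return `TRUE` iff `max(report$param_sd) <= tol`.
#' @export
assess_sphericity <- function(report, tol) {
  stopifnot(inherits(report, "robust_fit_report"), is.finite(tol))
  max(report$param_sd) <= tol
}
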