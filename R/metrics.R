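#' Summary statistics with the calibration-table conventions
#'
#' Summarises a vector of measurements the way the rig's validation tables do:
#' arithmetic mean; population standard deviation (divisor `n`, not `n - 1`);
#' median deviation (even-`n` median = mean of the two middle order statistics,
#' minus the mean); the largest deviation above the mean (printed "+") and the
#' magnitude of the largest deviation below it (printed "-"). The raw signed
#' extremes are returned too, since some tables print those instead.
#'
#' @param values numeric vector, `n >= 1`.
#' @param sd_divisor `"n"` (population, the table convention, default) or
#'   `"n-1"` (sample).
#' @return an object of class `summary_stats` with fields `mean`, `sd`,
#'   `median_deviation`, `max_dev_pos`, `min_dev_neg`, `max`, `min`, `n`.
#' @export
summary_stats <- function(values, sd_divisor = c("n", "n-1")) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty value sequence")
  sd_divisor <- match.arg(sd_divisor)
  n <- length(values)
  mu <- mean(values)
  sd <- if (sd_divisor == "n") pop_sd(values)
        else if (n > 1L) stats::sd(values) else 0
  structure(
    list(mean = mu,
         sd = sd,
         median_deviation = median(values) - mu,
         max_dev_pos = max(values) - mu,
         min_dev_neg = mu - min(values),
         max = max(values),
         min = min(values),
         n = n),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(paste0("<summary_stats> n=%d mean=%.4f sd=%.4f median_dev=%.4f ",
                     "max_dev+=%.4f min_dev-=%.4f\n"),
              x$n, x$mean, x$sd, x$median_deviation, x$max_dev_pos,
              x$min_dev_neg))
  invisible(x)
}

#' Centre deviations on a zero mean
#'
#' @param values numeric vector, `n >= 1`.
#' @return `values - mean(values)`; the output mean is zero to within 1e-12.
#' @export
center_deviations <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty value sequence")
  values - mean(values)
}

#' Remove mounting-grid shifts from recorded positions
#'
#' The specimen holder is remounted at known offsets on a hole grid (default
#' pitch 50 mm); subtracting the per-recording offset refers every position
#' back to the first mounting position so that the residual spread reflects
#' measurement error only.
#'
#' @param raw `n x 3` matrix of positions (mm).
#' @param grid_offsets `n x 3` matrix of mounting offsets (mm); x/y components
#'   should be integer multiples of `pitch` and z should be 0 -- violations
#'   raise a warning, not an error.
#' @param pitch grid pitch in mm (default 50).
#' @return `raw - grid_offsets`.
#' @export
normalize_positions <- function(raw, grid_offsets, pitch = 50) {
  raw <- as_point_matrix(raw)
  grid_offsets <- as_point_matrix(grid_offsets)
  if (nrow(raw) != nrow(grid_offsets))
    stop("raw and grid_offsets must have equal length")
  off_grid <- abs(grid_offsets[, 1:2] / pitch -
                  round(grid_offsets[, 1:2] / pitch)) > 1e-6
  if (any(off_grid) || any(abs(grid_offsets[, 3L]) > 1e-6))
    warning(sprintf("offsets are not on the %g mm grid", pitch))
  raw - grid_offsets
}

#' Resample a polyline to n points equally spaced in arc length
#'
#' Linear interpolation along cumulative chord length; used to put two
#' trajectories recorded at different rates into index correspondence.
#'
#' @param points `n x 3` matrix or [point_set()].
#' @param n_out number of output samples (`>= 2`).
#' @return `n_out x 3` matrix.
#' @export
resample_arclength <- function(points, n_out) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 2L) stop("need at least 2 points to resample")
  if (n_out < 2L) stop("n_out must be >= 2")
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  if (s[length(s)] == 0) return(pts[rep(1L, n_out), , drop = FALSE])
  # collapse duplicated arc-length knots (repeated points)
  keep <- !duplicated(s)
  s_out <- seq(0, s[length(s)], length.out = n_out)
  vapply(1:3, function(j) approx(s[keep], pts[keep, j], xout = s_out)$y,
         numeric(n_out))
}

#' Compare a reproduced trajectory against its reference
#'
#' Pairs the two curves point-by-point and reports the signed per-axis
#' deviations `test - reference`, the per-point Euclidean distances, and an
#' average/max/min summary per column -- the layout of a trajectory-accuracy
#' table. Pairing: `"arclength"` (default) resamples both curves to the
#' reference's sample count at equal arc-length spacing, then pairs by index --
#' appropriate when the two recordings sample the same path at different rates.
#' `"nearest"` pairs each reference point with its nearest test point.
#'
#' @param reference,test [point_set()]s (same frame) or `n x 3` matrices with
#'   at least 2 points each.
#' @param pairing `"arclength"` or `"nearest"`.
#' @return a `trajectory_comparison`: `dX`, `dY`, `dZ`, `euclidean` (numeric
#'   vectors) and `summary` (data frame, rows average/max/min, columns
#'   dX/dY/dZ/euclidean).
#' @export
compare_trajectories <- function(reference, test,
                                 pairing = c("arclength", "nearest")) {
  pairing <- match.arg(pairing)
  if (inherits(reference, "point_set") && inherits(test, "point_set") &&
      !identical(reference$frame, test$frame))
    stop(sprintf("frame mismatch: '%s' vs '%s'", reference$frame, test$frame))
  ref <- as_point_matrix(reference)
  tst <- as_point_matrix(test)
  if (nrow(ref) < 2L || nrow(tst) < 2L)
    stop("both trajectories need at least 2 points")
  if (pairing == "arclength") {
    n_out <- nrow(ref)
    ref_p <- resample_arclength(ref, n_out)
    tst_p <- resample_arclength(tst, n_out)
  } else {
    d2 <- outer(rowSums(ref^2), rowSums(tst^2), "+") - 2 * ref %*% t(tst)
    nn <- max.col(-d2, ties.method = "first")
    ref_p <- ref
    tst_p <- tst[nn, , drop = FALSE]
  }
  delta <- tst_p - ref_p
  eu <- sqrt(rowSums(delta^2))
  summ <- data.frame(
    dX = c(mean(delta[, 1L]), max(delta[, 1L]), min(delta[, 1L])),
    dY = c(mean(delta[, 2L]), max(delta[, 2L]), min(delta[, 2L])),
    dZ = c(mean(delta[, 3L]), max(delta[, 3L]), min(delta[, 3L])),
    euclidean = c(mean(eu), max(eu), min(eu)),
    row.names = c("average", "max", "min"))
  structure(
    list(dX = delta[, 1L], dY = delta[, 2L], dZ = delta[, 3L],
         euclidean = eu, summary = summ, pairing = pairing),
    class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf("<trajectory_comparison> %d paired points (%s pairing)\n",
              length(x$euclidean), x$pairing))
  print(round(x$summary, 3))
  invisible(x)
}
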