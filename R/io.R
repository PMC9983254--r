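#' Read a marker trajectory CSV
#'
#' Expected schema: header row with columns
#' `frame,pose_index,x_mm,y_mm,z_mm` and optionally
#' `alpha_deg,beta_deg,gamma_deg`; decimal points (not commas). Malformed rows
#' are reported with their line number and column.
#'
#' @param path file path.
#' @return a [point_set()] (all rows must share one frame label).
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("frame", "pose_index", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing, collapse = ", ")))
  if (nrow(df) < 1L) stop(sprintf("no samples in %s", path))
  num_cols <- c("pose_index", "x_mm", "y_mm", "z_mm")
  angle_cols <- intersect(c("alpha_deg", "beta_deg", "gamma_deg"), names(df))
  for (col in c(num_cols, angle_cols)) {
    raw <- trimws(df[[col]])
    comma <- grepl("^-?[0-9]+,[0-9]+$", raw)
    if (any(comma))
      stop(sprintf("comma decimal in %s, column '%s', line %d (cell '%s'); use dot decimals",
                   path, col, which(comma)[1L] + 1L, raw[which(comma)[1L]]))
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- is.na(parsed)
    if (any(bad))
      stop(sprintf("non-numeric cell in %s, column '%s', line %d (cell '%s')",
                   path, col, which(bad)[1L] + 1L, raw[which(bad)[1L]]))
    df[[col]] <- parsed
  }
  if (anyDuplicated(df$pose_index))
    stop(sprintf("duplicate pose_index in %s (first: %s)", path,
                 df$pose_index[duplicated(df$pose_index)][1L]))
  frame <- unique(df$frame)
  if (length(frame) != 1L)
    stop(sprintf("multiple frame labels in %s: %s", path,
                 paste(frame, collapse = ", ")))
  orientation <- if (length(angle_cols) == 3L)
    as.matrix(df[, c("alpha_deg", "beta_deg", "gamma_deg")]) else NULL
  point_set(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), frame = frame,
            pose_index = df$pose_index, orientation = orientation)
}

#' Write a point set to the trajectory CSV schema
#'
#' @param points a [point_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(points, path) {
  stopifnot(inherits(points, "point_set"))
  df <- data.frame(frame = points$frame, pose_index = points$pose_index,
                   x_mm = points$points[, 1L], y_mm = points$points[, 2L],
                   z_mm = points$points[, 3L])
  if (!is.null(points$orientation)) {
    df$alpha_deg <- points$orientation[, 1L]
    df$beta_deg <- points$orientation[, 2L]
    df$gamma_deg <- points$orientation[, 3L]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a frame transform to JSON
#'
#' Row-major map entries, both anchors, frames and the calibration residual,
#' at full precision.
#'
#' @param transform a `frame_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  stopifnot(inherits(transform, "frame_transform"))
  jsonlite::write_json(
    list(linear_map = as.numeric(t(transform$linear_map)),
         source_anchor = transform$source_anchor,
         target_anchor = transform$target_anchor,
         source_frame = transform$source_frame,
         target_frame = transform$target_frame,
         direction = transform$direction,
         residual_rms = transform$residual_rms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame transform back from JSON
#'
#' @param path path written by [write_transform_json()].
#' @return a `frame_transform`.
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame_transform(matrix(x$linear_map, 3L, byrow = TRUE),
                  source_anchor = x$source_anchor,
                  target_anchor = x$target_anchor,
                  source_frame = x$source_frame,
                  target_frame = x$target_frame,
                  residual_rms = x$residual_rms)
}

robust_report_payload <- function(report) {
  if (is.null(report)) return(NULL)
  list(n_combinations = nrow(report$params),
       n_survivors = report$n_survivors,
       iterations_run = report$iterations_run,
       k_sd = report$k_sd,
       center = report$final$center,
       radius = report$final$radius,
       param_sd = as.numeric(report$param_sd),
       spherical = report$spherical,
       tolerance_used = report$tolerance_used,
       survivor_mask_per_iteration =
         lapply(report$survivor_mask_per_iteration, as.logical))
}

#' Write a calibration result (and its audit trail) to JSON
#'
#' @param result a `calibration_result` from [run_calibration()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "calibration_result"))
  jsonlite::write_json(
    list(method = result$method,
         transform = list(
           linear_map = as.numeric(t(result$transform$linear_map)),
           source_anchor = result$transform$source_anchor,
           target_anchor = result$transform$target_anchor,
           direction = result$transform$direction,
           residual_rms = result$transform$residual_rms),
         tcp = result$tcp,
         lot = result$lot,
         origin_deviation = result$origin_deviation,
         sphere_report = robust_report_payload(result$sphere_report),
         trajectory_robot = list(
           frame = result$trajectory_robot$frame,
           n = nrow(result$trajectory_robot$points))),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
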