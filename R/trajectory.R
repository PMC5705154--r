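#' Trajectory tables
#'
#' A trajectory is an ordinary tibble with columns `frame` (strictly
#' increasing integer), `x`, `y` (pixel or cervical-unit coordinates,
#' bottom-left origin) and `status` (one of `ok`, `masked`, `failed`,
#' `interpolated`). All trajectory-consuming functions in the package accept
#' any data frame with these columns, so results chain with the pipe.
#'
#' @param df data frame with at least `frame`, `x`, `y`; a missing `status`
#'   column defaults to `"ok"`.
#' @param point optional point label (e.g. `"hyoid"`, `"C2"`) stored in a
#'   `point` column.
#' @return A tibble sorted by `frame`.
#' @export
as_trajectory <- function(df, point = NULL) {
  if (!all(c("frame", "x", "y") %in% names(df))) {
    abort("A trajectory needs columns `frame`, `x`, `y`.")
  }
  out <- tibble::as_tibble(df)
  if (!"status" %in% names(out)) out$status <- "ok"
  if (!is.null(point)) out$point <- point
  if (anyDuplicated(out$frame)) abort("Duplicated frame index in trajectory.")
  out <- dplyr::arrange(out, .data$frame)
  bad <- out$status != "failed" & (!is.finite(out$x) | !is.finite(out$y))
  if (any(bad)) {
    abort("Non-finite coordinates are only allowed on `failed` samples.")
  }
  out
}

#' Read a trajectory CSV
#'
#' Expects a header with columns `frame,x,y` and optionally `status`.
#'
#' @param path CSV file path.
#' @param point optional point label to attach.
#' @return A trajectory tibble (see [as_trajectory()]).
#' @export
read_trajectory <- function(path, point = NULL) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(df))) {
    abort(sprintf("'%s' must have columns frame,x,y[,status].", path))
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      abort(sprintf("Column `%s` in '%s' is not numeric.", col, path))
    }
  }
  as_trajectory(df[, intersect(c("frame", "x", "y", "status"), names(df))],
                point = point)
}

#' Write a trajectory CSV
#'
#' Columns are written in the fixed order `frame,x,y,status` with full
#' double precision, so write/read round trips are lossless.
#'
#' @param traj trajectory tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (nrow(traj) > 0) traj <- as_trajectory(traj)
  if (!"status" %in% names(traj)) traj$status <- character(0)
  df <- data.frame(frame = traj$frame,
                   x = format(traj$x, digits = 17, trim = TRUE, scientific = FALSE),
                   y = format(traj$y, digits = 17, trim = TRUE, scientific = FALSE),
                   status = traj$status)
  if (nrow(df) == 0) df <- data.frame(frame = numeric(0), x = numeric(0),
                                      y = numeric(0), status = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tracking session configuration
#'
#' Bundles the tracker constants: template side length, bounded search box,
#' failure threshold, smoothing parameter, frame rate and RNG seed. Defaults
#' follow the published implementation: shifts within ±5 px, rotations within
#' ±2.5 degrees, an 8-pixel failure threshold, and 30 fps.
#'
#' @param roi_side odd template side length in pixels (default 41).
#' @param max_shift half-width of the shift search box in pixels.
#' @param max_angle_deg half-width of the rotation search box in degrees.
#' @param failure_threshold displacement-error threshold in pixels at which a
#'   tracking step is declared a failure.
#' @param spline_p cubic smoothing-spline parameter in `[0, 1]`.
#' @param fps frames per second.
#' @param min_clip_frac smallest retained fraction of ROI pixels for a
#'   partially-masked frame to still be matched; below it the frame is treated
#'   as totally masked.
#' @param clip_margin extra pixels clipped beyond the mandible chord during
#'   tracking, absorbing the occluder's edge-response bleed (Sobel support
#'   plus subpixel interpolation).
#' @param mask_center_depth depth (px) of the target point beyond the chord
#'   at which a frame is declared totally masked: once the point itself is
#'   buried under the mandible, the clipped ROI holds no evidence of it and
#'   the position is interpolated from neighbouring frames instead.
#' @param seed integer seed for the stochastic optimizer variants.
#' @param optimizer `"grid"` (exhaustive coarse grid + simplex refinement) or
#'   `"ga"` (real-coded genetic algorithm + simplex refinement).
#' @param template_update `"fixed"` keeps each point's reference template
#'   anchored at its seed frame (only the ROI position follows the target),
#'   which avoids the cumulative subpixel drift of per-frame re-anchoring;
#'   `"each_ok"` re-samples the reference after every clean accepted step,
#'   for scenes whose appearance changes over the sequence.
#' @return A `session_config` list.
#' @export
session_config <- function(roi_side = 41L, max_shift = 5, max_angle_deg = 2.5,
                           failure_threshold = 8, spline_p = 0.3, fps = 30,
                           min_clip_frac = 0.1, clip_margin = 3,
                           mask_center_depth = 2, seed = 1L,
                           optimizer = c("grid", "ga"),
                           template_update = c("fixed", "each_ok")) {
  roi_side <- check_odd_side(roi_side)
  if (max_shift <= 0 || max_angle_deg <= 0) abort("Search bounds must be positive.")
  if (failure_threshold <= 0) abort("`failure_threshold` must be positive.")
  if (spline_p < 0 || spline_p > 1) abort("`spline_p` must be in [0, 1].")
  structure(list(
    roi_side = roi_side, max_shift = max_shift, max_angle_deg = max_angle_deg,
    failure_threshold = failure_threshold, spline_p = spline_p, fps = fps,
    min_clip_frac = min_clip_frac, clip_margin = clip_margin,
    mask_center_depth = mask_center_depth,
    seed = as.integer(seed),
    optimizer = match.arg(optimizer),
    template_update = match.arg(template_update)
  ), class = "session_config")
}
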