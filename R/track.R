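#' Track seeded anatomical points through a frame sequence
#'
#' Frame-by-frame edge-template tracking of up to five seeded points: the
#' hyoid target, two mandible-edge points, and the C2/C4 vertebral landmarks.
#' Each step searches the bounded rotation-and-shift box between the last
#' clean template and the current frame with [optimize_pose()] and moves the
#' point by the recovered shift. When the mandible chord (from the two
#' tracked mandible points) crosses the hyoid ROI, the masked part is clipped
#' from both the template and the current ROI before matching; frames whose
#' retained pixel fraction falls below `config$min_clip_frac` are treated as
#' totally masked and later filled by [interpolate_masked()]. The hyoid track
#' is monitored with the third-order motion predictor ([check_step()]); steps
#' whose displacement error reaches the failure threshold are flagged
#' `failed`.
#'
#' @param frames a [frame_sequence()].
#' @param seeds data frame with columns `point`, `x`, `y` (or a named list of
#'   `(x, y)` pairs). Recognized labels: `hyoid`, `mandible1`, `mandible2`,
#'   `C2`, `C4`; `hyoid` is required, the mandible pair enables occlusion
#'   handling, C2/C4 enable calibration.
#' @param config a [session_config()].
#' @return A `vfss_track` object; [tidy()] returns the long trajectory table,
#'   [glance()] a one-row summary.
#' @export
track_sequence <- function(frames, seeds, config = session_config()) {
  stopifnot(inherits(frames, "frame_sequence"))
  seeds <- normalize_seeds(seeds)
  if (!"hyoid" %in% seeds$point) abort("Seeds must include the `hyoid` point.")
  n <- length(frames$frames)
  f1 <- frames$frames[[1]]
  h <- (config$roi_side - 1) / 2
  for (k in seq_len(nrow(seeds))) {
    if (!in_bounds(f1, seeds$x[k], seeds$y[k])) {
      abort(sprintf("Seed for '%s' lies outside the image.", seeds$point[k]))
    }
    if (seeds$x[k] - h < 0 || seeds$x[k] + h > ncol(f1) - 1 ||
        seeds$y[k] - h < 0 || seeds$y[k] + h > nrow(f1) - 1) {
      abort(sprintf("Initial ROI for '%s' falls outside the image.",
                    seeds$point[k]))
    }
  }

  edges <- vector("list", n)
  edges[[1]] <- sobel_edges(f1)

  pts <- seeds$point
  order_pts <- intersect(c("mandible1", "mandible2", "C2", "C4", "hyoid"), pts)
  st <- setNames(vector("list", length(pts)), pts)
  for (p in pts) {
    i0 <- match(p, seeds$point)
    st[[p]] <- list(center = c(seeds$x[i0], seeds$y[i0]),
                    ref_frame = 1L, ref_center = c(seeds$x[i0], seeds$y[i0]))
  }
  pos <- array(NA_real_, c(n, 2, length(pts)),
               dimnames = list(NULL, c("x", "y"), pts))
  status <- matrix("ok", n, length(pts), dimnames = list(NULL, pts))
  match_err <- matrix(NA_real_, n, length(pts), dimnames = list(NULL, pts))
  delta <- rep(NA_real_, n)
  for (p in pts) pos[1, , p] <- st[[p]]$center

  occlusion_on <- all(c("mandible1", "mandible2") %in% pts)

  for (i in seq_len(n)[-1]) {
    edges[[i]] <- sobel_edges(frames$frames[[i]])
    for (p in order_pts) {
      s <- st[[p]]
      clip <- NULL
      stat <- "ok"
      if (p == "hyoid" && occlusion_on &&
          all(is.finite(pos[i, , "mandible1"])) &&
          all(is.finite(pos[i, , "mandible2"]))) {
        raw_chord <- mandible_chord(pos[i, , "mandible1"],
                                    pos[i, , "mandible2"])
        chord <- offset_chord(raw_chord, config$clip_margin)
        if (roi_is_masked(s$center, config$roi_side, chord)) {
          clip <- tryCatch(clip_roi(s$center, config$roi_side, chord),
                           hyoidtrack_totally_masked = function(e) NULL)
          full <- config$roi_side^2
          # the frame is unusable when the retained pixel set is tiny or the
          # target point itself sits inside the mandible: the clipped ROI
          # then holds no evidence of the target at all
          centre_depth <- chord_signed(raw_chord, s$center[1], s$center[2])
          if (is.null(clip) ||
              clip$n_retained < config$min_clip_frac * full ||
              centre_depth >= config$mask_center_depth) {
            status[i, p] <- "masked"          # totally masked: no coordinates
            next
          }
          stat <- "masked"
        }
      }
      tmpl <- edge_template(s$ref_center, config$roi_side)
      if (!is.null(clip)) {
        # apply the same retained offsets to template and current ROI
        clip_tmpl <- clip
      } else clip_tmpl <- NULL
      p_opt <- optimize_pose(tmpl, edges[[s$ref_frame]], edges[[i]],
                             clip = clip_tmpl, cur_center = s$center,
                             max_shift = config$max_shift,
                             max_angle_deg = config$max_angle_deg,
                             optimizer = config$optimizer,
                             seed = config$seed + i)
      new_center <- s$center + p_opt$shift
      match_err[i, p] <- p_opt$error

      if (p == "hyoid") {
        hist_rows <- monitor_history(pos[, , "hyoid", drop = FALSE],
                                     status[, "hyoid"], i)
        if (!is.null(hist_rows)) {
          chk <- check_step(hist_rows, new_center, config$failure_threshold)
          delta[i] <- chk$delta
          if (!chk$pass) stat <- "failed"
        }
      }

      pos[i, , p] <- new_center
      status[i, p] <- stat
      st[[p]]$center <- new_center
      if (stat == "ok" && config$template_update == "each_ok") {
        st[[p]]$ref_frame <- i              # clean re-anchor of the template
        st[[p]]$ref_center <- new_center
      }
    }
  }

  traj <- purrr::map_dfr(pts, function(p) {
    tibble::tibble(point = p, frame = seq_len(n) - 1L,
                   x = pos[, "x", p], y = pos[, "y", p],
                   status = status[, p])
  })
  traj <- traj |>
    dplyr::group_by(.data$point) |>
    dplyr::group_modify(function(df, key) {
      tryCatch(interpolate_masked(df), error = function(e) df)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("point", "frame", "x", "y", "status")

  run <- structure(list(
    trajectories = traj,
    delta = tibble::tibble(frame = seq_len(n) - 1L, delta = delta),
    match_error = match_err,
    seeds = seeds, config = config, fps = frames$fps,
    failure = NULL
  ), class = "vfss_track")
  if (any(status[, "hyoid"] == "failed")) {
    run$failure <- locate_failure(run)
  }
  run
}

# The monitor uses only clean, contiguous history: the four `ok` frames
# immediately preceding frame i. Masked, failed or interpolated frames reset
# the window, and monitoring stays inactive for the first steps after any
# (re)seed.
monitor_history <- function(pos, status, i) {
  if (i <= 4) return(NULL)
  win <- (i - 4):(i - 1)
  if (any(status[win] != "ok")) return(NULL)
  if (!all(is.finite(pos[win, , 1]))) return(NULL)
  data.frame(x = pos[win, "x", 1], y = pos[win, "y", 1])
}

normalize_seeds <- function(seeds) {
  if (is.data.frame(seeds)) {
    stopifnot(all(c("point", "x", "y") %in% names(seeds)))
    out <- tibble::as_tibble(seeds[, c("point", "x", "y")])
  } else if (is.list(seeds)) {
    out <- tibble::tibble(point = names(seeds),
                          x = vapply(seeds, `[`, numeric(1), 1),
                          y = vapply(seeds, `[`, numeric(1), 2))
  } else {
    abort("`seeds` must be a data frame (point, x, y) or a named list.")
  }
  known <- c("hyoid", "mandible1", "mandible2", "C2", "C4")
  bad <- setdiff(out$point, known)
  if (length(bad)) abort(sprintf("Unknown point label(s): %s.",
                                 paste(bad, collapse = ", ")))
  out
}

#' Resume a tracking run from a re-specified seed
#'
#' Re-tracks all points from `frame_index` onward, seeding the hyoid at
#' `new_seed` (and optionally a new ROI side length); earlier samples are
#' kept untouched and the motion history is reset at the splice, so
#' monitoring restarts fresh.
#'
#' @param run a `vfss_track` from [track_sequence()].
#' @param frames the same [frame_sequence()] the run was tracked on.
#' @param frame_index 0-based frame at which to resume.
#' @param new_seed `(x, y)` hyoid position in that frame.
#' @param new_side optional new odd ROI side length.
#' @return A spliced `vfss_track`.
#' @export
resume_tracking <- function(run, frames, frame_index, new_seed,
                            new_side = NULL) {
  stopifnot(inherits(run, "vfss_track"))
  n <- length(frames$frames)
  if (frame_index < 0 || frame_index > n - 1) abort("`frame_index` out of range.")
  config <- run$config
  if (!is.null(new_side)) config$roi_side <- check_odd_side(new_side)
  traj <- run$trajectories
  seeds <- traj |>
    dplyr::filter(.data$frame == frame_index) |>
    dplyr::transmute(point = .data$point, x = .data$x, y = .data$y)
  seeds$x[seeds$point == "hyoid"] <- new_seed[1]
  seeds$y[seeds$point == "hyoid"] <- new_seed[2]
  sub <- frame_sequence(frames$frames[(frame_index + 1):n], fps = frames$fps)
  new_run <- track_sequence(sub, seeds, config)
  new_traj <- new_run$trajectories |>
    dplyr::mutate(frame = .data$frame + frame_index)
  kept <- dplyr::filter(traj, .data$frame < frame_index)
  out <- new_run
  out$trajectories <- dplyr::arrange(dplyr::bind_rows(kept, new_traj),
                                     .data$point, .data$frame)
  out$seeds <- seeds
  out$config <- config
  out$delta <- dplyr::bind_rows(
    dplyr::filter(run$delta, .data$frame < frame_index),
    dplyr::mutate(new_run$delta, frame = .data$frame + frame_index))
  out$failure <- tryCatch(locate_failure(out), error = function(e) NULL)
  out
}

#' @export
print.vfss_track <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<vfss_track> %d frames, %d points (%s)\n", g$n_frames,
              g$n_points, paste(unique(x$trajectories$point), collapse = ", ")))
  cat(sprintf("  statuses: %d ok, %d masked, %d interpolated, %d failed\n",
              g$n_ok, g$n_masked, g$n_interpolated, g$n_failed))
  if (!is.null(x$failure)) {
    cat(sprintf("  first failed frame: %d (delta %.2f px >= %g px)\n",
                x$failure$first_failed_frame, x$failure$delta,
                x$failure$threshold))
  }
  invisible(x)
}

#' @rdname track_sequence
#' @param x a `vfss_track`.
#' @param ... unused.
#' @method tidy vfss_track
#' @export
tidy.vfss_track <- function(x, ...) x$trajectories

#' @rdname track_sequence
#' @method glance vfss_track
#' @export
glance.vfss_track <- function(x, ...) {
  tr <- x$trajectories
  hy <- tr$status[tr$point == "hyoid"]
  tibble::tibble(
    n_frames = length(unique(tr$frame)),
    n_points = length(unique(tr$point)),
    n_ok = sum(hy == "ok"),
    n_masked = sum(hy == "masked"),
    n_interpolated = sum(hy == "interpolated"),
    n_failed = sum(hy == "failed"),
    first_failed_frame = if (is.null(x$failure)) NA_integer_ else
      as.integer(x$failure$first_failed_frame),
    mean_match_error = mean(x$match_error[, "hyoid"], na.rm = TRUE)
  )
}

#' Write a tracking run to CSV files
#'
#' One trajectory CSV per tracked point (`<label>.csv`, columns
#' `frame,x,y,status`) plus `status.csv` with the per-frame hyoid status and
#' displacement error.
#'
#' @param run a `vfss_track`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_track <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in unique(run$trajectories$point)) {
    write_trajectory(dplyr::filter(run$trajectories, .data$point == p),
                     file.path(dir, paste0(p, ".csv")))
  }
  hy <- dplyr::filter(run$trajectories, .data$point == "hyoid")
  status <- dplyr::left_join(
    dplyr::select(hy, "frame", "status"), run$delta, by = "frame")
  utils::write.csv(status, file.path(dir, "status.csv"), row.names = FALSE)
  invisible(dir)
}
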