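#' Predict the next target position from recent motion
#'
#' Third-order prediction of the hyoid position one frame ahead,
#' `H(i+1) ~ H(i) + H'(i) dt + H''(i) dt^2 / 2 + H'''(i) dt^3 / 6` with
#' `dt = 1` frame. The derivatives are estimated from the interpolating cubic
#' through the last four accepted positions (equivalently, Newton backward
#' extrapolation `H + del + del^2 + del^3` on the backward differences),
#' which makes the prediction exact for any cubic-polynomial path.
#'
#' @param history matrix or data frame of the accepted positions in temporal
#'   order, columns `x`, `y`; at least the last four are required and used.
#' @return Predicted `(x, y)`.
#' @export
predict_position <- function(history) {
  h <- as.matrix(history[, c("x", "y"), drop = FALSE])
  if (nrow(h) < 4) {
    abort("Monitoring inactive: fewer than four accepted positions.",
          class = "hyoidtrack_monitor_inactive")
  }
  h <- h[nrow(h) - 3:0, , drop = FALSE]         # H(i-3) .. H(i)
  d1 <- h[4, ] - h[3, ]                          # backward differences at i
  d2 <- h[4, ] - 2 * h[3, ] + h[2, ]
  d3 <- h[4, ] - 3 * h[3, ] + 3 * h[2, ] - h[1, ]
  unname(h[4, ] + d1 + d2 + d3)
}

#' Check one tracking step against the motion prediction
#'
#' The displacement error is the Euclidean distance between the predicted
#' and the tracked position; the step fails when it reaches the threshold
#' (default 8 pixels).
#'
#' @inheritParams predict_position
#' @param tracked tracked `(x, y)` for the next frame.
#' @param threshold failure threshold in pixels.
#' @return List with `pass`, `delta`, `predicted` and `threshold`.
#' @export
check_step <- function(history, tracked, threshold = 8) {
  pred <- predict_position(history)
  delta <- sqrt(sum((pred - as.numeric(tracked))^2))
  list(pass = delta < threshold, delta = delta,
       predicted = pred, threshold = threshold)
}

#' Locate the first failed frame of a tracking run
#'
#' Re-evaluates the motion check over the stored hyoid positions around the
#' flagged frame — backwards first, then forwards — and returns the earliest
#' frame whose displacement error reaches the threshold.
#'
#' @param run a tracking run from [track_sequence()].
#' @param hint frame index near which the failure was flagged (defaults to
#'   the run's flagged frame).
#' @param threshold failure threshold in pixels (defaults to the run's).
#' @return List with `first_failed_frame`, `delta` and `threshold`.
#' @export
locate_failure <- function(run, hint = NULL, threshold = NULL) {
  traj <- dplyr::filter(tidy(run), .data$point == "hyoid")
  threshold <- threshold %||% run$config$failure_threshold
  usable <- is.finite(traj$x) & is.finite(traj$y) &
    traj$status != "interpolated"
  hint <- hint %||% {
    ff <- traj$frame[traj$status == "failed"]
    if (length(ff)) min(ff) else max(traj$frame)
  }
  scan <- function(rows) {
    for (i in rows) {
      win <- which(usable[seq_len(i - 1)])
      win <- tail(win, 4)
      if (length(win) < 4 || !usable[i]) next
      if (any(diff(win) != 1) || max(win) != i - 1) next
      chk <- check_step(traj[win, c("x", "y")], c(traj$x[i], traj$y[i]),
                        threshold)
      if (!chk$pass) return(list(first_failed_frame = traj$frame[i],
                                 delta = chk$delta, threshold = threshold))
    }
    NULL
  }
  hint_row <- which(traj$frame == hint)
  if (length(hint_row) == 0) hint_row <- nrow(traj)
  back <- scan(seq(2, hint_row))              # earliest first
  if (!is.null(back)) return(back)
  if (hint_row < nrow(traj)) {
    fwd <- scan(seq(hint_row + 1, nrow(traj)))
    if (!is.null(fwd)) return(fwd)
  }
  abort("No failure present in this tracking run.")
}
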