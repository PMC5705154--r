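#' Mandible chord
#'
#' The straight line through the two tracked mandible-edge points,
#' approximating the lower edge of the mandible. It is treated as an infinite
#' line; the "mandible side" (the side that masks the hyoid ROI) is the side
#' of greater y in the bottom-left-origin convention, i.e. superior in the
#' lateral projection. Points exactly on the line count as masked so pixel
#' counts are deterministic.
#'
#' @param p1,p2 numeric `(x, y)` mandible-edge points; must differ.
#' @return A `mandible_chord` with the line's unit normal pointing into the
#'   masked side and a `side()`-style signed-distance evaluator.
#' @export
mandible_chord <- function(p1, p2) {
  if (length(p1) != 2 || length(p2) != 2 || !all(is.finite(c(p1, p2)))) {
    abort("`p1` and `p2` must be finite (x, y) points.")
  }
  d <- c(p2[1] - p1[1], p2[2] - p1[2])
  if (all(d == 0)) abort("Mandible points are coincident.")
  n <- c(-d[2], d[1])                    # perpendicular to the chord
  if (n[2] < 0 || (n[2] == 0 && n[1] < 0)) n <- -n  # point toward greater y
  n <- n / sqrt(sum(n^2))
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), normal = n),
            class = "mandible_chord")
}

# Signed distance to the chord line; >= 0 means masked (mandible side).
chord_signed <- function(chord, x, y) {
  chord$normal[1] * (x - chord$p1[1]) + chord$normal[2] * (y - chord$p1[2])
}

# Shift the chord line by `margin` pixels against its normal, enlarging the
# masked side. The tracker clips with a small margin because the Sobel
# operator's 3x3 support and the bilinear pose sampling smear the occluder's
# edge response 1-2 px beyond the geometric boundary.
offset_chord <- function(chord, margin) {
  if (margin == 0) return(chord)
  shift <- -margin * chord$normal
  mandible_chord(chord$p1 + shift, chord$p2 + shift)
}

#' Does the mandible mask part of an ROI?
#'
#' True when any pixel of the square ROI lies on the mandible side of the
#' chord (equivalently, when the maximum over the four corners of the signed
#' distance to the line is non-negative). An ROI entirely on the clear side
#' returns `FALSE` and is matched as a normal, unclipped case.
#'
#' @param center ROI centre `(x, y)`.
#' @param side odd ROI side length in pixels.
#' @param chord a [mandible_chord()].
#' @return Logical scalar.
#' @export
roi_is_masked <- function(center, side, chord) {
  h <- (check_odd_side(side, min = 3L, arg = "side") - 1) / 2
  cx <- center[1] + c(-h, h, -h, h)
  cy <- center[2] + c(-h, -h, h, h)
  max(chord_signed(chord, cx, cy)) >= 0
}

#' Clip the masked part out of an ROI
#'
#' Retains exactly the ROI pixels strictly on the clear (non-mandible) side
#' of the chord line; pixels on the line are masked. The same retained offset
#' set is applied to the reference template so its edge characteristics stay
#' comparable with the clipped current ROI.
#'
#' @inheritParams roi_is_masked
#' @return A `clipped_region`: `offsets` (retained pixel offsets relative to
#'   the centre), `n_retained`, `n_masked` and `side`.
#' @export
clip_roi <- function(center, side, chord) {
  side <- check_odd_side(side, min = 3L, arg = "side")
  off <- roi_offsets(side)
  keep <- chord_signed(chord, center[1] + off$dx, center[2] + off$dy) < 0
  out <- structure(list(offsets = off[keep, , drop = FALSE],
                        n_retained = sum(keep),
                        n_masked = sum(!keep),
                        side = side),
                   class = "clipped_region")
  if (out$n_retained == 0) {
    abort("ROI is totally masked by the mandible.",
          class = "hyoidtrack_totally_masked")
  }
  out
}

#' Fill totally-masked or failed gaps by cubic interpolation
#'
#' Frames whose coordinates could not be tracked (totally-masked ROI, or
#' unresolved failures with missing coordinates) are estimated from the
#' points tracked in nearby frames: a cubic interpolant (up to four tracked
#' samples on each side of the gap, `stats::spline` with the
#' Forsythe-Malcolm-Moler end conditions, which reproduce cubic paths
#' exactly) is evaluated at the gap frames and the status is set to
#' `interpolated`. Gaps touching the first or last frame cannot be
#' extrapolated and raise an error.
#'
#' @param traj trajectory tibble with possibly-missing `x`/`y`.
#' @return The trajectory with gaps filled and statuses updated.
#' @export
interpolate_masked <- function(traj) {
  traj <- tibble::as_tibble(traj)
  miss <- !is.finite(traj$x) | !is.finite(traj$y)
  if (!any(miss)) return(traj)
  if (miss[1] || miss[length(miss)]) {
    abort("Cannot interpolate a gap at the sequence boundary.")
  }
  okf <- which(!miss)
  runs <- split(which(miss), cumsum(c(1, diff(which(miss)) != 1))[seq_along(which(miss))])
  for (run in runs) {
    lo <- tail(okf[okf < min(run)], 4)
    hi <- head(okf[okf > max(run)], 4)
    idx <- c(lo, hi)
    for (col in c("x", "y")) {
      traj[[col]][run] <- spline(traj$frame[idx], traj[[col]][idx],
                                 xout = traj$frame[run], method = "fmm")$y
    }
    traj$status[run] <- "interpolated"
  }
  traj
}
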