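#' Patient-centric anatomical reference frame
#'
#' Builds the C2-C4 reference frame for one video frame: the origin is the
#' anterior-inferior border of C4, the +y axis points along C4 -> C2, and one
#' cervical unit (CU) is the pixel distance |C2 - C4|. Calibrating into this
#' frame removes global head/body motion and makes trajectories comparable
#' across subjects without radiopaque markers.
#'
#' @param C2,C4 `(x, y)` landmark positions in image pixels.
#' @return An `anatomical_frame` with elements `C2`, `C4`, `theta` (rotation
#'   angle, radians) and `cu` (cervical unit in pixels).
#' @export
anatomical_frame <- function(C2, C4) {
  if (all(C2 == C4)) abort("C2 and C4 are coincident.")
  d <- c(C2[1] - C4[1], C2[2] - C4[2])
  cu <- sqrt(sum(d^2))
  theta <- atan2(d[1], d[2])   # angle of the spine axis from image +y
  structure(list(C2 = as.numeric(C2), C4 = as.numeric(C4),
                 theta = theta, cu = cu),
            class = "anatomical_frame")
}

#' Transform image points into the patient-centric frame
#'
#' Translates by `-C4`, rotates so the C4 -> C2 direction becomes +y, points
#' the anterior direction to +x, and optionally divides by the cervical unit.
#' By contract `C4` maps to `(0, 0)` and `C2` to `(0, 1)` when `scale = TRUE`.
#'
#' @param xy numeric `(x, y)` or a two-column matrix of points.
#' @param ref an [anatomical_frame()].
#' @param scale divide by the cervical unit (coordinates in CU) or keep
#'   pixels.
#' @param anterior which image direction is the patient's anterior: `"left"`
#'   (standard left-facing lateral projection; image -x maps to +x') or
#'   `"right"`.
#' @param compat `"geometric"` (default, the Fig-style contract above) or
#'   `"printed"`, the verbatim published rotation with its pi/2 offset,
#'   retained for comparison only.
#' @return Transformed coordinates, same shape as `xy`.
#' @export
to_patient_centric <- function(xy, ref, scale = TRUE,
                               anterior = c("left", "right"),
                               compat = c("geometric", "printed")) {
  anterior <- match.arg(anterior)
  compat <- match.arg(compat)
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  dx <- m[, 1] - ref$C4[1]
  dy <- m[, 2] - ref$C4[2]
  th <- if (compat == "printed") {
    pi / 2 + atan((ref$C4[1] - ref$C2[1]) / (ref$C4[2] - ref$C2[2]))
  } else ref$theta
  if (compat == "printed") {
    xp <- cos(th) * dx + sin(th) * dy
    yp <- -sin(th) * dx + cos(th) * dy
  } else {
    xp <- cos(th) * dx - sin(th) * dy
    yp <- sin(th) * dx + cos(th) * dy
  }
  if (anterior == "left") xp <- -xp
  if (scale) { xp <- xp / ref$cu; yp <- yp / ref$cu }
  out <- cbind(x = xp, y = yp)
  if (is.matrix(xy)) out else as.numeric(out)
}

#' Produce the six processing variants of a hyoid trajectory
#'
#' From the raw hyoid, C2 and C4 tracks, computes the six standard
#' comparisons: `Raw` (pixels, image frame), `RawNC` (patient-centric,
#' unscaled pixels), `RawNCC` (patient-centric, cervical units), and their
#' smoothed counterparts `Smo`, `SmoNC`, `SmoNCC`, where smoothing applies
#' the cubic smoothing spline to the hyoid *and* to the C2/C4 landmark
#' series before the per-frame transform. The C2/C4 frame is recomputed at
#' every video frame, so slow head motion is removed sample by sample.
#'
#' @param hyoid,C2,C4 trajectory tibbles sharing one frame range.
#' @param p smoothing parameter in `[0, 1]`.
#' @param anterior see [to_patient_centric()].
#' @return A `vfss_variants` tibble: columns `variant`, `frame`, `x`, `y`,
#'   `units` (`"px"` or `"CU"`), plus `status` carried from the hyoid track.
#' @export
calibrate_variants <- function(hyoid, C2, C4, p = 0.3,
                               anterior = c("left", "right")) {
  anterior <- match.arg(anterior)
  hyoid <- tibble::as_tibble(hyoid); C2 <- tibble::as_tibble(C2)
  C4 <- tibble::as_tibble(C4)
  if (!identical(hyoid$frame, C2$frame) || !identical(hyoid$frame, C4$frame)) {
    abort("hyoid, C2 and C4 must share the same frame range.")
  }
  smo_h <- smooth_trajectory(hyoid, p)
  smo_c2 <- smooth_trajectory(C2, p)
  smo_c4 <- smooth_trajectory(C4, p)

  per_frame <- function(h, c2, c4, scale) {
    out <- matrix(NA_real_, nrow(h), 2)
    for (i in seq_len(nrow(h))) {
      ref <- anatomical_frame(c(c2$x[i], c2$y[i]), c(c4$x[i], c4$y[i]))
      out[i, ] <- to_patient_centric(c(h$x[i], h$y[i]), ref, scale = scale,
                                     anterior = anterior)
    }
    out
  }
  build <- function(label, h, c2, c4) {
    base <- tibble::tibble(variant = label, frame = h$frame,
                           status = if ("status" %in% names(h)) h$status else "ok")
    switch(label,
      Raw = , Smo = dplyr::mutate(base, x = h$x, y = h$y, units = "px"),
      RawNC = , SmoNC = {
        m <- per_frame(h, c2, c4, scale = FALSE)
        dplyr::mutate(base, x = m[, 1], y = m[, 2], units = "px")
      },
      RawNCC = , SmoNCC = {
        m <- per_frame(h, c2, c4, scale = TRUE)
        dplyr::mutate(base, x = m[, 1], y = m[, 2], units = "CU")
      })
  }
  out <- dplyr::bind_rows(
    build("Raw", hyoid, C2, C4),
    build("RawNC", hyoid, C2, C4),
    build("RawNCC", hyoid, C2, C4),
    build("Smo", smo_h, smo_c2, smo_c4),
    build("SmoNC", smo_h, smo_c2, smo_c4),
    build("SmoNCC", smo_h, smo_c2, smo_c4)
  )
  out <- dplyr::select(out, "variant", "frame", "x", "y", "units", "status")
  class(out) <- c("vfss_variants", class(out))
  out
}

#' @method autoplot vfss_variants
#' @export
autoplot.vfss_variants <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::facet_wrap(~variant, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y",
                  title = "Hyoid trajectory under the six processing variants")
}
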