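#' Extract one swallow loop from a calibrated trajectory
#'
#' A complete loop is a time window `(tA, tB)` containing one peak of `y(t)`
#' (maximal elevation) and one valley of `x(t)`, with endpoints lying as
#' close together as possible in the plane (ideally coincident, a closed
#' loop). With `tA`/`tB` given the
#' window is validated; without them an automatic suggestion searches
#' endpoint pairs bracketing the global y-peak and minimizing the endpoint
#' distance.
#'
#' @param traj trajectory-like tibble with columns `frame`, `x`, `y` (one
#'   variant of [calibrate_variants()] output, typically `SmoNCC`).
#' @param tA,tB optional 0-based endpoint frames.
#' @return A `loop_window`: `tA`, `tB`, the enclosed `data`, and a
#'   `complete` flag (FALSE, with a warning, when the window lacks the
#'   required peak/valley).
#' @export
extract_loop <- function(traj, tA = NULL, tB = NULL) {
  traj <- tibble::as_tibble(traj)
  if ("variant" %in% names(traj) && length(unique(traj$variant)) > 1) {
    abort("Pass a single variant to `extract_loop()`.")
  }
  fr <- traj$frame
  manual <- !is.null(tA) || !is.null(tB)
  if (manual) {
    if (is.null(tA) || is.null(tB)) abort("Give both `tA` and `tB` or neither.")
    if (tA >= tB) abort("`tA` must be smaller than `tB`.")
    keep <- fr >= tA & fr <= tB
    if (sum(keep) < 8) abort("Loop window must contain at least 8 samples.")
    data <- traj[keep, ]
  } else {
    sug <- suggest_loop(traj)
    tA <- sug[1]; tB <- sug[2]
    data <- traj[fr >= tA & fr <= tB, ]
  }
  has_peak <- any(interior_extrema(data$y, max))
  # the anterior excursion is an x-valley in image coordinates but an x-peak
  # in the patient-centric frame (anterior = +x); accept either extremum
  has_valley <- any(interior_extrema(data$x, min)) ||
    any(interior_extrema(data$x, max))
  complete <- has_peak && has_valley
  if (!complete) {
    warn("Loop window lacks an interior y-peak and/or x-valley.")
  }
  structure(list(tA = tA, tB = tB, data = data, complete = complete,
                 manual = manual),
            class = "loop_window")
}

interior_extrema <- function(v, which = max) {
  n <- length(v)
  if (n < 3) return(logical(0))
  i <- 2:(n - 1)
  if (identical(which, max)) v[i] > v[i - 1] & v[i] >= v[i + 1]
  else v[i] < v[i - 1] & v[i] <= v[i + 1]
}

# Automatic loop suggestion: bracket the global y-peak / x-valley pair and
# minimize the Euclidean distance between the endpoint samples.
suggest_loop <- function(traj) {
  fr <- traj$frame
  ipk <- which.max(traj$y)
  ivl <- which.max(abs(traj$x - traj$x[1]))   # largest anterior excursion
  lo_max <- min(ipk, ivl) - 1L
  hi_min <- max(ipk, ivl) + 1L
  if (lo_max < 1 || hi_min > nrow(traj)) {
    return(c(fr[1], fr[nrow(traj)]))
  }
  best <- c(fr[1], fr[nrow(traj)]); bestd <- Inf
  for (a in seq_len(lo_max)) {
    d2 <- (traj$x[hi_min:nrow(traj)] - traj$x[a])^2 +
          (traj$y[hi_min:nrow(traj)] - traj$y[a])^2
    b <- which.min(d2)
    if ((hi_min + b - 1) - a + 1 < 8) next
    if (d2[b] < bestd) { bestd <- d2[b]; best <- c(fr[a], fr[hi_min + b - 1]) }
  }
  best
}

#' Velocity amplitude of a loop
#'
#' Fits cubic smoothing splines to `x(t)` and `y(t)` over the loop and
#' evaluates the speed `v(t) = sqrt(x'(t)^2 + y'(t)^2)` on the frame grid
#' (`dt` = 1 frame). A second smoothing spline fitted to `v(t)` provides the
#' continuous first and second derivatives used by the splitting-point
#' conditions (`v' = 0`, `v'' > 0`).
#'
#' @param loop a [extract_loop()] window (or a plain tibble with `frame`,
#'   `x`, `y`).
#' @param p smoothing parameter for both spline fits.
#' @return A `velocity_profile`: tibble-backed `t`, `v`, plus derivative
#'   evaluator functions `vd1(t)`, `vd2(t)`.
#' @export
velocity_profile <- function(loop, p = 0.3) {
  data <- if (inherits(loop, "loop_window")) loop$data else tibble::as_tibble(loop)
  if (nrow(data) < 4) abort("Too few samples for the velocity spline.")
  sx <- smoothing_spline(data$frame, data$x, p)
  sy <- smoothing_spline(data$frame, data$y, p)
  tt <- data$frame
  v <- sqrt(predict(sx, tt, deriv = 1)^2 + predict(sy, tt, deriv = 1)^2)
  as_velocity_profile(tt, v, p)
}

#' @rdname velocity_profile
#' @param t,v sampled frame grid and velocity amplitude (for building a
#'   profile from precomputed speeds, e.g. synthetic test profiles).
#' @export
as_velocity_profile <- function(t, v, p = 0.3) {
  if (any(v < -1e-9)) abort("Velocity amplitude must be non-negative.")
  sv <- smoothing_spline(t, v, p)
  structure(list(t = t, v = as.numeric(v), p = p, spline = sv,
                 vd1 = function(tt) predict(sv, tt, deriv = 1),
                 vd2 = function(tt) predict(sv, tt, deriv = 2)),
            class = "velocity_profile")
}

#' Candidate splitting points of a velocity profile
#'
#' All interior local minima of `v(t)`: roots of `v'(t)` (located by
#' sign-change bracketing on a fine grid, refined by bisection on the fitted
#' spline) at which `v''(t) > 0`. Each root is reported at the nearest sample
#' frame, which must itself be a local minimum of the sampled profile (this
#' suppresses the numerically-flat ripples a spline develops on plateaus);
#' the loop endpoints are excluded.
#'
#' @param vp a [velocity_profile()].
#' @return Tibble with columns `t` (frame) and `v`.
#' @export
find_split_candidates <- function(vp) {
  t0 <- min(vp$t); t1 <- max(vp$t)
  grid <- seq(t0, t1, by = 0.1)
  d1 <- vp$vd1(grid)
  sgn <- sign(d1)
  flips <- which(sgn[-length(sgn)] < 0 & sgn[-1] >= 0)  # - to + : minimum
  if (length(flips) == 0) {
    return(tibble::tibble(t = numeric(0), v = numeric(0)))
  }
  roots <- vapply(flips, function(i) {
    a <- grid[i]; b <- grid[i + 1]
    for (k in 1:40) {
      m <- (a + b) / 2
      if (vp$vd1(m) < 0) a <- m else b <- m
    }
    (a + b) / 2
  }, numeric(1))
  keep <- vp$vd2(roots) > 0
  roots <- roots[keep]
  # snap each root to the smallest sampled value within one frame, then
  # require that sample to be a genuine local minimum of the sampled
  # profile; this drops the numerically-flat ripples a spline develops on
  # plateau stretches
  frames <- vapply(roots, function(r) {
    w <- round(r) + (-1:1)
    w <- w[w > t0 & w < t1]
    if (length(w) == 0) return(NA_real_)
    w[which.min(vp$v[match(w, vp$t)])]
  }, numeric(1))
  frames <- unique(frames[!is.na(frames)])
  ok <- vapply(frames, function(f) {
    i <- match(f, vp$t)
    if (is.na(i) || i <= 1 || i >= length(vp$t)) return(FALSE)
    le <- vp$v[i] <= vp$v[i - 1] + 1e-12 && vp$v[i] <= vp$v[i + 1] + 1e-12
    strict <- vp$v[i] < vp$v[i - 1] - 1e-12 || vp$v[i] < vp$v[i + 1] - 1e-12
    le && strict
  }, logical(1))
  frames <- frames[ok]
  tibble::tibble(t = frames, v = vp$v[match(frames, vp$t)])
}

#' Score candidate splitting points
#'
#' For candidate `t_i` with chronological neighbours `t_{i-1}`, `t_{i+1}`
#' (the loop start and end standing in at the ends), the forward splitting
#' score is `FSS = max(v(t)) - v(t_i)` over `[t_{i-1}, t_i]`, the backward
#' score `BSS` is its mirror over `[t_i, t_{i+1}]`, and `SS = FSS + BSS` —
#' the "turning intensity" of the minimum. Maxima are taken over the sampled
#' frame grid of the profile.
#'
#' @param vp a [velocity_profile()].
#' @param candidates tibble from [find_split_candidates()] (columns `t`, `v`).
#' @return The candidates with `FSS`, `BSS` and `SS` columns.
#' @export
score_split_candidates <- function(vp, candidates) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, FSS = numeric(0), BSS = numeric(0),
                         SS = numeric(0)))
  }
  candidates <- dplyr::arrange(tibble::as_tibble(candidates), .data$t)
  bounds <- c(min(vp$t), candidates$t, max(vp$t))
  vmax_in <- function(a, b) max(vp$v[vp$t >= a & vp$t <= b])
  fss <- bss <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    fss[i] <- vmax_in(bounds[i], candidates$t[i]) - candidates$v[i]
    bss[i] <- vmax_in(candidates$t[i], bounds[i + 2]) - candidates$v[i]
  }
  dplyr::mutate(candidates, FSS = fss, BSS = bss, SS = fss + bss)
}

#' Segment a loop into the four swallow phases
#'
#' Chooses the three candidates with the largest splitting scores (ties
#' broken toward the earlier frame), orders them chronologically, and labels
#' the four resulting intervals elevation, anterior movement, descending and
#' returning. With exactly three candidates all are used; with two the
#' outcome is `three_phase`; with fewer, `abnormal`. Supplying `splits`
#' overrides the automatic choice (`manual4`). Phase labels follow interval
#' order only; a warning is attached if the first phase does not actually
#' ascend.
#'
#' @param loop a [extract_loop()] window.
#' @param scored scored candidates from [score_split_candidates()]; computed
#'   from `loop` when omitted.
#' @param splits optional manual splitting frames (length 3).
#' @param p smoothing parameter used when `scored` is omitted.
#' @return A `phase_segmentation`; [tidy()] gives the per-phase table,
#'   [glance()] the outcome row.
#' @export
segment_loop <- function(loop, scored = NULL, splits = NULL, p = 0.3) {
  stopifnot(inherits(loop, "loop_window"))
  vp <- velocity_profile(loop, p)
  if (is.null(scored)) {
    scored <- score_split_candidates(vp, find_split_candidates(vp))
  }
  phase_names <- c("elevation", "anterior movement", "descending", "returning")
  if (!is.null(splits)) {
    if (length(splits) != 3) abort("Manual `splits` must have length 3.")
    sel <- sort(as.numeric(splits))
    outcome <- "manual4"
  } else if (nrow(scored) >= 3) {
    ord <- order(-scored$SS, scored$t)
    sel <- sort(scored$t[ord[1:3]])
    outcome <- "auto4"
  } else if (nrow(scored) == 2) {
    sel <- sort(scored$t)
    outcome <- "three_phase"
  } else {
    sel <- sort(scored$t)
    outcome <- "abnormal"
  }
  bounds <- c(loop$tA, sel, loop$tB)
  phases <- NULL
  if (outcome %in% c("auto4", "manual4")) labels <- phase_names
  else if (outcome == "three_phase") labels <- phase_names[1:3]
  else labels <- NULL
  if (!is.null(labels)) {
    phases <- purrr::map_dfr(seq_along(labels), function(k) {
      a <- bounds[k]; b <- bounds[k + 1]
      seg <- loop$data[loop$data$frame >= a & loop$data$frame <= b, ]
      tibble::tibble(
        phase = labels[k], t_start = a, t_end = b, duration = b - a,
        dx = seg$x[nrow(seg)] - seg$x[1], dy = seg$y[nrow(seg)] - seg$y[1],
        displacement = sqrt((seg$x[nrow(seg)] - seg$x[1])^2 +
                            (seg$y[nrow(seg)] - seg$y[1])^2))
    })
  }
  ascends <- if (!is.null(phases) && nrow(phases) > 0) phases$dy[1] > 0 else NA
  structure(list(loop = loop, candidates = scored, splits = sel,
                 outcome = outcome, phases = phases, profile = vp,
                 first_phase_ascends = ascends),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> outcome: %s; loop (%g, %g); splits: %s\n",
              x$outcome, x$loop$tA, x$loop$tB,
              paste(x$splits, collapse = ", ")))
  if (!is.null(x$phases)) print(x$phases)
  invisible(x)
}

#' @rdname segment_loop
#' @param x a `phase_segmentation`.
#' @param ... unused.
#' @method tidy phase_segmentation
#' @export
tidy.phase_segmentation <- function(x, ...) {
  x$phases %||% tibble::tibble(phase = character(0), t_start = numeric(0),
                               t_end = numeric(0), duration = numeric(0),
                               dx = numeric(0), dy = numeric(0),
                               displacement = numeric(0))
}

#' @rdname segment_loop
#' @method glance phase_segmentation
#' @export
glance.phase_segmentation <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, tA = x$loop$tA, tB = x$loop$tB,
                 n_candidates = nrow(x$candidates),
                 n_splits = length(x$splits),
                 first_phase_ascends = x$first_phase_ascends)
}

#' @method autoplot phase_segmentation
#' @export
autoplot.phase_segmentation <- function(object, ...) {
  vp <- object$profile
  df <- tibble::tibble(t = vp$t, v = vp$v)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$splits, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "frame", y = "velocity amplitude",
                  title = sprintf("Loop segmentation (%s)", object$outcome))
  if (nrow(object$candidates) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = tibble::tibble(t = object$candidates$t, v = object$candidates$v),
      colour = "black")
  }
  gg
}
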