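#' Synthetic VFSS phantom specification
#'
#' Defines a ground-truthed synthetic swallow scene: a bright compact
#' hyoid-like blob moving along a closed four-phase loop (elevation,
#' anterior movement, descending, returning), two static high-contrast
#' vertebral landmarks (C2, C4), a bright mandible band whose lower edge
#' dips across the hyoid for a contiguous occlusion window, slow global head
#' motion (translation plus rotation), and additive Gaussian noise. The
#' defaults emulate a 30 fps lateral-projection recording: 256x256 frames,
#' 90-frame sequence, swallow range of motion about 45 px on each axis (the
#' pixel scale of adult swallows in clinical recordings), a 5-frame
#' occlusion, and mild head sway. Anterior is the -x image direction
#' (left-facing projection).
#'
#' @param size image side in pixels.
#' @param n_frames sequence length.
#' @param fps frames per second.
#' @param hyoid_start hyoid `(x, y)` at the first frame. This and the other
#'   geometry defaults are defined on the 256 px reference scene and scale
#'   with `size`.
#' @param legs 4x2 matrix of per-phase displacement vectors (px); must sum
#'   to ~0 so the loop closes.
#' @param phase_durations four phase durations in frames (sum = n_frames-1);
#'   by default allocated proportionally to the 20/25/20/24 split of the
#'   90-frame sequence.
#' @param leg_ramp deceleration-ramp length (frames) at each leg end.
#' @param blob_radius,blob_intensity hyoid blob size (Gaussian sigma is
#'   radius/2) and peak intensity.
#' @param C2,C4 vertebral landmark centres; `landmark_half` is the half-side
#'   of the square landmarks.
#' @param mandible1,mandible2 points defining the mandible band's lower edge.
#' @param band_thickness,band_intensity mandible band geometry/intensity;
#'   small bright dots at the two mandible points make them identifiable.
#' @param occlusion_start,occlusion_len contiguous frames (0-based start;
#'   defaults to about a third into the sequence, during the anterior
#'   movement) during which the band fully dips over the hyoid;
#'   `occlusion_depth` is the dip in px and `occlusion_ramp` its rise/fall
#'   time in frames.
#' @param head_translation amplitudes `(x, y)` of the sinusoidal head sway
#'   in px; `head_rotation_deg` the rotation amplitude about the image
#'   centre; one period spans the sequence.
#' @param noise_sd additive Gaussian noise SD on [0, 1] intensities.
#' @param background background intensity.
#' @param seed RNG seed; every generated sequence is reproducible from
#'   (spec, seed).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 256L, n_frames = 90L, fps = 30,
                         hyoid_start = NULL, legs = NULL,
                         phase_durations = NULL,
                         leg_ramp = 3,
                         blob_radius = 6, blob_intensity = 0.75,
                         C2 = NULL, C4 = NULL,
                         landmark_half = 4,
                         mandible1 = NULL, mandible2 = NULL,
                         band_thickness = NULL, band_intensity = 0.65,
                         occlusion_start = NULL, occlusion_len = 5L,
                         occlusion_depth = NULL, occlusion_ramp = 10,
                         head_translation = c(3, 2), head_rotation_deg = 0.5,
                         noise_sd = 0.02, background = 0.08, seed = 1L) {
  # geometry defaults are defined on the 256 px reference scene and scale
  # with the image size
  sf <- size / 256
  if (is.null(hyoid_start)) hyoid_start <- c(150, 80) * sf
  if (is.null(legs)) legs <- rbind(c(-5, 40), c(-40, 5),
                                   c(5, -40), c(40, -5)) * sf
  if (is.null(C2)) C2 <- c(202, 185) * sf
  if (is.null(C4)) C4 <- c(198, 100) * sf
  if (is.null(mandible1)) mandible1 <- c(60, 155) * sf
  if (is.null(mandible2)) mandible2 <- c(170, 140) * sf
  if (is.null(band_thickness)) band_thickness <- 20 * sf
  if (is.null(occlusion_depth)) occlusion_depth <- 25 * sf
  if (is.null(phase_durations)) {
    phase_durations <- floor(c(20, 25, 20, 24) / 89 * (n_frames - 1))
    phase_durations[4] <- (n_frames - 1) - sum(phase_durations[1:3])
  }
  if (is.null(occlusion_start)) occlusion_start <- round(0.31 * n_frames)
  spec <- list(size = as.integer(size), n_frames = as.integer(n_frames),
               fps = fps, hyoid_start = hyoid_start, legs = legs,
               phase_durations = phase_durations, leg_ramp = leg_ramp,
               blob_radius = blob_radius, blob_intensity = blob_intensity,
               C2 = C2, C4 = C4, landmark_half = landmark_half,
               mandible1 = mandible1, mandible2 = mandible2,
               band_thickness = band_thickness,
               band_intensity = band_intensity,
               occlusion_start = as.integer(occlusion_start),
               occlusion_len = as.integer(occlusion_len),
               occlusion_depth = occlusion_depth,
               occlusion_ramp = occlusion_ramp,
               head_translation = head_translation,
               head_rotation_deg = head_rotation_deg,
               noise_sd = noise_sd, background = background,
               seed = as.integer(seed))
  if (max(abs(colSums(legs))) > 1e-9) abort("Phase legs must close the loop.")
  if (length(phase_durations) != 4 ||
      sum(phase_durations) != n_frames - 1) {
    abort("`phase_durations` must be four durations summing to n_frames - 1.")
  }
  if (occlusion_len > 0 &&
      (occlusion_start < 0 || occlusion_start + occlusion_len > n_frames)) {
    abort("Occlusion window must lie within the sequence.")
  }
  structure(spec, class = "phantom_spec")
}

# Normalized progress along one leg at offsets u in [0, D]: constant speed
# with cosine deceleration ramps of length r at both ends (speed 0 exactly
# at the junctions).
leg_progress <- function(u, D, r) {
  r <- min(r, D / 2)
  w <- function(s) {
    out <- rep(1, length(s))
    a <- s < r
    out[a] <- 0.5 * (1 - cos(pi * s[a] / r))
    b <- s > D - r
    out[b] <- 0.5 * (1 - cos(pi * (D - s[b]) / r))
    out
  }
  fine <- seq(0, D, by = 0.01)
  cum <- cumsum(w(fine)) * 0.01
  cum <- cum / cum[length(cum)]
  stats::approx(fine, cum, xout = u, rule = 2)$y
}

#' Ground-truth phantom trajectories
#'
#' Computes the per-frame true positions of the hyoid, C2, C4 and the two
#' mandible-edge points under the spec's loop, occlusion dip and global head
#' motion, together with the phase-junction frames.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_truth` list: `trajectories` (long tibble `point`,
#'   `frame`, `x`, `y`), `junctions` (three interior phase-boundary frames),
#'   `loop` (`tA`, `tB`) and the `spec`.
#' @export
phantom_trajectory <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_frames
  t <- seq_len(n) - 1
  cuts <- cumsum(c(0, spec$phase_durations))
  hx <- numeric(n); hy <- numeric(n)
  start <- spec$hyoid_start
  for (k in 1:4) {
    sel <- t >= cuts[k] & t <= cuts[k + 1]
    u <- t[sel] - cuts[k]
    s <- leg_progress(u, spec$phase_durations[k], spec$leg_ramp)
    hx[sel] <- start[1] + s * spec$legs[k, 1]
    hy[sel] <- start[2] + s * spec$legs[k, 2]
    start <- start + spec$legs[k, ]
  }
  # mandible dip covering the occlusion window
  dip <- rep(0, n)
  if (spec$occlusion_len > 0) {
    t0 <- spec$occlusion_start; t1 <- t0 + spec$occlusion_len - 1
    r <- spec$occlusion_ramp
    up <- t >= t0 - r & t < t0
    dip[up] <- 0.5 * (1 - cos(pi * (t[up] - (t0 - r)) / r))
    dip[t >= t0 & t <= t1] <- 1
    down <- t > t1 & t <= t1 + r
    dip[down] <- 0.5 * (1 + cos(pi * (t[down] - t1) / r))
  }
  m1 <- cbind(spec$mandible1[1] + 0 * t, spec$mandible1[2] - spec$occlusion_depth * dip)
  m2 <- cbind(spec$mandible2[1] + 0 * t, spec$mandible2[2] - spec$occlusion_depth * dip)

  # slow global head motion: rotation about the image centre plus sway
  ph <- 2 * pi * t / n
  tx <- spec$head_translation[1] * sin(ph)
  ty <- spec$head_translation[2] * sin(ph + pi / 3)
  rho <- deg2rad(spec$head_rotation_deg) * sin(ph + pi / 5)
  ctr <- (spec$size - 1) / 2
  head_xform <- function(px, py, i) {
    dx <- px - ctr; dy <- py - ctr
    c(ctr + cos(rho[i]) * dx - sin(rho[i]) * dy + tx[i],
      ctr + sin(rho[i]) * dx + cos(rho[i]) * dy + ty[i])
  }
  pts <- list(hyoid = cbind(hx, hy),
              C2 = cbind(rep(spec$C2[1], n), rep(spec$C2[2], n)),
              C4 = cbind(rep(spec$C4[1], n), rep(spec$C4[2], n)),
              mandible1 = m1, mandible2 = m2)
  traj <- purrr::map_dfr(names(pts), function(p) {
    m <- pts[[p]]
    moved <- t(vapply(seq_len(n), function(i) head_xform(m[i, 1], m[i, 2], i),
                      numeric(2)))
    tibble::tibble(point = p, frame = t, x = moved[, 1], y = moved[, 2])
  })
  structure(list(trajectories = traj,
                 junctions = cuts[2:4],
                 loop = c(tA = 0, tB = n - 1),
                 spec = spec),
            class = "phantom_truth")
}

#' Render a phantom frame sequence
#'
#' Draws, per frame: dark background, the Gaussian hyoid blob at its true
#' position, the two square vertebral landmarks, the mandible band (a bright
#' half-plane of limited thickness above the chord through the two mandible
#' points, drawn over the blob so it genuinely occludes it) with small
#' bright dots pinning the two tracked mandible points, then adds seeded
#' Gaussian noise and clips to [0, 1].
#'
#' @param truth a [phantom_trajectory()] result.
#' @return A [frame_sequence()].
#' @export
render_sequence <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  n <- spec$n_frames; sz <- spec$size
  X <- matrix(rep(0:(sz - 1), each = sz), sz, sz)   # col index = x
  Y <- matrix(rep(0:(sz - 1), sz), sz, sz)          # row index = y
  tr <- truth$trajectories
  get <- function(p, i) {
    r <- tr[tr$point == p & tr$frame == i - 1, ]
    c(r$x, r$y)
  }
  sigma <- spec$blob_radius / 2
  frames <- with_local_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      f <- matrix(spec$background, sz, sz)
      h <- get("hyoid", i)
      if (h[1] < 0 || h[1] > sz - 1 || h[2] < 0 || h[2] > sz - 1) {
        abort("Hyoid blob outside the image.")
      }
      f <- f + spec$blob_intensity *
        exp(-((X - h[1])^2 + (Y - h[2])^2) / (2 * sigma^2))
      for (p in c("C2", "C4")) {
        c0 <- get(p, i)
        rect <- abs(X - c0[1]) <= spec$landmark_half &
                abs(Y - c0[2]) <= spec$landmark_half
        f[rect] <- 0.85
      }
      m1 <- get("mandible1", i); m2 <- get("mandible2", i)
      ch <- mandible_chord(m1, m2)
      sgn <- chord_signed(ch, X, Y)
      band <- sgn >= 0 & sgn <= spec$band_thickness
      f[band] <- spec$band_intensity
      for (m in list(m1, m2)) {
        dot <- (X - m[1])^2 + (Y - m[2])^2 <= 2.5^2
        f[dot] <- 0.95
      }
      if (spec$noise_sd > 0) {
        f <- f + matrix(rnorm(sz * sz, 0, spec$noise_sd), sz, sz)
      }
      # quantize to 8-bit levels, as a fluoroscopy export would be stored;
      # PNG write/read round trips are then bit-exact
      round(pmin(pmax(f, 0), 1) * 255) / 255
    })
  })
  frame_sequence(frames, fps = spec$fps)
}

#' Simulate a complete phantom study
#'
#' Convenience wrapper: ground truth plus rendered frames.
#'
#' @param spec a [phantom_spec()].
#' @return List with `frames`, `truth` and `spec`.
#' @export
simulate_vfss <- function(spec = phantom_spec()) {
  truth <- phantom_trajectory(spec)
  list(frames = render_sequence(truth), truth = truth, spec = spec)
}

#' Synthetic velocity profiles with known minima
#'
#' A flat plateau minus `n_dips` separated smooth (Gaussian) dips of
#' randomized depth — a controlled exercise bed for the local-minimum
#' conditions and the splitting scores.
#'
#' @param n_dips number of dips (>= 0).
#' @param seed RNG seed.
#' @param spacing frames between dip centres (dips overlap negligibly).
#' @return List with `t`, `v`, and the true `minima` locations.
#' @export
velocity_testcase <- function(n_dips, seed = 1L, spacing = 15) {
  if (n_dips < 0) abort("`n_dips` must be >= 0.")
  len <- 20 + spacing * max(n_dips, 1)
  t <- 0:len
  v <- rep(5, length(t))
  centers <- numeric(0)
  if (n_dips > 0) {
    draw <- with_local_seed(seed, list(
      jitter = round(runif(n_dips, -2, 2)),
      depths = runif(n_dips, 1.5, 4)))
    centers <- 10 + spacing * (seq_len(n_dips) - 1) + draw$jitter
    for (j in seq_len(n_dips)) {
      v <- v - draw$depths[j] * exp(-(t - centers[j])^2 / (2 * 2^2))
    }
  }
  list(t = t, v = v, minima = centers)
}
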