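#' Template matching error
#'
#' Mean squared difference between the reference template's Sobel edge
#' characteristics and those of the current frame sampled under a candidate
#' pose (rotation about the template centre plus shift). When part of the ROI
#' is masked by the mandible, `clip` restricts the sum to the retained pixels
#' and the error is averaged over their count, so partially-masked and
#' unmasked frames are comparable. Transformed sample positions use bilinear
#' interpolation with reflect padding.
#'
#' @param template an [edge_template()] anchored in the reference frame.
#' @param ref_edges,cur_edges Sobel edge images ([sobel_edges()]) of the
#'   reference and current frames.
#' @param pose list or numeric vector giving `shift` `(x, y)` in pixels and
#'   `angle` in radians, e.g. `pose(1, -2, 0.01)`.
#' @param clip optional clipped region from [clip_roi()]; its `offsets`
#'   replace the full square.
#' @param cur_center centre of the ROI in the current frame (defaults to the
#'   template centre; during tracking it is the last tracked position).
#' @return Non-negative scalar matching error.
#' @export
matching_error <- function(template, ref_edges, cur_edges, pose = c(0, 0, 0),
                           clip = NULL, cur_center = template$center) {
  off <- if (is.null(clip)) template$offsets else clip$offsets
  if (nrow(off) == 0) {
    abort("All template pixels are masked.", class = "hyoidtrack_totally_masked")
  }
  exr <- bilinear_sample(ref_edges$Ex, template$center[1] + off$dx,
                         template$center[2] + off$dy)
  eyr <- bilinear_sample(ref_edges$Ey, template$center[1] + off$dx,
                         template$center[2] + off$dy)
  p <- as_pose(pose)
  .pose_ssd_batch(cur_edges$Ex, cur_edges$Ey, exr, eyr, off$dx, off$dy,
                  cur_center[1], cur_center[2],
                  matrix(c(p$shift[1], p$shift[2], p$angle), nrow = 1))[1]
}

#' Candidate pose
#'
#' @param x,y shift in pixels.
#' @param angle rotation in radians about the template centre.
#' @return A `pose` list.
#' @export
pose <- function(x = 0, y = 0, angle = 0) {
  structure(list(shift = c(x, y), angle = angle), class = "hyoid_pose")
}

as_pose <- function(p) {
  if (inherits(p, "hyoid_pose")) return(p)
  if (is.numeric(p) && length(p) == 3) return(pose(p[1], p[2], p[3]))
  if (is.list(p) && all(c("shift", "angle") %in% names(p))) {
    return(pose(p$shift[1], p$shift[2], p$angle))
  }
  abort("`pose` must be a pose(), a (x, y, angle) triple, or a shift/angle list.")
}

# Batched matching error over a matrix of poses (columns sx, sy, theta).
matching_error_batch <- function(template, ref_edges, cur_edges, poses,
                                 clip = NULL, cur_center = template$center) {
  off <- if (is.null(clip)) template$offsets else clip$offsets
  if (nrow(off) == 0) {
    abort("All template pixels are masked.", class = "hyoidtrack_totally_masked")
  }
  exr <- bilinear_sample(ref_edges$Ex, template$center[1] + off$dx,
                         template$center[2] + off$dy)
  eyr <- bilinear_sample(ref_edges$Ey, template$center[1] + off$dx,
                         template$center[2] + off$dy)
  .pose_ssd_batch(cur_edges$Ex, cur_edges$Ey, exr, eyr, off$dx, off$dy,
                  cur_center[1], cur_center[2], poses)
}

#' Find the best pose within the bounded search box
#'
#' Minimizes [matching_error()] over shifts within `±max_shift` pixels and
#' rotations within `±max_angle_deg` degrees. The default strategy evaluates
#' an exhaustive coarse grid (1 px, 0.5 degree) and refines the best cell
#' with a Nelder-Mead simplex clamped to the box; `optimizer = "ga"` instead
#' seeds the refinement with a small real-coded genetic algorithm
#' (population 50), which is deterministic for a fixed `seed`.
#'
#' @inheritParams matching_error
#' @param max_shift,max_angle_deg half-widths of the search box (defaults
#'   ±5 px and ±2.5 degrees).
#' @param optimizer `"grid"` or `"ga"`.
#' @param seed RNG seed used by the `"ga"` optimizer.
#' @return A [pose()] with an extra `error` element, never outside the box.
#' @export
optimize_pose <- function(template, ref_edges, cur_edges, clip = NULL,
                          cur_center = template$center,
                          max_shift = 5, max_angle_deg = 2.5,
                          optimizer = c("grid", "ga"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  amax <- deg2rad(max_angle_deg)
  lower <- c(-max_shift, -max_shift, -amax)
  upper <- c(max_shift, max_shift, amax)

  # sample the reference template once; all candidate poses reuse it
  off <- if (is.null(clip)) template$offsets else clip$offsets
  if (nrow(off) == 0) {
    abort("All template pixels are masked.", class = "hyoidtrack_totally_masked")
  }
  exr <- bilinear_sample(ref_edges$Ex, template$center[1] + off$dx,
                         template$center[2] + off$dy)
  eyr <- bilinear_sample(ref_edges$Ey, template$center[1] + off$dx,
                         template$center[2] + off$dy)
  eval_batch <- function(poses) {
    .pose_ssd_batch(cur_edges$Ex, cur_edges$Ey, exr, eyr, off$dx, off$dy,
                    cur_center[1], cur_center[2], poses)
  }
  obj3 <- function(par) {
    par <- pmin(pmax(par, lower), upper)
    eval_batch(matrix(par, nrow = 1))[1]
  }

  start <- if (optimizer == "grid") {
    sx <- seq(-max_shift, max_shift, by = 1)
    th <- deg2rad(seq(-max_angle_deg, max_angle_deg, by = 0.5))
    grid <- as.matrix(expand.grid(sx = sx, sy = sx, th = th))
    errs <- eval_batch(grid)
    grid[which.min(errs), ]
  } else {
    ga_minimize(obj3, lower, upper, pop = 50L, generations = 40L, seed = seed)
  }

  fit <- optim(start, obj3, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-10,
                              parscale = c(1, 1, deg2rad(0.5))))
  best <- pmin(pmax(fit$par, lower), upper)
  if (fit$value > obj3(start)) best <- pmin(pmax(start, lower), upper)
  out <- pose(best[1], best[2], best[3])
  out$error <- obj3(best)
  out
}

# Small real-coded genetic algorithm on a box: tournament selection, blend
# crossover, Gaussian mutation. Deterministic for a fixed seed.
ga_minimize <- function(fn, lower, upper, pop = 50L, generations = 40L,
                        seed = 1L) {
  d <- length(lower)
  with_local_seed(seed, {
    P <- matrix(runif(pop * d, rep(lower, each = pop), rep(upper, each = pop)),
                nrow = pop)
    P[1, ] <- (lower + upper) / 2
    fit <- apply(P, 1, fn)
    for (g in seq_len(generations)) {
      elite <- P[which.min(fit), ]
      idx1 <- pmin(sample.int(pop, pop, TRUE), sample.int(pop, pop, TRUE))
      idx2 <- pmin(sample.int(pop, pop, TRUE), sample.int(pop, pop, TRUE))
      o <- order(fit)
      a <- P[o[idx1], , drop = FALSE]
      b <- P[o[idx2], , drop = FALSE]
      w <- matrix(runif(pop * d, -0.25, 1.25), pop, d)
      Q <- w * a + (1 - w) * b
      mut <- matrix(rnorm(pop * d, 0, 0.08), pop, d) *
        matrix(rep(upper - lower, each = pop), pop, d)
      hit <- matrix(runif(pop * d) < 0.2, pop, d)
      Q[hit] <- Q[hit] + mut[hit]
      Q <- pmin(pmax(Q, matrix(rep(lower, each = pop), pop, d)),
                matrix(rep(upper, each = pop), pop, d))
      Q[1, ] <- elite
      P <- Q
      fit <- apply(P, 1, fn)
    }
    P[which.min(fit), ]
  })
}
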