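#' Cubic smoothing spline with derivative evaluators
#'
#' Fits the natural cubic smoothing spline minimizing
#' `p * sum((value - f(t))^2) + (1 - p) * integral(f''(t)^2 dt)`,
#' the convention in which `p = 1` gives the interpolating spline and `p = 0`
#' the least-squares straight line. Trajectory smoothing in practice uses
#' `p` around 0.15-0.45 (default 0.3). The fit is computed with the Reinsch
#' algorithm (Green & Silverman band formulation) at the sample points, and
#' the returned object evaluates `f`, `f'` and `f''` at arbitrary `t` inside
#' the sample range from the per-interval cubic coefficients.
#'
#' @param t strictly increasing sample locations (>= 4 unless `p = 0`).
#' @param value sample values.
#' @param p smoothing parameter in `[0, 1]`.
#' @return A `smoothing_spline` object; use [predict()] with
#'   `deriv = 0, 1, 2`, or the `$fitted` values at the knots.
#' @examples
#' t <- 0:20
#' fit <- smoothing_spline(t, sin(t / 3) + rnorm(21, 0, 0.1), p = 0.3)
#' predict(fit, 10.5, deriv = 1)
#' @export
smoothing_spline <- function(t, value, p = 0.3) {
  if (!is_scalar_number(p) || p < 0 || p > 1) abort("`p` must be in [0, 1].")
  if (length(t) != length(value)) abort("`t` and `value` lengths differ.")
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.")
  n <- length(t)
  if (p == 0) {                       # limit: least-squares straight line
    if (n < 2) abort("Need at least 2 samples.")
    fit <- lm(value ~ t)
    return(structure(list(t = t, fitted = unname(fit$fitted.values),
                          gamma = rep(0, n), p = p,
                          line = unname(coef(fit))),
                     class = "smoothing_spline"))
  }
  if (n < 4) abort("Need at least 4 samples for a smoothing spline.")
  lambda <- (1 - p) / p
  h <- diff(t)
  # Q: n x (n-2), R: (n-2) x (n-2) as in Green & Silverman (1994)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in seq_len(n - 2)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
    Q[j + 2, j] <- 1 / h[j + 1]
    R[j, j] <- (h[j] + h[j + 1]) / 3
    if (j < n - 2) {
      R[j, j + 1] <- h[j + 1] / 6
      R[j + 1, j] <- h[j + 1] / 6
    }
  }
  gamma <- solve(R + lambda * crossprod(Q), crossprod(Q, value))
  fitted <- value - lambda * (Q %*% gamma)
  structure(list(t = t, fitted = as.numeric(fitted),
                 gamma = c(0, as.numeric(gamma), 0), p = p, line = NULL),
            class = "smoothing_spline")
}

#' @rdname smoothing_spline
#' @param object a `smoothing_spline`.
#' @param newt evaluation locations (defaults to the knots).
#' @param deriv derivative order 0, 1 or 2.
#' @param ... unused.
#' @export
predict.smoothing_spline <- function(object, newt = object$t, deriv = 0, ...) {
  if (!is.null(object$line)) {
    b <- object$line
    return(switch(as.character(deriv),
                  "0" = b[1] + b[2] * newt,
                  "1" = rep(b[2], length(newt)),
                  "2" = rep(0, length(newt)),
                  abort("`deriv` must be 0, 1 or 2.")))
  }
  t <- object$t; f <- object$fitted; g <- object$gamma
  n <- length(t)
  i <- findInterval(newt, t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  h <- t[i + 1] - t[i]
  s <- newt - t[i]
  # cubic on [t_i, t_i+1]: a + b s + c s^2 + d s^3 (natural spline pieces)
  a <- f[i]
  c <- g[i] / 2
  d <- (g[i + 1] - g[i]) / (6 * h)
  b <- (f[i + 1] - f[i]) / h - h * (2 * g[i] + g[i + 1]) / 6
  switch(as.character(deriv),
         "0" = a + s * (b + s * (c + s * d)),
         "1" = b + s * (2 * c + 3 * s * d),
         "2" = 2 * c + 6 * s * d,
         abort("`deriv` must be 0, 1 or 2."))
}

#' Smooth a trajectory's coordinates
#'
#' Applies [smoothing_spline()] independently to `x(t)` and `y(t)` of a
#' trajectory table, the per-point denoising step used before calibration
#' and segmentation.
#'
#' @param traj trajectory tibble (`frame`, `x`, `y`).
#' @param p smoothing parameter in `[0, 1]`.
#' @return The trajectory with smoothed `x`, `y`.
#' @export
smooth_trajectory <- function(traj, p = 0.3) {
  traj <- tibble::as_tibble(traj)
  out <- traj
  out$x <- smoothing_spline(traj$frame, traj$x, p)$fitted
  out$y <- smoothing_spline(traj$frame, traj$y, p)$fitted
  out
}
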