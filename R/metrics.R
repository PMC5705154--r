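#' Range of motion of a trajectory
#'
#' Per-axis coordinate ranges and the 2D excursion of a swallow loop. The 2D
#' range is the trajectory diameter — the maximum pairwise Euclidean distance
#' between any two samples — which is always between `max(ROM_x, ROM_y)` and
#' `sqrt(ROM_x^2 + ROM_y^2)`.
#'
#' @param traj tibble with columns `x`, `y` (>= 2 samples).
#' @return Tibble with `rom_x`, `rom_y`, `rom_2d`.
#' @export
rom <- function(traj) {
  if (nrow(traj) < 1) abort("Empty trajectory.")
  x <- traj$x; y <- traj$y
  pts <- cbind(x, y)
  if (nrow(pts) > 400) {            # diameter is attained on the convex hull
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- if (nrow(pts) >= 2) max(stats::dist(pts)) else 0
  tibble::tibble(rom_x = max(x) - min(x), rom_y = max(y) - min(y),
                 rom_2d = d2)
}

#' Relative error between two ranges of motion
#'
#' `|ROM_auto - ROM_manual| / ROM_manual * 100`, in percent.
#'
#' @param rom_auto,rom_manual ranges of motion in the same units.
#' @return Percent relative error (vectorized).
#' @export
relative_error <- function(rom_auto, rom_manual) {
  if (any(rom_manual <= 0)) abort("`rom_manual` must be positive.")
  abs(rom_auto - rom_manual) / rom_manual * 100
}

#' Per-axis Pearson correlation between two trajectories
#'
#' @param a,b tibbles with columns `x`, `y`, equal length (>= 3).
#' @return Tibble with `r_x`, `r_y` and two-sided `p_x`, `p_y`.
#' @export
pearson_axes <- function(a, b) {
  if (nrow(a) != nrow(b)) abort("Trajectories must have equal length.")
  if (nrow(a) < 3) abort("Need at least 3 paired samples.")
  if (var(a$x) == 0 || var(b$x) == 0 || var(a$y) == 0 || var(b$y) == 0) {
    abort("Zero variance on one axis.")
  }
  tx <- cor.test(a$x, b$x)
  ty <- cor.test(a$y, b$y)
  tibble::tibble(r_x = unname(tx$estimate), p_x = tx$p.value,
                 r_y = unname(ty$estimate), p_y = ty$p.value)
}

#' Intraclass correlation for two raters
#'
#' Single-measure, absolute-agreement, two-way random-effects ICC — ICC(A,1)
#' in the McGraw & Wong taxonomy — with its F-based 95% confidence interval,
#' the standard inter-rater reliability measure for two observers rating the
#' same targets. Computed from the two-way ANOVA mean squares of the
#' subjects-by-raters table.
#'
#' @param x1,x2 coordinate series from the two raters (equal length >= 3).
#' @param conf confidence level (default 0.95).
#' @return Tibble with `icc`, `lower`, `upper`, `p_value`.
#' @export
icc_two_raters <- function(x1, x2, conf = 0.95) {
  if (length(x1) != length(x2)) abort("Series must have equal length.")
  n <- length(x1)
  if (n < 3) abort("Need at least 3 paired samples.")
  Y <- cbind(x1, x2)
  k <- 2
  row_m <- rowMeans(Y); col_m <- colMeans(Y); g <- mean(Y)
  msr <- k * sum((row_m - g)^2) / (n - 1)              # subjects
  msc <- n * sum((col_m - g)^2) / (k - 1)              # raters
  sse <- sum((Y - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse + k * (msc - mse) / n <= 0) {
    abort("Degenerate variance; ICC undefined.")
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  # McGraw & Wong (1996) interval for ICC(A,1), Satterthwaite df
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  # test of ICC = 0 via the one-way F on subjects
  f0 <- msr / mse
  p <- stats::pf(f0, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  tibble::tibble(icc = icc, lower = lower, upper = min(upper, 1),
                 p_value = p)
}

#' Summarize agreement between two tracking methods
#'
#' Aggregates per-loop agreement statistics over a set of trajectory pairs in
#' the layout of a methods-comparison table: for each variant and group, the
#' mean and SD of the per-loop ROMs for both methods on each axis and in 2D,
#' the mean and SD of the per-loop relative errors, and the per-loop Pearson
#' correlations averaged over loops.
#'
#' @param pairs long tibble with columns `loop` (loop id), `group`,
#'   `variant`, `frame`, and paired coordinates `xa`, `ya` (method A,
#'   e.g. automatic) and `xb`, `yb` (method B, e.g. manual).
#' @return Tibble with one row per `variant` x `group`.
#' @export
summarize_agreement <- function(pairs) {
  need <- c("loop", "variant", "frame", "xa", "ya", "xb", "yb")
  if (!all(need %in% names(pairs))) {
    abort(sprintf("`pairs` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (!"group" %in% names(pairs)) pairs$group <- "all"
  per_loop <- pairs |>
    dplyr::group_by(.data$group, .data$variant, .data$loop) |>
    dplyr::group_modify(function(df, key) {
      ra <- rom(tibble::tibble(x = df$xa, y = df$ya))
      rb <- rom(tibble::tibble(x = df$xb, y = df$yb))
      pr <- pearson_axes(tibble::tibble(x = df$xa, y = df$ya),
                         tibble::tibble(x = df$xb, y = df$yb))
      tibble::tibble(
        rom_x_a = ra$rom_x, rom_y_a = ra$rom_y, rom_2d_a = ra$rom_2d,
        rom_x_b = rb$rom_x, rom_y_b = rb$rom_y, rom_2d_b = rb$rom_2d,
        err_x = relative_error(ra$rom_x, rb$rom_x),
        err_y = relative_error(ra$rom_y, rb$rom_y),
        err_2d = relative_error(ra$rom_2d, rb$rom_2d),
        r_x = pr$r_x, r_y = pr$r_y)
    }) |>
    dplyr::ungroup()
  per_loop |>
    dplyr::group_by(.data$group, .data$variant) |>
    dplyr::summarise(
      n_loops = dplyr::n(),
      dplyr::across(c("rom_x_a", "rom_y_a", "rom_2d_a",
                      "rom_x_b", "rom_y_b", "rom_2d_b",
                      "err_x", "err_y", "err_2d"),
                    list(mean = mean, sd = sd)),
      r_x = mean(.data$r_x), r_y = mean(.data$r_y),
      .groups = "drop")
}
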