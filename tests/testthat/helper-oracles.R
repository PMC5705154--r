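# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain loops, written from the definitions.

# symmetric reflect of a 0-based index into [0, n-1], edge pixel repeated
oracle_reflect <- function(i, n) {
  if (n == 1) return(0)
  i <- i %% (2 * n)
  if (i < 0) i <- i + 2 * n
  if (i >= n) i <- 2 * n - 1 - i
  i
}

# bilinear interpolation of matrix m (row 1 = y 0) at continuous (x, y)
oracle_bilinear <- function(m, x, y) {
  nx <- ncol(m); ny <- nrow(m)
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  g <- function(xx, yy) m[oracle_reflect(yy, ny) + 1, oracle_reflect(xx, nx) + 1]
  (1 - ty) * ((1 - tx) * g(x0, y0) + tx * g(x0 + 1, y0)) +
    ty * ((1 - tx) * g(x0, y0 + 1) + tx * g(x0 + 1, y0 + 1))
}

# double-loop template matching error: mean over retained offsets of the
# squared Sobel-response differences under the pose
oracle_matching_error <- function(center, offsets, ref_edges, cur_edges,
                                  shift, angle, cur_center = center) {
  n <- nrow(offsets)
  acc <- 0
  for (k in seq_len(n)) {
    rx <- center[1] + offsets$dx[k]
    ry <- center[2] + offsets$dy[k]
    exr <- oracle_bilinear(ref_edges$Ex, rx, ry)
    eyr <- oracle_bilinear(ref_edges$Ey, rx, ry)
    px <- cur_center[1] + cos(angle) * offsets$dx[k] -
      sin(angle) * offsets$dy[k] + shift[1]
    py <- cur_center[2] + sin(angle) * offsets$dx[k] +
      cos(angle) * offsets$dy[k] + shift[2]
    acc <- acc + (exr - oracle_bilinear(cur_edges$Ex, px, py))^2 +
      (eyr - oracle_bilinear(cur_edges$Ey, px, py))^2
  }
  acc / n
}

# per-pixel count of ROI pixels on the clear side of the chord (pixels with
# signed distance >= 0 toward greater y are masked, ties masked)
oracle_clip_count <- function(center, side, p1, p2) {
  h <- (side - 1) / 2
  d <- p2 - p1
  nrm <- c(-d[2], d[1])
  if (nrm[2] < 0 || (nrm[2] == 0 && nrm[1] < 0)) nrm <- -nrm
  keep <- 0
  for (dx in -h:h) for (dy in -h:h) {
    s <- nrm[1] * (center[1] + dx - p1[1]) + nrm[2] * (center[2] + dy - p1[2])
    if (s < 0) keep <- keep + 1
  }
  keep
}

oracle_any_masked <- function(center, side, p1, p2) {
  oracle_clip_count(center, side, p1, p2) < side^2
}

# textbook product-moment correlation
oracle_pearson <- function(a, b) {
  n <- length(a)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# all-pairs trajectory diameter
oracle_rom2d <- function(x, y) {
  best <- 0
  for (i in seq_along(x)) for (j in seq_along(x)) {
    best <- max(best, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  }
  best
}

# Analytic smooth scene (sum of random Gaussians) and its rendering under a
# rigid pose about `center`: cur(q) = f(center + R(-theta) (q - center - s)).
# Matching the template at pose (s, theta) is then exact by construction.
make_gauss_scene <- function(seed, size = 64) {
  set.seed(seed)
  k <- 40
  px <- runif(k, 5, size - 5); py <- runif(k, 5, size - 5)
  a <- runif(k, -1, 1); s2 <- runif(k, 1.2, 3)^2
  f <- function(x, y) {
    val <- 0
    for (j in 1:k) val <- val + a[j] * exp(-((x - px[j])^2 + (y - py[j])^2) / (2 * s2[j]))
    val
  }
  render <- function(shift = c(0, 0), angle = 0, center = c(size / 2, size / 2)) {
    m <- matrix(0, size, size)
    for (yy in 0:(size - 1)) for (xx in 0:(size - 1)) {
      qx <- xx - center[1] - shift[1]
      qy <- yy - center[2] - shift[2]
      m[yy + 1, xx + 1] <- f(center[1] + cos(-angle) * qx - sin(-angle) * qy,
                             center[2] + sin(-angle) * qx + cos(-angle) * qy)
    }
    m
  }
  list(render = render)
}
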