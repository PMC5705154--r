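test_that("the anatomical frame maps C4 to the origin and C2 to (0, 1)", {
  ref <- anatomical_frame(C2 = c(0, 100), C4 = c(0, 0))
  expect_equal(ref$cu, 100)
  expect_equal(to_patient_centric(c(0, 0), ref), c(0, 0))
  expect_equal(to_patient_centric(c(0, 100), ref), c(0, 1))
  expect_equal(to_patient_centric(c(0, 50), ref, scale = FALSE), c(0, 50))

  ref2 <- anatomical_frame(C2 = c(10, 110), C4 = c(10, 10))
  expect_equal(ref2$cu, 100)
  expect_equal(to_patient_centric(c(10, 10), ref2), c(0, 0))
  # one cervical unit anterior (image left) of C4
  expect_equal(to_patient_centric(c(-90, 10), ref2), c(1, 0))
  expect_equal(to_patient_centric(c(-90, 10), ref2, anterior = "right"),
               c(-1, 0))
  expect_error(anatomical_frame(c(5, 5), c(5, 5)), "coincident")
})

test_that("random rotated configurations satisfy the geometric contract", {
  set.seed(61)
  for (rep in 1:50) {
    C4 <- runif(2, -50, 50)
    ang <- runif(1, -pi, pi)
    len <- runif(1, 20, 200)
    C2 <- C4 + len * c(sin(ang), cos(ang))
    ref <- anatomical_frame(C2, C4)
    expect_equal(to_patient_centric(C2, ref), c(0, 1), tolerance = 1e-9)
    expect_equal(to_patient_centric(C4, ref), c(0, 0), tolerance = 1e-9)
    m <- to_patient_centric(rbind(C2, C4), ref)
    expect_equal(sqrt(sum((m[1, ] - m[2, ])^2)), 1, tolerance = 1e-9)
  }
})

test_that("the verbatim printed rotation is available behind the compat flag", {
  C2 <- c(12, 140); C4 <- c(18, 40)
  ref <- anatomical_frame(C2, C4)
  pt <- c(-20, 90)
  th <- pi / 2 + atan((C4[1] - C2[1]) / (C4[2] - C2[2]))
  cu <- sqrt(sum((C2 - C4)^2))
  want <- c(cos(th) * (pt[1] - C4[1]) + sin(th) * (pt[2] - C4[2]),
            -sin(th) * (pt[1] - C4[1]) + cos(th) * (pt[2] - C4[2])) / cu
  want[1] <- -want[1]                       # anterior flip applies throughout
  got <- to_patient_centric(pt, ref, compat = "printed")
  expect_equal(got, want, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    to_patient_centric(C2, ref, compat = "printed"), c(0, 1))))
})

test_that("a hyoid resting on C4 calibrates to the origin in all NCC frames", {
  fr <- 0:19
  hyoid <- tibble::tibble(frame = fr, x = 30, y = 40)
  C2 <- tibble::tibble(frame = fr, x = 32, y = 120)
  C4 <- tibble::tibble(frame = fr, x = 30, y = 40)
  v <- calibrate_variants(hyoid, C2, C4, p = 0.5)
  ncc <- v[v$variant == "RawNCC", ]
  expect_equal(max(abs(ncc$x)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ncc$y)), 0, tolerance = 1e-9)
})

test_that("p = 1 makes the smoothed variants equal the raw ones at the knots", {
  set.seed(62)
  fr <- 0:29
  hyoid <- tibble::tibble(frame = fr, x = 100 + cumsum(rnorm(30)),
                          y = 80 + cumsum(rnorm(30)))
  C2 <- tibble::tibble(frame = fr, x = 150 + rnorm(30, 0, 0.1),
                       y = 180 + rnorm(30, 0, 0.1))
  C4 <- tibble::tibble(frame = fr, x = 148 + rnorm(30, 0, 0.1),
                       y = 100 + rnorm(30, 0, 0.1))
  v <- calibrate_variants(hyoid, C2, C4, p = 1)
  expect_equal(v$x[v$variant == "Smo"], v$x[v$variant == "Raw"],
               tolerance = 1e-7)
  expect_equal(v$y[v$variant == "SmoNCC"], v$y[v$variant == "RawNCC"],
               tolerance = 1e-7)
  expect_error(calibrate_variants(hyoid[1:10, ], C2, C4), "frame range")
})

test_that("NCC variants are invariant under global rigid motion and scaling", {
  set.seed(63)
  fr <- 0:39
  hyoid <- tibble::tibble(frame = fr, x = 120 - fr * 0.8 + rnorm(40, 0, 0.5),
                          y = 90 + sin(fr / 6) * 20)
  C2 <- tibble::tibble(frame = fr, x = 190 + rnorm(40, 0, 0.2),
                       y = 200 + rnorm(40, 0, 0.2))
  C4 <- tibble::tibble(frame = fr, x = 186 + rnorm(40, 0, 0.2),
                       y = 110 + rnorm(40, 0, 0.2))
  base <- calibrate_variants(hyoid, C2, C4, p = 0.3)

  ang <- 0.4; sc <- 1.7; off <- c(33, -12)
  rigid <- function(df) {
    tibble::tibble(frame = df$frame,
                   x = sc * (cos(ang) * df$x - sin(ang) * df$y) + off[1],
                   y = sc * (sin(ang) * df$x + cos(ang) * df$y) + off[2])
  }
  moved <- calibrate_variants(rigid(hyoid), rigid(C2), rigid(C4), p = 0.3)
  for (vn in c("RawNCC", "SmoNCC")) {
    expect_equal(moved$x[moved$variant == vn], base$x[base$variant == vn],
                 tolerance = 1e-9)
    expect_equal(moved$y[moved$variant == vn], base$y[base$variant == vn],
                 tolerance = 1e-9)
  }
  # the pixel-frame variants do change
  expect_false(isTRUE(all.equal(moved$x[moved$variant == "Raw"],
                                base$x[base$variant == "Raw"])))
})

test_that("pure head motion leaves the calibrated trajectory constant", {
  spec <- phantom_spec(legs = matrix(0, 4, 2), occlusion_len = 0)
  tr <- phantom_trajectory(spec)$trajectories
  pick <- function(p) tr[tr$point == p, c("frame", "x", "y")]
  v <- calibrate_variants(pick("hyoid"), pick("C2"), pick("C4"))
  raw <- v[v$variant == "Raw", ]
  ncc <- v[v$variant == "RawNCC", ]
  expect_gt(sd(raw$x) + sd(raw$y), 1)        # head sway moves the raw track
  expect_lt(sd(ncc$x) + sd(ncc$y), 1e-12)    # calibration removes it
})

test_that("smoothing does not inflate the range of motion", {
  fix <- clean_tracked()
  tr <- tidy(fix$run)
  pick <- function(p) tr[tr$point == p, c("frame", "x", "y")]
  v <- calibrate_variants(pick("hyoid"), pick("C2"), pick("C4"), p = 0.3)
  rr <- rom(v[v$variant == "Raw", ])
  rs <- rom(v[v$variant == "Smo", ])
  expect_lte(rs$rom_x, rr$rom_x + 2)
  expect_lte(rs$rom_y, rr$rom_y + 2)
})
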