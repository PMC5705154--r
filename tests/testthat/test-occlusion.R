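test_that("the mandible chord is the line through the two tracked points", {
  ch <- mandible_chord(c(0, 10), c(20, 10))        # horizontal line y = 10
  expect_false(roi_is_masked(c(10, -2), 9, ch))    # ROI far below
  expect_true(roi_is_masked(c(10, 10), 9, ch))     # chord through the centre
  ch2 <- mandible_chord(c(0, 0), c(10, 10))        # line y = x
  expect_true(roi_is_masked(c(0, 5), 5, ch2))
  expect_false(roi_is_masked(c(8, 0), 5, ch2))
  expect_error(mandible_chord(c(3, 3), c(3, 3)), "coincident")
})

test_that("roi_is_masked agrees with a per-pixel side test on random cases", {
  set.seed(41)
  for (rep in 1:100) {
    center <- runif(2, -10, 30)
    p1 <- runif(2, -20, 40); p2 <- runif(2, -20, 40)
    if (all(p1 == p2)) next
    ch <- mandible_chord(p1, p2)
    expect_identical(roi_is_masked(center, 9, ch),
                     oracle_any_masked(center, 9, p1, p2))
  }
})

test_that("clip_roi keeps exactly the pixels below the chord", {
  ch_above <- mandible_chord(c(-10, 100), c(60, 100))
  full <- clip_roi(c(20, 20), 41, ch_above)        # no crossing: full square
  expect_equal(full$n_retained, 41^2)
  # horizontal chord through the exact centre: the boundary row is masked
  ch_mid <- mandible_chord(c(-10, 20), c(60, 20))
  half <- clip_roi(c(20, 20), 41, ch_mid)
  expect_equal(half$n_retained, 41 * 20)
  expect_true(all(half$offsets$dy < 0))
})

test_that("clip counts match brute force for 200 random chords", {
  set.seed(42)
  for (rep in 1:200) {
    center <- runif(2, 0, 60)
    p1 <- runif(2, -30, 90); p2 <- runif(2, -30, 90)
    want <- oracle_clip_count(center, 21, p1, p2)
    ch <- mandible_chord(p1, p2)
    if (want == 0) {
      expect_error(clip_roi(center, 21, ch), class = "hyoidtrack_totally_masked")
    } else {
      got <- clip_roi(center, 21, ch)
      expect_equal(got$n_retained, want)
      expect_equal(got$n_retained + got$n_masked, 21^2)
    }
  }
})

test_that("a clip that removes nothing leaves the matching error unchanged", {
  set.seed(43)
  f <- matrix(runif(900), 30, 30); g <- matrix(runif(900), 30, 30)
  ef <- sobel_edges(f); eg <- sobel_edges(g)
  tm <- edge_template(c(14, 14), 11)
  ch <- mandible_chord(c(-10, 200), c(40, 200))    # far above the ROI
  clip <- clip_roi(c(14, 14), 11, ch)
  expect_equal(clip$n_retained, 121)
  p <- pose(2, -1, 0.01)
  expect_identical(matching_error(tm, ef, eg, p),
                   matching_error(tm, ef, eg, p, clip = clip))
})

test_that("interior gaps are filled by cubic interpolation", {
  lin <- tibble::tibble(frame = 0:4, x = c(10, NA, 12, 13, 14),
                        y = c(10, NA, 12, 13, 14),
                        status = c("ok", "masked", "ok", "ok", "ok"))
  out <- interpolate_masked(lin)
  expect_equal(out$x[2], 11)
  expect_equal(out$y[2], 11)
  expect_identical(out$status[2], "interpolated")

  # a cubic path with a 3-frame interior gap is recovered exactly
  t <- 0:14
  cub <- tibble::tibble(frame = t, x = 0.2 * t^3 - t^2 + 3, y = t^2 - 0.5 * t,
                        status = "ok")
  cub$x[7:9] <- NA; cub$y[7:9] <- NA; cub$status[7:9] <- "masked"
  filled <- interpolate_masked(cub)
  expect_equal(filled$x[7:9], 0.2 * (6:8)^3 - (6:8)^2 + 3, tolerance = 1e-6)
  expect_equal(filled$y[7:9], (6:8)^2 - 0.5 * (6:8), tolerance = 1e-6)

  # boundary gaps cannot be extrapolated
  bad <- tibble::tibble(frame = 0:3, x = c(NA, 1, 2, 3), y = c(NA, 1, 2, 3),
                        status = c("masked", "ok", "ok", "ok"))
  expect_error(interpolate_masked(bad), "boundary")
})

test_that("tracking survives a partial mandible occlusion without losing the track", {
  fix <- default_tracked()
  spec <- fix$sim$spec
  err <- tracking_errors(fix$run, fix$sim$truth)
  hy <- err[err$point == "hyoid", ]
  occ <- hy$frame >= spec$occlusion_start &
    hy$frame < spec$occlusion_start + spec$occlusion_len
  expect_true(all(hy$err[occ] < 2))
  # masked frames are flagged around the dip
  expect_gt(sum(hy$status == "masked"), 0)
  # the track rejoins ground truth after the occlusion
  post <- hy$frame > spec$occlusion_start + spec$occlusion_len + spec$occlusion_ramp
  expect_lt(sqrt(mean(hy$err[post]^2)), 1.5)
  expect_equal(sum(hy$status == "failed"), 0)
})

test_that("a totally-masked window is interpolated and the track recovers", {
  # near-stationary hyoid close under the mandible; the band dips far enough
  # to bury the target point completely for a contiguous window
  spec <- phantom_spec(n_frames = 60, hyoid_start = c(120, 125),
                       legs = matrix(0, 4, 2), occlusion_depth = 35,
                       occlusion_ramp = 14, seed = 5L)
  sim <- simulate_vfss(spec)
  seeds <- sim$truth$trajectories[sim$truth$trajectories$frame == 0,
                                  c("point", "x", "y")]
  run <- track_sequence(sim$frames, seeds)
  hy <- tidy(run)
  hy <- hy[hy$point == "hyoid", ]
  expect_gt(sum(hy$status == "interpolated"), 0)
  expect_true(all(is.finite(hy$x)))
  err <- tracking_errors(run, sim$truth)
  hye <- err[err$point == "hyoid", ]
  post <- hye$frame > spec$occlusion_start + spec$occlusion_len + spec$occlusion_ramp
  expect_lt(sqrt(mean(hye$err[post]^2)), 1.5)
  # interpolated frames stay close to the hidden true positions
  interp <- hye$status == "interpolated"
  expect_lt(max(hye$err[interp]), 3)
})
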