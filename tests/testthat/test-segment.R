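circle_loop <- function(n = 40, r = 1, closed = TRUE) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  if (!closed) th <- th[-(n + 1)]
  tibble::tibble(frame = seq_along(th) - 1, x = 1.5 + r * cos(th - pi / 2),
                 y = 2 + r * sin(th - pi / 2))
}

test_that("a closed loop is extracted whole with coincident endpoints", {
  traj <- circle_loop()
  loop <- extract_loop(traj)
  expect_equal(loop$tA, 0)
  expect_equal(loop$tB, 40)
  d <- loop$data
  ends <- sqrt((d$x[1] - d$x[nrow(d)])^2 + (d$y[1] - d$y[nrow(d)])^2)
  expect_equal(ends, 0, tolerance = 1e-12)
  expect_true(loop$complete)
})

test_that("auto extraction picks the loop holding the larger y-peak", {
  small <- circle_loop(30, r = 0.5, closed = FALSE)
  big <- circle_loop(30, r = 1.2, closed = FALSE)
  big$frame <- big$frame + 30
  two <- dplyr::bind_rows(small, big)
  two$frame <- seq_len(nrow(two)) - 1
  loop <- extract_loop(two)
  peak <- two$frame[which.max(two$y)]
  expect_true(loop$tA <= peak && peak <= loop$tB)
  expect_gte(loop$tA, 30)            # the window sits on the second loop
})

test_that("manual windows are validated", {
  traj <- circle_loop()
  expect_error(extract_loop(traj, tA = 10, tB = 10), "smaller")
  expect_error(extract_loop(traj, tA = 10, tB = NULL), "both")
  expect_error(extract_loop(traj, tA = 0, tB = 4), "8 samples")
  expect_warning(extract_loop(tibble::tibble(frame = 0:9, x = 0:9, y = 0:9),
                              tA = 0, tB = 9), "lacks")
  win <- extract_loop(traj, tA = 0, tB = 40)
  expect_true(win$manual)
})

test_that("the velocity amplitude matches closed forms", {
  still <- tibble::tibble(frame = 0:19, x = 3, y = 4)
  vp0 <- velocity_profile(still)
  expect_equal(max(abs(vp0$v)), 0, tolerance = 1e-9)

  uniform <- tibble::tibble(frame = 0:19, x = 3 * (0:19), y = 4 * (0:19))
  vp1 <- velocity_profile(uniform)
  expect_equal(vp1$v, rep(5, 20), tolerance = 1e-8)

  # circle of radius r at omega rad/frame: speed = omega * r
  om <- 0.06; r <- 40
  t <- 0:260
  circ <- tibble::tibble(frame = t, x = r * cos(om * t), y = r * sin(om * t))
  vp2 <- velocity_profile(circ, p = 0.9)
  inner <- vp2$v[20:240]
  expect_lt(max(abs(inner - om * r)) / (om * r), 0.01)
})

test_that("find_split_candidates locates exactly the constructed dips", {
  one <- velocity_testcase(1, seed = 2)
  vp <- as_velocity_profile(one$t, one$v, p = 0.9)
  cand <- find_split_candidates(vp)
  expect_equal(nrow(cand), 1)
  expect_lte(abs(cand$t - one$minima), 1)

  four <- velocity_testcase(4, seed = 3)
  c4 <- find_split_candidates(as_velocity_profile(four$t, four$v, p = 0.9))
  expect_equal(nrow(c4), 4)
  expect_true(all(abs(sort(c4$t) - sort(four$minima)) <= 1))

  none <- velocity_testcase(0)
  expect_equal(nrow(find_split_candidates(
    as_velocity_profile(none$t, none$v, p = 0.9))), 0)

  mono <- as_velocity_profile(0:30, seq(1, 4, length.out = 31), p = 0.9)
  expect_equal(nrow(find_split_candidates(mono)), 0)
})

test_that("splitting scores reproduce the worked piecewise-linear profile", {
  # anchors v = [5, 1, 4, 2, 6] at t = 0, 10, 20, 30, 40, sampled densely
  anchors_t <- c(0, 10, 20, 30, 40)
  anchors_v <- c(5, 1, 4, 2, 6)
  t <- 0:40
  v <- approx(anchors_t, anchors_v, xout = t)$y
  vp <- as_velocity_profile(t, v, p = 1)
  scored <- score_split_candidates(vp, tibble::tibble(t = c(10, 30),
                                                      v = c(1, 2)))
  expect_equal(scored$FSS, c(4, 2))
  expect_equal(scored$BSS, c(3, 4))
  expect_equal(scored$SS, c(7, 6))
})

test_that("scores vanish on flat flanks and are never negative", {
  flat <- as_velocity_profile(0:20, rep(2, 21), p = 1)
  sc <- score_split_candidates(flat, tibble::tibble(t = 10, v = 2))
  expect_equal(sc$FSS, 0)
  expect_equal(sc$BSS, 0)
  set.seed(71)
  for (rep in 1:20) {
    n <- 60
    v <- abs(cumsum(rnorm(n))) + 0.1
    vp <- as_velocity_profile(0:(n - 1), v, p = 0.5)
    cand <- find_split_candidates(vp)
    sc <- score_split_candidates(vp, cand)
    expect_true(all(sc$FSS >= -1e-12))
    expect_true(all(sc$BSS >= -1e-12))
    expect_equal(sc$SS, sc$FSS + sc$BSS)
  }
})

test_that("top-3 selection matches a brute-force ranking of the scores", {
  six <- velocity_testcase(6, seed = 13)
  vp <- as_velocity_profile(six$t, six$v, p = 0.9)
  cand <- find_split_candidates(vp)
  expect_equal(nrow(cand), 6)
  scored <- score_split_candidates(vp, cand)
  loop <- suppressWarnings(
    extract_loop(tibble::tibble(frame = six$t,
                                x = -cumsum(six$v), y = cumsum(six$v)),
                 tA = min(six$t), tB = max(six$t)))
  seg <- suppressWarnings(segment_loop(loop, scored = scored))
  want <- sort(scored$t[order(-scored$SS, scored$t)][1:3])
  expect_equal(seg$splits, want)
  expect_equal(seg$outcome, "auto4")
  expect_true(all(seg$splits %in% cand$t))
})

test_that("segmentation outcomes track the number of candidates", {
  mk_loop <- function() {
    extract_loop(circle_loop(), tA = 0, tB = 40)
  }
  scored3 <- tibble::tibble(t = c(10, 20, 30), v = 1,
                            FSS = c(3, 2, 1), BSS = c(1, 1, 1),
                            SS = c(4, 3, 2))
  seg3 <- segment_loop(mk_loop(), scored = scored3)
  expect_equal(seg3$outcome, "auto4")
  expect_equal(seg3$splits, c(10, 20, 30))
  expect_equal(tidy(seg3)$phase,
               c("elevation", "anterior movement", "descending", "returning"))

  seg2 <- segment_loop(mk_loop(), scored = scored3[1:2, ])
  expect_equal(seg2$outcome, "three_phase")
  expect_equal(nrow(tidy(seg2)), 3)

  seg1 <- segment_loop(mk_loop(), scored = scored3[1, ])
  expect_equal(seg1$outcome, "abnormal")
  expect_equal(nrow(tidy(seg1)), 0)

  segm <- segment_loop(mk_loop(), splits = c(8, 19, 33))
  expect_equal(segm$outcome, "manual4")
  expect_error(segment_loop(mk_loop(), splits = c(10, 20)), "length 3")
})

test_that("equal scores break ties toward the earlier frame", {
  loop <- extract_loop(circle_loop(), tA = 0, tB = 40)
  scored <- tibble::tibble(t = c(5, 12, 21, 33), v = 1,
                           FSS = c(2, 2, 2, 2), BSS = c(1, 1, 1, 1),
                           SS = c(3, 3, 3, 3))
  seg <- segment_loop(loop, scored = scored)
  expect_equal(seg$splits, c(5, 12, 21))
})

test_that("segmentation is invariant to uniform scaling of the trajectory", {
  tr <- phantom_trajectory(phantom_spec())$trajectories
  pick <- function(p) tr[tr$point == p, c("frame", "x", "y")]
  v <- calibrate_variants(pick("hyoid"), pick("C2"), pick("C4"))
  cu_traj <- v[v$variant == "SmoNCC", c("frame", "x", "y")]
  px_traj <- dplyr::mutate(cu_traj, x = x * 83.7, y = y * 83.7)
  seg_cu <- segment_loop(extract_loop(cu_traj))
  seg_px <- segment_loop(extract_loop(px_traj))
  expect_equal(seg_cu$splits, seg_px$splits)
  expect_equal(order(-seg_cu$candidates$SS), order(-seg_px$candidates$SS))
})

test_that("a four-phase phantom is split at its constructed junctions", {
  truth <- phantom_trajectory(phantom_spec())
  tr <- truth$trajectories
  pick <- function(p) tr[tr$point == p, c("frame", "x", "y")]
  v <- calibrate_variants(pick("hyoid"), pick("C2"), pick("C4"))
  seg <- segment_loop(extract_loop(v[v$variant == "SmoNCC", ]))
  expect_equal(seg$outcome, "auto4")
  expect_length(seg$splits, 3)
  expect_true(all(abs(sort(seg$splits) - sort(truth$junctions)) <= 2))
  g <- glance(seg)
  expect_true(g$first_phase_ascends)
})
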