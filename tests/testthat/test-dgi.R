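test_that("velocity products match the worked one-interval examples", {
  # left +10 deg/s, right -10 deg/s over a 1 s interval
  r <- binocular_recording(c(0, 1), c(0, 10), c(0, -10))
  expect_identical(compute_series(r)$dv, -100)
  # left +10 deg/s, right +20 deg/s: conjugate, positive product
  r <- binocular_recording(c(0, 1), c(0, 10), c(0, 20))
  expect_identical(compute_series(r)$dv, 200)
})

test_that("disparity and velocity product follow their definitions exactly", {
  set.seed(3)
  t <- cumsum(runif(30, 0.004, 0.006))
  xl <- rnorm(30); xr <- rnorm(30)
  s <- compute_series(binocular_recording(t, xl, xr))
  expect_identical(s$d, xl - xr)
  dt <- diff(t)
  expect_identical(s$dv, (diff(xl) / dt) * (diff(xr) / dt))
  # identical eyes: zero disparity, non-negative product
  s0 <- compute_series(binocular_recording(t, xl, xl))
  expect_true(all(s0$d == 0))
  expect_true(all(s0$dv >= 0))
})

test_that("candidate runs are the maximal negative stretches", {
  s <- compute_series(rec_from_dv_signs(c(1, 1, 1)))
  expect_identical(nrow(find_candidate_segments(s)), 0L)

  s <- compute_series(rec_from_dv_signs(c(1, -1, -1, 1, -1)))
  runs <- find_candidate_segments(s)
  expect_equal(unname(runs), rbind(c(2L, 3L), c(5L, 5L)))

  # negative run touching the recording boundary is kept
  s <- compute_series(rec_from_dv_signs(c(-1, -1)))
  expect_equal(unname(find_candidate_segments(s)), rbind(c(1L, 2L)))

  # a zero product terminates runs
  s <- compute_series(rec_from_dv_signs(c(-1, 0, -1)))
  expect_equal(unname(find_candidate_segments(s)), rbind(c(1L, 1L), c(3L, 3L)))
})

test_that("runs are split at disparity sign changes, zeros as boundaries", {
  # constant positive shrinking disparity: one converging sub-segment
  rec <- binocular_recording(0:3, c(0.02, 0.01, 0.005, 0.005) + 1:4,
                             1:4)
  s <- compute_series(rec)
  segs <- split_by_direction(rbind(c(1L, 2L)), s)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$direction, "converging")
  expect_identical(segs$n_samples, 3L)

  # disparity flips sign inside the run: split into two
  rec <- binocular_recording(0:2, c(0.01, 0.004, -0.01), c(0, 0.01, 0.02))
  s <- compute_series(rec)
  expect_true(all(s$dv < 0))
  segs <- split_by_direction(rbind(c(1L, 2L)), s)
  expect_identical(segs$start_index, c(1L, 2L))
  expect_identical(segs$end_index, c(1L, 3L))

  # exact zero disparity at an interior sample acts as a cut point
  rec <- binocular_recording(0:2, c(0.01, 0, -0.01) + c(0, 0.01, 0.02),
                             c(0, 0.01, 0.02))
  s <- compute_series(rec)
  segs <- split_by_direction(rbind(c(1L, 2L)), s)
  expect_identical(segs$start_index, c(1L, 3L))
  expect_identical(segs$n_samples, c(1L, 1L))
})

test_that("the dwell filter keeps >=3-sample segments, boundary included", {
  segs <- data.frame(n_samples = c(2L, 3L, 4L), id = 1:3)
  expect_identical(filter_segments(segs)$id, 2:3)
  expect_identical(filter_segments(segs, min_samples = 1L)$id, 1:3)
})

test_that("a conjugate recording has DGI zero for any constant offset", {
  t <- (0:999) / 200
  x <- cumsum(rnorm(1000, 0, 0.01))
  for (c0 in c(0, 1.5)) {
    res <- compute_dgi(binocular_recording(t, x + c0, x, rate = 200))
    expect_identical(res$count, 0L)
    expect_identical(res$dgi, 0)
    expect_identical(res$mean_duration_ms, 0)
    expect_identical(res$mean_amplitude_deg, 0)
  }
})

test_that("well-separated injected events are counted exactly and scale with time", {
  rec <- flat_rec(n = 6000, rate = 200, d0 = 0.2)
  starts <- seq(0.5, 27.5, length.out = 12)
  for (k in seq_along(starts))
    rec <- inject_event(rec, starts[k], 0.003, 5,
                        if (k %% 2) "diverging" else "converging")
  res <- compute_dgi(rec)
  expect_identical(res$count, 12L)
  expect_equal(res$dgi, 12 / res$total_duration_s)
  expect_equal(res$dgi, 0.4, tolerance = 1e-3)

  # doubling all timestamps: count invariant, durations double, rate halves
  rec2 <- binocular_recording(rec$t * 2, rec$xl, rec$xr, rate = rec$rate / 2)
  res2 <- compute_dgi(rec2)
  expect_identical(res2$count, res$count)
  expect_equal(res2$dgi, res$dgi / 2)
  expect_equal(res2$mean_duration_ms, res$mean_duration_ms * 2)
})

test_that("segment lists equal the brute-force oracle on random walks", {
  for (seed in 1:60) {
    rec <- random_walk_rec(seed, n = sample(10:200, 1))
    s <- compute_series(rec)
    got <- filter_segments(split_by_direction(find_candidate_segments(s), s))
    want <- oracle_segments(rec)
    expect_identical(got$start_index, want$start_index)
    expect_identical(got$end_index, want$end_index)
  }
})

test_that("detector is invariant to eye swap, mirroring and gain", {
  for (seed in 101:110) {
    rec <- smooth_walk_rec(seed, n = 150)
    res <- compute_dgi(rec)
    cols <- c("start_index", "end_index", "duration_ms", "amplitude_deg",
              "direction")

    # swap eyes: d negated, dv unchanged
    swap <- binocular_recording(rec$t, rec$xr, rec$xl, rate = rec$rate)
    expect_identical(compute_dgi(swap)$segments[cols], res$segments[cols])

    # mirror both position signals
    mir <- binocular_recording(rec$t, -rec$xl, -rec$xr, rate = rec$rate)
    expect_identical(compute_dgi(mir)$segments[cols], res$segments[cols])

    # gain a > 0: amplitudes scale by a, everything else unchanged
    a <- 2.7
    sc <- binocular_recording(rec$t, a * rec$xl, a * rec$xr, rate = rec$rate)
    res_sc <- compute_dgi(sc)
    expect_identical(res_sc$segments$start_index, res$segments$start_index)
    expect_identical(res_sc$segments$direction, res$segments$direction)
    expect_equal(res_sc$segments$amplitude_deg, a * res$segments$amplitude_deg)
    expect_identical(res_sc$dgi, res$dgi)
  }
})

test_that("amplitude histograms pool per group over shared bins", {
  rec <- flat_rec(n = 2000, d0 = 0.2)
  rec1 <- inject_event(rec, 2, 0.004, 4, "diverging")
  r1 <- compute_dgi(rec1)
  h <- amplitude_histogram(list(r1), bins = 10)
  expect_identical(sum(h$counts), 1L)

  # two identical cohorts give identical histograms
  r1b <- r1; r1b$label <- "dyslexic"
  h2 <- amplitude_histogram(list(r1, r1b), bins = 10)
  expect_identical(h2$counts["unknown", ], h2$counts["dyslexic", ])

  # no segments anywhere -> explicit empty signal
  r0 <- compute_dgi(flat_rec(n = 500))
  expect_error(amplitude_histogram(list(r0)), "no segments")
})
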