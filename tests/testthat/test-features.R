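test_that("conjugate position is the exact two-eye average", {
  set.seed(11)
  t <- (0:199) / 200
  x <- cumsum(rnorm(200, 0, 0.05))
  d <- runif(200, -0.3, 0.3)
  cs <- conjugate(binocular_recording(t, x + d, x - d, rate = 200))
  expect_equal(cs$pos, x, tolerance = 1e-12)    # disparity cancels
  cs2 <- conjugate(binocular_recording(t, x, x, rate = 200))
  expect_identical(cs2$pos, x)
  # constant position: velocity numerically zero
  cs3 <- conjugate(binocular_recording(t, rep(2, 200), rep(2, 200), rate = 200))
  expect_lt(max(abs(cs3$vel)), 1e-9)
  expect_error(conjugate(binocular_recording(c(0, 1), 1:2, 1:2)), "too short")
})

test_that("a single minimum-jerk saccade is detected with faithful kinematics", {
  amp <- 10; dur <- 0.0536                      # peak 1.875*10/0.0536 ~ 350 deg/s
  rec <- minjerk_rec(amp = amp, dur = dur, pad = 1)
  ev <- detect_saccades(conjugate(rec))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$peak_velocity, 1.875 * amp / dur, tolerance = 0.02)
  # onset/offset bracket the true movement interval
  expect_lte(ev$onset_s, 1 + dur)
  expect_gte(ev$offset_s, 1)
  # threshold truncation can only shrink the measured amplitude
  expect_gte(ev$amplitude, 0.95 * amp)
  expect_lte(ev$amplitude, amp * (1 + 1e-9))
  # average velocity is amplitude over duration by definition
  expect_identical(ev$average_velocity, ev$amplitude / (ev$duration / 1000))
})

test_that("fixation noise below the floor yields no events", {
  set.seed(5)
  t <- (0:999) / 200
  x <- 0.05 * sin(2 * pi * t)                  # peak velocity ~ 0.3 deg/s
  ev <- detect_saccades(conjugate(binocular_recording(t, x, x, rate = 200)))
  expect_identical(nrow(ev), 0L)
})

test_that("two separated saccades give two events and the fixation interval", {
  dt <- 1 / 200; dur <- 0.05
  t <- seq(0, 2.5, by = dt)
  tau1 <- pmin(pmax((t - 1) / dur, 0), 1)
  tau2 <- pmin(pmax((t - 1.55) / dur, 0), 1)   # onset 500 ms after offset 1
  pos <- 10 * (10 * tau1^3 - 15 * tau1^4 + 6 * tau1^5) +
         8 * (10 * tau2^3 - 15 * tau2^4 + 6 * tau2^5)
  rec <- binocular_recording(t, pos, pos, rate = 200)
  ev <- event_features(detect_saccades(conjugate(rec)), rec)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$fixation_duration[1], 500, tolerance = 0.03)
  expect_true(is.na(ev$fixation_duration[2]))  # last saccade: no successor
})

test_that("post-saccadic disconjugate drift integrates to its injected value", {
  dt <- 1 / 200; dur <- 0.05; t_end <- 1 + dur
  t <- seq(0, 2, by = dt)
  tau <- pmin(pmax((t - 1) / dur, 0), 1)
  pos <- 10 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  # antisymmetric 0.5 deg/s disconjugate ramp for 400 ms from saccade end
  ramp <- 0.5 * pmin(pmax(t - t_end, 0), 0.4)
  rec <- binocular_recording(t, pos + ramp / 2, pos - ramp / 2, rate = 200)
  ev <- event_features(detect_saccades(conjugate(rec)), rec)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$drift1, 0.04, tolerance = 0.1)    # 0.5 deg/s x 80 ms
  expect_equal(ev$drift2, 0.08, tolerance = 0.1)    # 0.5 deg/s x 160 ms
  expect_equal(ev$total_amplitude, ev$amplitude + abs(ev$drift2))

  # perfectly conjugate recording: drift exactly zero
  rec0 <- binocular_recording(t, pos, pos, rate = 200)
  ev0 <- event_features(detect_saccades(conjugate(rec0)), rec0)
  expect_identical(ev0$drift1, 0)
  expect_identical(ev0$drift2, 0)
  expect_identical(ev0$total_amplitude, ev0$amplitude)
})

test_that("drift windows past the end of the recording are aberrant", {
  dt <- 1 / 200; dur <- 0.05
  t <- seq(0, 1.1, by = dt)                    # offset + 160 ms beyond end
  tau <- pmin(pmax((t - 1) / dur, 0), 1)
  pos <- 10 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  rec <- binocular_recording(t, pos, pos, rate = 200)
  ev <- event_features(detect_saccades(conjugate(rec)), rec)
  expect_identical(nrow(ev), 1L)
  expect_true(is.na(ev$drift1))
  expect_true(is.na(ev$drift2))
  expect_true(is.na(ev$total_amplitude))
})

test_that("summaries aggregate mean/sd/cv/n with aberrances zeroed", {
  ev <- empty_events_df()
  ev[1:2, ] <- NA
  ev$amplitude <- c(8, 12); ev$duration <- c(40, 60)
  ev$peak_velocity <- c(300, 400); ev$average_velocity <- c(200, 200)
  ev$drift1 <- c(0.05, NA); ev$drift2 <- c(0.1, 0.1)
  ev$total_amplitude <- c(8.1, 12.1); ev$fixation_duration <- c(250, NA)
  s <- summarize_events(ev)
  expect_identical(unname(s["amplitude_mean"]), 10)
  expect_identical(unname(s["amplitude_sd"]), 2)     # population convention
  expect_identical(unname(s["amplitude_cv"]), 20)
  expect_identical(unname(s["amplitude_n"]), 2)
  # aberrant drift contributes 0, n unchanged
  expect_identical(unname(s["drift1_mean"]), 0.025)
  expect_identical(unname(s["drift1_n"]), 2)
  expect_length(unclass(s), 32L)

  # single event: sd and cv are zero
  s1 <- summarize_events(ev[1, ])
  expect_identical(unname(s1["amplitude_sd"]), 0)
  expect_identical(unname(s1["amplitude_cv"]), 0)
  expect_identical(unname(s1["amplitude_n"]), 1)

  # order invariance
  expect_identical(summarize_events(ev[2:1, ]), s)

  # no events: all-zero summary
  s0 <- summarize_events(empty_events_df(0))
  expect_true(all(unclass(s0) == 0))
})

test_that("extract_features is deterministic and counts trials", {
  sim <- simulate_recording(control_profile(), sim_config(duration = 10),
                            subject_seed = 21, event_rate = 5)
  f1 <- extract_features(sim$recording)
  f2 <- extract_features(sim$recording)
  expect_identical(f1, f2)
  expect_gt(unname(f1["amplitude_n"]), 3)      # free viewing has saccades

  # pure fixation: zero-event summary
  t <- (0:999) / 200
  rec <- binocular_recording(t, rep(0.3, 1000), rep(0.1, 1000), rate = 200)
  expect_true(all(unclass(extract_features(rec)) == 0))
})
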