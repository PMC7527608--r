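# Five-case detector: case assignment, latency, peak velocity, error and
# reflexive rules, aggregation.

test_that("a clean pro-saccade trial is case 1 with correct latency and sign", {
  w <- make_saccade_window(latency_ms = 200, amplitude = -8,
                           peak_velocity = 350, side = "right")
  r <- classify_and_detect(w)
  expect_equal(r$case_id, 1L)
  expect_false(r$is_error)
  expect_false(r$has_reflexive_onset)
  expect_lt(abs(r$latency_ms - 200), 1000 / 120 + 1e-9)
  expect_lt(r$peak_velocity, 0) # rightward => negative
  expect_lt(abs(abs(r$peak_velocity) - 350) / 350, 0.05)

  # same trace, side label flipped -> direction error
  r2 <- classify_and_detect(w, expected_side = "left")
  expect_true(r2$is_error)
})

test_that("anti-saccade sign inversion and reflexive cases work", {
  # anti trial, stimulus right => correct movement is leftward (positive)
  w <- make_saccade_window(latency_ms = 300, amplitude = 8,
                           peak_velocity = 320, task = "anti",
                           side = "right")
  r <- classify_and_detect(w)
  expect_equal(r$case_id, 1L)
  expect_false(r$is_error)

  # reflexive excursion toward the stimulus, then corrective saccade
  win <- c(125, 750)
  t <- seq(win[1], win[2], by = 1000 / 120)
  refl <- saccade_waveform(-4, 220, t, onset_ms = 180,
                           clip_preserve = "amplitude")
  corr <- saccade_waveform(12, 330, t, onset_ms = 330,
                           clip_preserve = "amplitude")
  wr <- make_window(t, refl$values + corr$values, task = "anti",
                    side = "right")
  rr <- classify_and_detect(wr)
  expect_equal(rr$case_id, 3L)
  expect_false(rr$is_error)
  expect_true(rr$has_reflexive_onset)
  # latency measured on the corrective movement, not the reflexive one
  expect_gt(rr$latency_ms, 300)
  expect_lt(abs(rr$latency_ms - 330), 2 * 1000 / 120)

  # add a return peak after the corrective saccade -> case 4
  ret <- saccade_waveform(-8, 330, t, onset_ms = 560,
                          clip_preserve = "amplitude")
  wr4 <- make_window(t, refl$values + corr$values + ret$values,
                     task = "anti", side = "right")
  expect_equal(classify_and_detect(wr4)$case_id, 4L)
})

test_that("a return movement inside the window gives case 2", {
  t <- seq(100, 500, by = 1000 / 120)
  out <- saccade_waveform(-8, 350, t, onset_ms = 180)
  back <- saccade_waveform(8, 350, t, onset_ms = 380,
                           clip_preserve = "amplitude")
  w <- make_window(t, out$values + back$values, side = "right")
  r <- classify_and_detect(w)
  expect_equal(r$case_id, 2L)
  expect_false(r$is_error)
  expect_lt(abs(r$latency_ms - 180), 1000 / 120 + 1e-9)
})

test_that("no-movement windows are case 5 for both signal kinds", {
  t <- seq(100, 500, by = 1000 / 120)
  # gaze range 0.2 deg < 1 deg
  w <- make_window(t, 0.1 * sin(t / 30))
  r <- classify_and_detect(w)
  expect_equal(r$case_id, 5L)
  expect_true(is.na(r$latency_ms))
  expect_true(is.na(r$peak_velocity))
  expect_true(r$is_error)

  # pupil-position range 0.0005 < 0.001
  wp <- make_window(t, 0.5 + 0.00025 * sin(t / 30),
                    signal_kind = "pupil_pos_x")
  expect_equal(classify_and_detect(wp)$case_id, 5L)

  # perfectly flat trace (degenerate normalization)
  wf <- make_window(t, rep(2, length(t)))
  expect_equal(classify_and_detect(wf)$case_id, 5L)
})

test_that("reflexive flag implements the 3-degree excursion rule", {
  t <- seq(125, 750, by = 1000 / 120)
  # monotone correct-direction anti saccade (right stimulus -> leftward)
  ok <- make_window(t, saccade_waveform(8, 300, t, 300)$values,
                    task = "anti", side = "right")
  expect_false(reflexive_flag(ok))

  # 4-degree wrong-direction excursion then correction -> flagged
  refl4 <- saccade_waveform(-4, 220, t, 200, clip_preserve = "amplitude")
  corr <- saccade_waveform(12, 300, t, 400, clip_preserve = "amplitude")
  expect_true(reflexive_flag(make_window(t, refl4$values + corr$values,
                                         task = "anti", side = "right")))

  # 2-degree excursion stays below threshold
  refl2 <- saccade_waveform(-2, 150, t, 200, clip_preserve = "amplitude")
  corr2 <- saccade_waveform(10, 300, t, 400, clip_preserve = "amplitude")
  expect_false(reflexive_flag(make_window(t, refl2$values + corr2$values,
                                          task = "anti", side = "right")))
})

test_that("pupil-position variant matches the gaze classification", {
  lat <- 240
  for (side in c("right", "left")) {
    amp <- if (side == "right") -8 else 8
    wg <- make_saccade_window(latency_ms = lat, amplitude = amp,
                              peak_velocity = 340, side = side)
    # same movement in pupil-position units (inverted x convention)
    wp <- make_saccade_window(latency_ms = lat, amplitude = amp,
                              peak_velocity = 340, side = side)
    wp$signal_kind <- "pupil_pos_x"
    wp$values <- 0.5 - wp$values / 110
    rg <- classify_and_detect(wg)
    rp <- classify_and_detect(wp)
    expect_equal(rp$is_error, rg$is_error)
    expect_equal(rp$case_id, rg$case_id)
    expect_lt(abs(rp$latency_ms - rg$latency_ms), 2 * 1000 / 120)
    expect_true(is.na(rp$peak_velocity)) # no degree conversion
  }
})

test_that("error rate is exact arithmetic over analyzed trials", {
  base <- data.frame(
    trial_index = 0:119, task = "pro", side = "right", eye = "left",
    signal_kind = "gaze_deg", case_id = 1L, latency_ms = 200,
    peak_velocity = -300, is_error = FALSE, has_reflexive_onset = FALSE,
    unanalyzable = FALSE
  )
  expect_equal(error_rate(base), 0)
  wrong <- base
  wrong$is_error[c(3, 50, 100)] <- TRUE
  expect_equal(error_rate(wrong), 2.5)
  # unanalyzable trials leave the denominator
  wrong$unanalyzable[30:49] <- TRUE
  expect_equal(error_rate(wrong), 100 * 3 / 100)
})

test_that("aggregation pools eyes and accounts for every trial", {
  one_eye <- data.frame(
    trial_index = 0:9, task = "pro", side = "right", eye = "left",
    signal_kind = "gaze_deg", case_id = 1L,
    latency_ms = seq(200, 290, by = 10),
    peak_velocity = -seq(300, 390, by = 10),
    is_error = FALSE, has_reflexive_onset = FALSE, unanalyzable = FALSE
  )
  other <- one_eye
  other$eye <- "right"
  m <- aggregate_metrics(rbind(one_eye, other))
  both <- m[m$eye == "both", ]
  left <- m[m$eye == "left", ]
  # pooling identical per-eye results leaves the means unchanged
  expect_equal(both$latency_mean_ms, left$latency_mean_ms)
  expect_equal(both$peak_velocity_mean_dps, left$peak_velocity_mean_dps)
  expect_equal(both$n_trials, 20L)
  expect_equal(left$n_analyzed + left$n_unanalyzable, left$n_trials)
})

test_that("case assignment matches the exhaustive decision oracle", {
  set.seed(2024)
  cfg <- detection_config()
  n_checked <- 0
  for (i in 1:300) {
    n <- sample(12:60, 1)
    t <- 100 + cumsum(runif(n, 6, 11))
    # random smooth-ish signal with occasional large swings
    x <- cumsum(rnorm(n, 0, sample(c(0.05, 0.5, 2), 1)))
    w <- add_velocity(make_window(t, x,
                                  side = sample(c("right", "left"), 1)))
    r <- classify_and_detect(w, config = cfg)
    v <- w$velocity
    vmax <- max(abs(v))
    vnorm <- if (vmax > 0) v / vmax else v
    o <- oracle_case_assignment(
      vnorm, expected_velocity_sign(w$task, w$side, w$signal_kind),
      w$values, cfg$no_move_deg
    )
    expect_equal(r$case_id, o$case_id, info = paste("iter", i))
    if (o$case_id != 5L) {
      expect_equal(r$is_error, o$is_error, info = paste("iter", i))
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 300)
})

test_that("noise-free parameter recovery: latency and direction", {
  # latencies uniform over the search window; direction never misread
  set.seed(7)
  lats <- runif(300, 150, 400)
  errs <- numeric(0)
  for (lat in lats) {
    side <- sample(c("right", "left"), 1)
    amp <- if (side == "right") -8 else 8
    w <- make_saccade_window(latency_ms = lat, amplitude = amp,
                             peak_velocity = runif(1, 150, 500),
                             side = side)
    r <- classify_and_detect(w)
    expect_false(r$is_error)
    errs <- c(errs, abs(r$latency_ms - lat))
  }
  expect_lt(mean(errs), 1000 / 120) # within one sample interval
})

test_that("noise-free peak-velocity recovery is within 5 % per trial", {
  set.seed(8)
  for (i in 1:100) {
    vp <- runif(1, 130, 415) # durations inside the 30-100 ms band
    w <- make_saccade_window(latency_ms = runif(1, 150, 350),
                             amplitude = -8, peak_velocity = vp,
                             side = "right")
    r <- classify_and_detect(w)
    expect_lt(abs(abs(r$peak_velocity) - vp) / vp, 0.05)
  }
})

test_that("detection is deterministic and respects config invariants", {
  w <- make_saccade_window(200, -8, 350, side = "right")
  expect_identical(classify_and_detect(w), classify_and_detect(w))
  expect_error(detection_config(onset_threshold_norm = 0.6),
               "onset_threshold_norm")
  expect_error(detection_config(peak_threshold_norm = 1.2),
               "onset_threshold_norm")
})
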