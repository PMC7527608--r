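# Simulator: waveform kinematics, determinism, inversion, end-to-end
# agreement with the detector.

test_that("raised-cosine waveform has the stated closed-form kinematics", {
  # duration = (pi/2) * A / V
  w <- saccade_waveform(8, 357.9, t_grid_ms = seq(0, 60, by = 1))
  expect_equal(w$duration_ms, 1000 * pi * 8 / (2 * 357.9),
               tolerance = 1e-12)
  expect_equal(w$duration_ms, 35.1, tolerance = 1e-3)
  expect_false(w$clipped)

  # numeric maximum derivative on a 1 kHz grid matches V within 1 %
  t <- seq(-5, 60, by = 1)
  x <- saccade_waveform(8, 357.9, t, onset_ms = 0)$values
  vmax <- max(diff(x) / 1e-3)
  expect_lt(abs(vmax - 357.9) / 357.9, 0.01)
  expect_equal(x[length(x)], 8, tolerance = 1e-12) # full displacement

  # zero amplitude -> flat trace
  expect_equal(saccade_waveform(0, 300, t)$values, numeric(length(t)))
})

test_that("duration clipping preserves the requested quantity", {
  # too fast for 8 deg: duration clips to 30 ms
  wv <- saccade_waveform(8, 600, seq(0, 50, 1),
                         clip_preserve = "peak_velocity")
  expect_true(wv$clipped)
  expect_equal(wv$duration_ms, 30)
  expect_equal(wv$peak_velocity_dps, 600)
  expect_equal(wv$amplitude_deg, 2 * 0.030 * 600 / pi, tolerance = 1e-12)

  wa <- saccade_waveform(8, 600, seq(0, 50, 1),
                         clip_preserve = "amplitude")
  expect_true(wa$clipped)
  expect_equal(wa$amplitude_deg, 8)
  expect_equal(wa$peak_velocity_dps, pi * 8 / (2 * 0.030),
               tolerance = 1e-12)
})

test_that("simulation is seed-deterministic", {
  cfg <- sim_config(warmup_duration_s = 0)
  a <- simulate_trials(4, "pro", cfg, seed = 11)
  b <- simulate_trials(4, "pro", cfg, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_trials(4, "pro", cfg, seed = 12)
  expect_false(identical(a$samples, c$samples))
})

test_that("gaze direction inverts exactly and pupil position is consistent", {
  cfg <- sim_config(warmup_duration_s = 0, angle_noise_sd_deg = 0,
                    spike_prob = 0, invalid_prob = 0)
  ses <- simulate_trials(2, "pro", cfg, seed = 5)
  s <- ses$samples
  ang <- gaze_angle_deg(s$left_gaze_dir_x, s$left_gaze_dir_z)
  # the same intended angle drives the pupil-position channel
  expect_equal(ang, -(s$left_pupil_pos_x - 0.5) * cfg$fov_deg,
               tolerance = 1e-9)
  expect_true(max(abs(ang)) > 7) # saccades actually reach the target
  expect_true(all(abs(s$left_gaze_dir_x) <= 1 & abs(s$left_gaze_dir_z) <= 1))
})

test_that("ground truth covers every trial; events exclude practice", {
  prot <- generate_session_protocol(seed = 3)
  short <- prot[prot$phase %in% c("pro_practice", "pro_1"), ]
  attr(short, "phases") <- session_phase_table()[1:2, ]
  class(short) <- c("session_protocol", "data.frame")
  cfg <- sim_config(warmup_duration_s = 0)
  ses <- simulate_session(short, cfg, seed = 3)
  expect_equal(nrow(ses$ground_truth), 70L)
  expect_equal(nrow(ses$events), 60L)
  expect_true(all(!ses$events$trial_index %in%
                    short$trial_index[short$is_practice]))
})

test_that("degenerate and stress settings behave as specified", {
  # all samples invalid -> cleaning reports no valid samples
  cfg <- sim_config(warmup_duration_s = 0, invalid_prob = 1)
  ses <- simulate_trials(2, "pro", cfg, seed = 2)
  expect_error(clean_samples(ses$samples, "left"), "no valid samples")

  # reflexive probability 1 on anti: every trial trips the 3-degree rule
  cfgr <- sim_config(warmup_duration_s = 0, invalid_prob = 0,
                     spike_prob = 0,
                     reflexive_prob = c(pro = 0, anti = 1),
                     error_prob = c(pro = 0, anti = 0))
  sesr <- simulate_trials(20, "anti", cfgr, seed = 6)
  ana <- analyze_session(sesr$samples, sesr$events,
                         signal_kinds = "gaze_deg")
  r <- ana$trial_results
  r <- r[!r$unanalyzable, ]
  expect_true(all(r$has_reflexive_onset))
  expect_true(all(sesr$ground_truth$is_reflexive))
})

test_that("warm-up, duplicates and frame drops shape the sampling clock", {
  cfg <- sim_config(warmup_duration_s = 10, duplicate_prob = 0.01,
                    drop_prob = 0.01, lead_in_s = 12)
  ses <- simulate_trials(8, "pro", cfg, seed = 21)
  s <- ses$samples
  host_d <- diff(s$host_time_ms)
  n_warm <- sum(cumsum(host_d) < 10000)
  # warm-up intervals all above the 8.33 ms frame period
  expect_true(mean(host_d[1:n_warm] > 8.34) > 0.95)

  rep <- timing_report(s)
  # about 1 % duplicate pairs, all carrying the bug signature
  expect_gt(nrow(rep$duplicates), nrow(s) * 0.003)
  expect_lt(nrow(rep$duplicates), nrow(s) * 0.03)
  expect_true(all(rep$duplicates$type == "timestamp_bug"))
  # dropped frames produce 16/17 ms device intervals
  cls <- rep$interval_class_counts
  expect_gt(cls[["16"]] + cls[["17"]], 0)

  # clean mode: no dropped frames -> no 16/17 ms class
  cfg0 <- sim_config(warmup_duration_s = 5, lead_in_s = 6)
  ses0 <- simulate_trials(4, "pro", cfg0, seed = 22)
  cls0 <- classify_intervals(diff(ses0$samples$device_timestamp_ms))
  expect_equal(unname(cls0[["16"]] + cls0[["17"]]), 0L)
  expect_equal(unname(cls0[["other"]]), 0L)
})

test_that("noise-free end-to-end run recovers the ground truth", {
  cfg <- sim_config(warmup_duration_s = 0, angle_noise_sd_deg = 0,
                    spike_prob = 0, invalid_prob = 0,
                    error_prob = c(pro = 0, anti = 0),
                    reflexive_prob = c(pro = 0, anti = 0))
  ses <- simulate_trials(30, "pro", cfg, seed = 13)
  ana <- analyze_session(ses$samples, ses$events,
                         signal_kinds = "gaze_deg")
  r <- ana$trial_results[ana$trial_results$eye == "left", ]
  m <- merge(r, ses$ground_truth, by = "trial_index")
  expect_true(all(!m$is_error.x))
  expect_true(all(sign(m$peak_velocity) == m$direction))
  expect_lt(mean(abs(m$latency_ms.x - m$latency_ms.y)), 1000 / 120)
})

test_that("simulated sessions round-trip through the log files", {
  cfg <- sim_config(warmup_duration_s = 0)
  ses <- simulate_trials(4, "anti", cfg, seed = 14)
  dir <- tempfile()
  paths <- write_sim_session(ses, dir)
  expect_true(all(file.exists(paths)))
  back <- read_samples(paths[["samples"]])
  expect_equal(nrow(back), nrow(ses$samples))
  expect_equal(back$host_time_ms, ses$samples$host_time_ms)
  ev <- read_events(paths[["events"]])
  expect_equal(nrow(ev), 4L)
  cfg_back <- read_run_config(paths[["config"]])
  expect_equal(as.numeric(cfg_back$latency_mean_ms.pro), 220.40)
})
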