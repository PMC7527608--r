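# Preprocessing: angle conversion, cleaning, despiking, segmentation,
# velocity.

test_that("gaze angle conversion matches the arctangent closed form", {
  expect_equal(gaze_angle_deg(0, 1), 0)
  expect_equal(gaze_angle_deg(tan(8 * pi / 180), 1), 8, tolerance = 1e-12)
  # odd function in the x component
  set.seed(1)
  x <- runif(50, -0.9, 0.9)
  z <- runif(50, 0.1, 1)
  expect_equal(gaze_angle_deg(-x, z), -gaze_angle_deg(x, z),
               tolerance = 1e-12)
  expect_warning(out <- gaze_angle_deg(c(0.5, 0.2), c(1, 0)), "gd_z = 0")
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("cleaning keeps exactly the validity-31 rows, unaltered", {
  s <- make_valid_samples(100)
  expect_identical(clean_samples(s, "left")[, names(s)], s)

  s$left_validity[42] <- 15L
  cl <- clean_samples(s, "left")
  expect_equal(nrow(cl), 99L)
  expect_equal(attr(cl, "retention"), 0.99)
  expect_identical(cl$left_gaze_dir_x, s$left_gaze_dir_x[-42])

  # asymmetric per-eye dropouts give different stream lengths
  s$right_validity[c(5, 6, 7)] <- 3L
  expect_equal(nrow(clean_samples(s, "right")), 97L)
  expect_equal(nrow(clean_samples(s, "left")), 99L)

  s_all_bad <- make_valid_samples(10)
  s_all_bad$left_validity <- 0L
  expect_error(clean_samples(s_all_bad, "left"), "no valid samples")
})

test_that("despike removes isolated spikes and preserves structure", {
  expect_equal(despike(rep(2.5, 50)), rep(2.5, 50))

  x <- rep(1, 60)
  x[30] <- 50
  expect_equal(despike(x), rep(1, 60))

  # step function: preserved within order/2 samples of the edge
  step <- c(rep(0, 40), rep(10, 40))
  f <- despike(step)
  expect_true(all(f[1:35] == 0))
  expect_true(all(f[46:80] == 10))
  expect_error(despike(rep(1, 5)), "exceed")
})

test_that("despike equals the brute-force window-median oracle", {
  set.seed(99)
  for (rep_i in 1:20) {
    n <- sample(20:200, 1)
    x <- rnorm(n) + ifelse(runif(n) < 0.05, 30, 0)
    expect_equal(despike(x), oracle_running_median(x, 10L),
                 tolerance = 1e-12)
  }
  # odd order too
  x <- rnorm(80)
  expect_equal(despike(x, order = 11L), oracle_running_median(x, 11L))
})

test_that("trial segmentation uses the task windows with closed bounds", {
  dt <- 1000 / 120
  stream <- data.frame(host_time_ms = seq(0, 2000, by = dt), value = 0)
  ev <- trial_events(0L, "pro", "right", onset_host_time_ms = 500)

  w <- segment_trial(stream, ev[1, ])
  expect_s3_class(w, "trial_window")
  expect_false(w$unanalyzable)
  # 400 ms / 8.33 ms -> about 48 samples
  expect_true(length(w$times_ms) %in% 47:49)
  expect_true(all(w$times_ms >= 100 & w$times_ms <= 500))

  # anti window spans 625 ms
  eva <- trial_events(0L, "anti", "left", onset_host_time_ms = 500)
  wa <- segment_trial(stream, eva[1, ])
  expect_equal(wa$window_ms, c(125, 750))
  expect_true(max(wa$times_ms) - min(wa$times_ms) <= 625)
  expect_true(length(wa$times_ms) %in% 74:76)

  # a sample exactly on a bound is included
  stream2 <- data.frame(host_time_ms = c(599.9, 600, 750, 1000, 1000.1),
                        value = 1:5)
  ev2 <- trial_events(0L, "pro", "right", onset_host_time_ms = 500)
  w2 <- segment_trial(stream2, ev2[1, ],
                      config = detection_config(min_samples = 3))
  expect_equal(w2$times_ms, c(100, 250, 500))

  # truncated window at stream end -> unanalyzable
  ev3 <- trial_events(0L, "pro", "right", onset_host_time_ms = 1950)
  expect_true(segment_trial(stream, ev3[1, ])$unanalyzable)
})

test_that("velocity is a time-aware difference with correct sign", {
  # linear ramp: -8 deg over 40 ms -> -200 deg/s (rightward, negative)
  t <- seq(100, 500, by = 1000 / 120)
  x <- numeric(length(t))
  ramp <- t >= 200 & t <= 240
  x[ramp] <- -8 * (t[ramp] - 200) / 40
  x[t > 240] <- -8
  w <- add_velocity(make_window(t, x))
  interior <- which(t > 205 & t < 230)
  expect_equal(w$velocity[interior], rep(-200, length(interior)),
               tolerance = 1e-9)

  # constant signal -> zero velocity
  wc <- add_velocity(make_window(t, rep(3, length(t))))
  expect_true(all(wc$velocity == 0))

  # affine signal under jittered timestamps -> constant slope to 1e-9
  set.seed(4)
  tj <- sort(100 + cumsum(runif(60, 4, 12)))
  wj <- add_velocity(make_window(tj, 2 + 0.05 * tj))
  expect_equal(wj$velocity, rep(50, length(tj)), tolerance = 1e-9)

  # repeated timestamps are dropped before differencing
  td <- c(100, 110, 110, 120, 130)
  wd <- add_velocity(make_window(td, c(0, 1, 99, 2, 3)))
  expect_equal(length(wd$times_ms), 4L)
  expect_true(all(is.finite(wd$velocity)))
})
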