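# Synthetic gaze-trace simulator: main-sequence saccade kinematics on a
# 120 Hz binocular sampling clock with warm-up, frame drops, duplicate
# reads, spike noise, validity dropouts, and pupillometry.

#' Simulation configuration
#'
#' The stated world of the simulator. Defaults put the generator in the
#' regime observed for healthy young adults on a 120 Hz head-mounted
#' tracker: pro-saccade latency 220.40 +/- 43.16 ms and peak velocity
#' 357.90 +/- 111.99 deg/s, anti-saccade latency 343.35 +/- 76.42 ms and
#' peak velocity 318.79 +/- 116.69 deg/s, direction-error rates 0.24 %
#' (pro) and 0.66 % (anti), reflexive-response rates 1.4 % (pro) and
#' 13.2 % (anti), pupil diameter about 4.3 mm, saccade durations within
#' the physiological 30-100 ms band, and a sampling warm-up of roughly
#' 25 s during which the recording loop runs slower than the tracker.
#'
#' @param latency_mean_ms,latency_sd_ms named numeric (`pro`, `anti`):
#'   per-trial latency distribution, truncated to the task's search
#'   window.
#' @param peak_velocity_mean_dps,peak_velocity_sd_dps named numeric:
#'   per-trial peak-velocity distribution, truncated positive.
#' @param saccade_amplitude_deg target eccentricity of the main saccade
#'   (default 8).
#' @param saccade_duration_bounds_ms physiological duration band
#'   (default 30-100 ms); derived durations are clipped into it.
#' @param reflexive_prob named numeric: probability of a reflexive
#'   wrong-direction excursion before the corrective saccade.
#' @param reflexive_amplitude_deg amplitude of the reflexive excursion
#'   (default 4, comfortably over the 3-degree flag threshold).
#' @param reflexive_gap_ms pause between the reflexive excursion's end
#'   and the corrective saccade (default 80 ms).
#' @param reflexive_peak_velocity_dps peak velocity of the reflexive
#'   excursion (default 250 deg/s).
#' @param error_prob named numeric: probability that the primary saccade
#'   goes to the wrong side.
#' @param angle_noise_sd_deg per-sample Gaussian angle noise (default
#'   0.05 deg, the order of the tracker's spatial resolution).
#' @param spike_prob,spike_amplitude_deg isolated spike-noise rate and
#'   size.
#' @param invalid_prob probability that a sample's eye data is invalid
#'   (validity mask below 31).
#' @param pupil_mean_mm,pupil_sd_mm between-subject pupil-diameter
#'   distribution; `pupil_jitter_sd_mm` is the within-subject per-sample
#'   jitter.
#' @param nominal_hz tracker sampling frequency (default 120).
#' @param warmup_duration_s duration of the slow warm-up regime of the
#'   recording loop (default 25 s; the observed range is about 19-28 s).
#' @param warmup_interval_ms_range loop-iteration time during warm-up
#'   (default 9-12 ms, always above the 8.33 ms frame period).
#' @param stable_loop_ms_range loop-iteration time after warm-up
#'   (default 3.9-8.5 ms).
#' @param drop_prob probability the tracker drops a frame (doubled
#'   device-clock intervals of 16-17 ms).
#' @param duplicate_prob probability a frame is re-served with an
#'   unchanged device timestamp and frame sequence but fresh pupil data
#'   (the timestamp-bug signature).
#' @param lead_in_s non-assessment period before the first trial;
#'   defaults to `warmup_duration_s + 35` so trials never overlap the
#'   warm-up or queue-drain regimes (2 s when warm-up is disabled).
#' @param return_saccade_delay_ms delay after stimulus offset before the
#'   gaze returns to center.
#' @param fov_deg horizontal field of view used to back-compute
#'   normalized pupil position from gaze angle (default 110).
#' @param epoch_ms Unix-epoch offset added to all host times.
#' @param seed default seed used by [simulate_session()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(latency_mean_ms = c(pro = 220.40, anti = 343.35),
                       latency_sd_ms = c(pro = 43.16, anti = 76.42),
                       peak_velocity_mean_dps = c(pro = 357.90,
                                                  anti = 318.79),
                       peak_velocity_sd_dps = c(pro = 111.99,
                                                anti = 116.69),
                       saccade_amplitude_deg = 8,
                       saccade_duration_bounds_ms = c(30, 100),
                       reflexive_prob = c(pro = 0.014, anti = 0.132),
                       reflexive_amplitude_deg = 4,
                       reflexive_gap_ms = 80,
                       reflexive_peak_velocity_dps = 250,
                       error_prob = c(pro = 0.0024, anti = 0.0066),
                       angle_noise_sd_deg = 0.05,
                       spike_prob = 0.001,
                       spike_amplitude_deg = 50,
                       invalid_prob = 0.01,
                       pupil_mean_mm = 4.3,
                       pupil_sd_mm = 1.0,
                       pupil_jitter_sd_mm = 0.05,
                       nominal_hz = 120,
                       warmup_duration_s = 25,
                       warmup_interval_ms_range = c(9, 12),
                       stable_loop_ms_range = c(3.9, 8.5),
                       drop_prob = 0,
                       duplicate_prob = 0,
                       lead_in_s = NULL,
                       return_saccade_delay_ms = 150,
                       fov_deg = 110,
                       epoch_ms = 1.6e12,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("reflexive_prob", "error_prob")) {
    v <- cfg[[p]]
    if (!all(TASKS %in% names(v)) || any(v < 0) || any(v > 1)) {
      stop_bad("'%s' must be named (pro, anti) with values in [0, 1]", p)
    }
  }
  for (p in c("drop_prob", "duplicate_prob", "invalid_prob",
              "spike_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop_bad("'%s' must be in [0, 1]", p)
    }
  }
  stopifnot(saccade_amplitude_deg >= 0,
            length(saccade_duration_bounds_ms) == 2L,
            saccade_duration_bounds_ms[1] > 0,
            diff(saccade_duration_bounds_ms) > 0,
            nominal_hz > 0, warmup_duration_s >= 0,
            all(warmup_interval_ms_range > nominal_interval_ms(nominal_hz)))
  if (is.null(cfg$lead_in_s)) {
    cfg$lead_in_s <- if (warmup_duration_s > 0) warmup_duration_s + 35 else 2
  }
  structure(cfg, class = "sim_config")
}

# Truncated-normal draws by rejection; bounds are honest truncation, not
# clipping.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  for (it in seq_len(1000L)) {
    if (length(need) == 0L) break
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  if (length(need) > 0L) out[need] <- pmin(pmax(mean, lo), hi)
  out
}

#' Raised-cosine saccade waveform
#'
#' Smooth monotone position profile
#' `x(t) = A/2 * (1 - cos(pi * (t - onset) / D))` over a duration `D`
#' derived from the main-sequence relation `D = (pi/2) * A / V_peak`, so
#' the analytic maximum velocity equals `peak_velocity_dps` and the total
#' displacement equals `amplitude_deg`. If the derived duration falls
#' outside `duration_bounds_ms` it is clipped; the quantity named by
#' `clip_preserve` is then kept and the other recomputed (preserving the
#' peak velocity grows the amplitude, as the main sequence dictates for a
#' fast saccade; preserving the amplitude rescales the velocity).
#'
#' @param amplitude_deg signed displacement (deg); 0 yields a flat trace.
#' @param peak_velocity_dps peak velocity magnitude (deg/s).
#' @param t_grid_ms times at which to evaluate the position.
#' @param onset_ms movement onset.
#' @param duration_bounds_ms physiological clipping band, ms.
#' @param clip_preserve which parameter survives a duration clip.
#' @return list with `values` (deg, length of `t_grid_ms`),
#'   `duration_ms`, realized `amplitude_deg` and `peak_velocity_dps`
#'   (signed), and `clipped`.
#' @export
saccade_waveform <- function(amplitude_deg, peak_velocity_dps, t_grid_ms,
                             onset_ms = 0,
                             duration_bounds_ms = c(30, 100),
                             clip_preserve = c("peak_velocity",
                                               "amplitude")) {
  clip_preserve <- match.arg(clip_preserve)
  stopifnot(is.numeric(t_grid_ms))
  if (amplitude_deg == 0 || peak_velocity_dps == 0) {
    return(list(values = numeric(length(t_grid_ms)), duration_ms = 0,
                amplitude_deg = 0, peak_velocity_dps = 0, clipped = FALSE))
  }
  s <- sign(amplitude_deg)
  a <- abs(amplitude_deg)
  v <- abs(peak_velocity_dps)
  d_ms <- 1000 * pi * a / (2 * v)
  clipped <- d_ms < duration_bounds_ms[1] || d_ms > duration_bounds_ms[2]
  if (clipped) {
    d_ms <- min(max(d_ms, duration_bounds_ms[1]), duration_bounds_ms[2])
    if (clip_preserve == "peak_velocity") {
      a <- 2 * (d_ms / 1000) * v / pi
    } else {
      v <- pi * a / (2 * (d_ms / 1000))
    }
  }
  ph <- (t_grid_ms - onset_ms) / d_ms
  ph <- pmin(pmax(ph, 0), 1)
  list(values = s * a / 2 * (1 - cos(pi * ph)),
       duration_ms = d_ms,
       amplitude_deg = s * a,
       peak_velocity_dps = s * v,
       clipped = clipped)
}

# Waveform parameters without evaluation (used by the session builder).
waveform_params <- function(amplitude_deg, peak_velocity_dps,
                            duration_bounds_ms, clip_preserve) {
  w <- saccade_waveform(amplitude_deg, peak_velocity_dps,
                        t_grid_ms = numeric(0),
                        duration_bounds_ms = duration_bounds_ms,
                        clip_preserve = clip_preserve)
  w$values <- NULL
  w
}

# Schedule of trial start / stimulus-onset / stimulus-offset times (ms,
# capture clock) for a protocol, including 60 s breaks after flagged
# phases.
schedule_trials <- function(protocol, config) {
  phases <- attr(protocol, "phases") %||% session_phase_table()
  break_after <- setNames(phases$break_after, phases$phase)
  n <- nrow(protocol)
  start <- numeric(n)
  cursor <- config$lead_in_s * 1000
  for (i in seq_len(n)) {
    start[i] <- cursor
    cursor <- cursor + protocol$fore_period_s[i] * 1000 + 1000
    if (i < n && protocol$phase[i] != protocol$phase[i + 1] &&
        isTRUE(break_after[[protocol$phase[i]]])) {
      cursor <- cursor + 60000
    }
  }
  onset <- start + protocol$fore_period_s * 1000
  data.frame(start_ms = start, onset_ms = onset, offset_ms = onset + 1000)
}

#' Simulate a full assessment session
#'
#' Generates the eye-sample log, trial-event log and ground truth for a
#' session protocol. Per trial, the gaze fixates at 0 degrees during the
#' fore-period; at stimulus onset plus a drawn latency the saccade
#' executes toward the correct side for the task (wrong side with the
#' task's error probability); with the task's reflexive probability a
#' small excursion toward the erroneous direction precedes the corrective
#' saccade by a fixed gap; after stimulus offset the gaze returns to
#' center. Gaze-direction components are back-computed so that
#' [gaze_angle_deg()] inverts exactly to the intended angle, and
#' normalized pupil position is derived from the same angle with its own
#' (inverted) coordinate convention.
#'
#' The sampling clock emulates a polling recording loop: the tracker
#' captures frames on an exact 120 Hz grid (integer-ms device clock), the
#' loop consumes them from a queue with iteration times drawn from the
#' warm-up distribution while the host clock is inside the warm-up span
#' and from the steady-state distribution afterwards. During warm-up the
#' loop is slower than the tracker, so recorded host intervals exceed
#' 8.33 ms and a backlog builds; afterwards the backlog drains at the
#' fast loop period (host intervals well below 8 ms -- the stabilization
#' signature) before settling at the frame rate.
#'
#' @param protocol a [generate_session_protocol()] result (or compatible
#'   data frame).
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param error_trials optional integer vector of `trial_index` values
#'   forced to be direction errors (all other trials are then forced
#'   correct), for exact error-rate constructions.
#' @return list of class `sim_session`: `samples`, `events`
#'   (non-practice trials), `ground_truth` (one row per trial),
#'   `config`, `seed`.
#' @export
simulate_session <- function(protocol, config = sim_config(),
                             seed = config$seed, error_trials = NULL) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(protocol))
  if (!is_count(seed)) stop_bad("'seed' must be a non-negative integer")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  sched <- schedule_trials(protocol, config)
  session_end_ms <- sched$offset_ms[nrow(sched)] + 1000
  period_ms <- nominal_interval_ms(config$nominal_hz)

  # tracker capture grid, with frame drops
  k <- 0:floor(session_end_ms / period_ms)
  keep <- runif(length(k)) >= config$drop_prob
  keep[1] <- TRUE
  frame_seq <- k[keep]
  capture <- frame_seq * period_ms
  n <- length(capture)

  # per-trial ground truth and waveform list
  nt <- nrow(protocol)
  windows <- list(pro = detection_config()$window_pro_ms,
                  anti = detection_config()$window_anti_ms)
  gt <- data.frame(
    trial_index = protocol$trial_index,
    task = protocol$task, side = protocol$side,
    is_practice = protocol$is_practice,
    onset_ms = sched$onset_ms,
    latency_ms = NA_real_, direction = NA_real_,
    peak_velocity_dps = NA_real_,
    is_error = NA, is_reflexive = NA, clipped = FALSE,
    stringsAsFactors = FALSE
  )
  waves <- vector("list", 4L * nt)
  nw <- 0L
  add_wave <- function(onset_ms, amplitude, velocity, preserve) {
    w <- waveform_params(amplitude, velocity,
                         config$saccade_duration_bounds_ms, preserve)
    nw <<- nw + 1L
    waves[[nw]] <<- c(onset = onset_ms, amp = w$amplitude_deg,
                      dur = w$duration_ms)
    w
  }
  for (i in seq_len(nt)) {
    task <- protocol$task[i]
    tgt_sign <- if (protocol$side[i] == "right") -1 else 1
    correct <- if (task == "pro") tgt_sign else -tgt_sign
    err <- if (is.null(error_trials)) {
      runif(1) < config$error_prob[[task]]
    } else {
      protocol$trial_index[i] %in% error_trials
    }
    refl <- runif(1) < config$reflexive_prob[[task]]
    actual <- if (err) -correct else correct
    win <- windows[[task]]
    err_dir <- -correct
    ra <- err_dir * config$reflexive_amplitude_deg
    rp <- waveform_params(ra, config$reflexive_peak_velocity_dps,
                          config$saccade_duration_bounds_ms, "amplitude")
    # a reflexive excursion must fit inside the search window before the
    # corrective saccade, so reflexive trials draw their latency with a
    # raised lower truncation bound
    lat_lo <- if (refl) {
      win[1] + config$reflexive_gap_ms + rp$duration_ms +
        1.2 * nominal_interval_ms(config$nominal_hz)
    } else {
      win[1]
    }
    lat <- rtrunc_norm(1, config$latency_mean_ms[[task]],
                       config$latency_sd_ms[[task]], lat_lo, win[2])
    vel <- rtrunc_norm(1, config$peak_velocity_mean_dps[[task]],
                       config$peak_velocity_sd_dps[[task]], lo = 1)
    t_on <- sched$onset_ms[i] + lat
    amp8 <- config$saccade_amplitude_deg
    if (refl) {
      r_on <- t_on - config$reflexive_gap_ms - rp$duration_ms
      add_wave(r_on, ra, config$reflexive_peak_velocity_dps, "amplitude")
      w <- add_wave(t_on, actual * amp8 - ra, vel, "amplitude")
    } else {
      w <- add_wave(t_on, actual * amp8, vel, "peak_velocity")
    }
    # return to center after stimulus offset
    end_pos <- w$amplitude_deg + if (refl) ra else 0
    add_wave(sched$offset_ms[i] + config$return_saccade_delay_ms,
             -end_pos,
             rtrunc_norm(1, config$peak_velocity_mean_dps[[task]],
                         config$peak_velocity_sd_dps[[task]], lo = 1),
             "amplitude")
    gt$latency_ms[i] <- lat
    gt$direction[i] <- actual
    gt$peak_velocity_dps[i] <- sign(w$peak_velocity_dps) *
      abs(w$peak_velocity_dps)
    gt$is_error[i] <- err
    gt$is_reflexive[i] <- refl
    gt$clipped[i] <- w$clipped
  }
  waves <- waves[seq_len(nw)]

  # intended gaze angle: completed amplitudes via a step array, active
  # ramps evaluated locally
  theta <- numeric(n)
  steps <- numeric(n + 1L)
  for (w in waves) {
    i1 <- findInterval(w[["onset"]], capture) + 1L # first index >= onset
    i2 <- findInterval(w[["onset"]] + w[["dur"]], capture,
                       left.open = TRUE) + 1L      # first index > end
    i1 <- min(i1, n + 1L)
    i2 <- min(i2, n + 1L)
    if (i1 < i2) {
      idx <- i1:(i2 - 1L)
      ph <- (capture[idx] - w[["onset"]]) / w[["dur"]]
      theta[idx] <- theta[idx] + w[["amp"]] / 2 * (1 - cos(pi * ph))
    }
    steps[i2] <- steps[i2] + w[["amp"]]
  }
  theta <- theta + cumsum(steps)[seq_len(n)]

  # host read times of the polling loop
  warm <- runif(n, config$warmup_interval_ms_range[1],
                config$warmup_interval_ms_range[2])
  stab <- runif(n, config$stable_loop_ms_range[1],
                config$stable_loop_ms_range[2])
  host <- host_read_times(capture, warm, stab,
                          config$warmup_duration_s * 1000)

  samples <- data.frame(frame_sequence = frame_seq,
                        device_timestamp_ms = round(capture),
                        host_time_ms = config$epoch_ms + host)
  for (eye in EYES) {
    th <- theta + rnorm(n, 0, config$angle_noise_sd_deg)
    spikes <- which(runif(n) < config$spike_prob)
    if (length(spikes) > 0) {
      th[spikes] <- th[spikes] +
        sample(c(-1, 1), length(spikes), replace = TRUE) *
        config$spike_amplitude_deg
    }
    pd_base <- max(1.5, rnorm(1, config$pupil_mean_mm, config$pupil_sd_mm))
    pd <- pd_base + rnorm(n, 0, config$pupil_jitter_sd_mm)
    invalid <- runif(n) < config$invalid_prob
    validity <- rep(VALID_ALL, n)
    if (any(invalid)) {
      validity[invalid] <- sample(c(0L, 1L, 3L, 7L, 15L), sum(invalid),
                                  replace = TRUE)
    }
    rad <- th * pi / 180
    e <- list()
    e[[paste0(eye, "_validity")]] <- validity
    e[[paste0(eye, "_openness")]] <- rep(1, n)
    e[[paste0(eye, "_pupil_diameter_mm")]] <- pd
    e[[paste0(eye, "_pupil_pos_x")]] <-
      pmin(pmax(0.5 - th / config$fov_deg, 0), 1)
    e[[paste0(eye, "_pupil_pos_y")]] <- rep(0.5, n)
    e[[paste0(eye, "_gaze_origin_x_mm")]] <-
      rep(if (eye == "left") -32 else 32, n)
    e[[paste0(eye, "_gaze_origin_y_mm")]] <- rep(0, n)
    e[[paste0(eye, "_gaze_origin_z_mm")]] <- rep(0, n)
    e[[paste0(eye, "_gaze_dir_x")]] <- sin(rad)
    e[[paste0(eye, "_gaze_dir_y")]] <- rep(0, n)
    e[[paste0(eye, "_gaze_dir_z")]] <- cos(rad)
    # blank out fields whose validity bit is unset
    fl <- decode_validity(validity)
    blank <- list(gaze_origin = paste0(eye, "_gaze_origin_",
                                       c("x", "y", "z"), "_mm"),
                  gaze_direction = paste0(eye, "_gaze_dir_",
                                          c("x", "y", "z")),
                  pupil_diameter = paste0(eye, "_pupil_diameter_mm"),
                  eye_openness = paste0(eye, "_openness"),
                  pupil_position = paste0(eye, "_pupil_pos_",
                                          c("x", "y")))
    for (fld in names(blank)) {
      off <- !fl[[fld]]
      if (any(off)) for (col in blank[[fld]]) e[[col]][off] <- NA_real_
    }
    samples <- cbind(samples, as.data.frame(e))
  }

  # duplicate-read injection (timestamp-bug signature)
  if (config$duplicate_prob > 0 && n > 2L) {
    dup <- which(runif(n - 1L) < config$duplicate_prob)
    if (length(dup) > 0L) {
      extra <- samples[dup, , drop = FALSE]
      gap <- samples$host_time_ms[dup + 1L] - samples$host_time_ms[dup]
      extra$host_time_ms <- samples$host_time_ms[dup] + pmin(4, gap / 2)
      for (eye in EYES) {
        col <- paste0(eye, "_pupil_diameter_mm")
        extra[[col]] <- extra[[col]] - 0.0104
      }
      samples <- rbind(samples, extra)
      samples <- samples[order(samples$host_time_ms,
                               samples$frame_sequence), , drop = FALSE]
      rownames(samples) <- NULL
    }
  }

  keep_ev <- !protocol$is_practice
  events <- trial_events(
    trial_index = protocol$trial_index[keep_ev],
    task = protocol$task[keep_ev],
    side = protocol$side[keep_ev],
    onset_host_time_ms = config$epoch_ms + sched$onset_ms[keep_ev],
    offset_host_time_ms = config$epoch_ms + sched$offset_ms[keep_ev]
  )
  structure(list(samples = samples, events = events, ground_truth = gt,
                 config = config, seed = as.integer(seed)),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf(
    "Simulated session: %d samples, %d events, %d trials (seed %d)\n",
    nrow(x$samples), nrow(x$events), nrow(x$ground_truth), x$seed))
  invisible(x)
}

#' Simulate a batch of single-task trials
#'
#' Convenience wrapper for parameter-recovery studies: builds an ad-hoc
#' non-practice protocol of `n_trials` trials of one task (sides
#' balanced, fore-periods drawn with the standard 1.5 s phase-mean law)
#' and simulates it.
#'
#' @param n_trials number of trials (even, for exact side balance).
#' @param task `"pro"` or `"anti"`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param error_trials passed to [simulate_session()].
#' @return a `sim_session`.
#' @export
simulate_trials <- function(n_trials, task = c("pro", "anti"),
                            config = sim_config(), seed = 1L,
                            error_trials = NULL) {
  task <- match.arg(task)
  stopifnot(is_count(n_trials), n_trials >= 2, n_trials %% 2 == 0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  prot <- data.frame(
    trial_index = seq_len(n_trials) - 1L,
    phase = paste0(task, "_batch"),
    task = task,
    side = draw_sides(n_trials),
    fore_period_s = draw_fore_periods(n_trials),
    is_practice = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  attr(prot, "phases") <- data.frame(phase = paste0(task, "_batch"),
                                     task = task, n_trials = n_trials,
                                     is_practice = FALSE,
                                     break_after = FALSE,
                                     stringsAsFactors = FALSE)
  class(prot) <- c("session_protocol", "data.frame")
  simulate_session(prot, config,
                   seed = (as.integer(seed) %% 2000000000L) + 1L,
                   error_trials = error_trials)
}

#' Simulate a single trial
#'
#' @param task,side trial type and stimulus side.
#' @param fore_period_s fore-period duration (s).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a `sim_session` with one trial.
#' @export
simulate_trial <- function(task = c("pro", "anti"),
                           side = c("right", "left"),
                           fore_period_s = 1.5,
                           config = sim_config(), seed = 1L) {
  task <- match.arg(task)
  side <- match.arg(side)
  prot <- data.frame(trial_index = 0L, phase = paste0(task, "_single"),
                     task = task, side = side,
                     fore_period_s = fore_period_s, is_practice = FALSE,
                     stringsAsFactors = FALSE)
  attr(prot, "phases") <- data.frame(phase = paste0(task, "_single"),
                                     task = task, n_trials = 1L,
                                     is_practice = FALSE,
                                     break_after = FALSE,
                                     stringsAsFactors = FALSE)
  class(prot) <- c("session_protocol", "data.frame")
  simulate_session(prot, config, seed = seed)
}

#' Write a simulated session to disk
#'
#' Writes the sample log, event log, ground-truth TSV and the resolved
#' simulation config (seed included) under a common prefix.
#'
#' @param session a `sim_session`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths.
#' @export
write_sim_session <- function(session, dir) {
  stopifnot(inherits(session, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(samples = file.path(dir, "samples.tsv"),
             events = file.path(dir, "events.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"),
             config = file.path(dir, "sim_config.cfg"))
  write_samples(session$samples, paths[["samples"]])
  write_events(session$events, paths[["events"]])
  write.table(session$ground_truth, paths[["ground_truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(session$config)
  cfg$seed <- session$seed
  flat <- list()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.null(names(v)) && length(v) > 1) {
      for (sub in names(v)) flat[[paste0(nm, ".", sub)]] <- v[[sub]]
    } else {
      flat[[nm]] <- v
    }
  }
  write_run_config(flat, paths[["config"]])
  invisible(paths)
}
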