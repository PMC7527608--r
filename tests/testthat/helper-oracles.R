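# Independent oracles and fixture builders, written against the module
# contracts rather than the implementation.

# Brute-force running median: explicit window construction per index,
# full sort, lower median. Mirrors the despike() contract: interior
# windows [i - w/2 + 1, i + w/2] for even w, symmetric shrink at edges.
oracle_running_median <- function(x, order = 10L) {
  n <- length(x)
  out <- numeric(n)
  if (order %% 2L == 0L) {
    back <- order / 2L - 1L
    fwd <- order / 2L
  } else {
    back <- (order - 1L) / 2L
    fwd <- back
  }
  for (i in seq_len(n)) {
    if (i - back >= 1L && i + fwd <= n) {
      w <- x[(i - back):(i + fwd)]
    } else {
      s <- min(i - 1L, n - i)
      w <- x[(i - s):(i + s)]
    }
    srt <- sort(w)
    out[i] <- srt[floor((length(w) + 1) / 2)] # lower median
  }
  out
}

# Exhaustive five-case decision oracle: enumerate every local extremum of
# |vnorm| above threshold (plain index-by-index scan) and apply the case
# rules by direct enumeration of the (first-peak sign, later-peak signs)
# possibilities.
oracle_case_assignment <- function(vnorm, exp_sign, values, no_move,
                                   peak_thr = 0.5) {
  if (diff(range(values)) < no_move || all(vnorm == 0)) {
    return(list(case_id = 5L, is_error = TRUE, selected = NA_integer_))
  }
  n <- length(vnorm)
  a <- abs(vnorm)
  ext <- integer(0)
  for (i in seq_len(n - 1L)) { # last sample carries a duplicated velocity
    left_ok <- (i == 1L) || (a[i] >= a[i - 1L])
    right_ok <- a[i] > a[i + 1L]
    strict_left <- (i == 1L) && a[i] > a[i + 1L]
    if ((left_ok && right_ok) || strict_left) ext <- c(ext, i)
  }
  ext <- ext[a[ext] > peak_thr]
  if (length(ext) == 0L) {
    return(list(case_id = 5L, is_error = TRUE, selected = NA_integer_))
  }
  sg <- sign(vnorm[ext])
  if (sg[1] == exp_sign) {
    sel <- ext[1]
    case <- if (any(sg[-1] == -exp_sign)) 2L else 1L
    err <- FALSE
  } else if (any(sg == exp_sign)) {
    sel <- ext[which(sg == exp_sign)[1]]
    later <- sg[ext > sel]
    case <- if (any(later == -exp_sign)) 4L else 3L
    err <- FALSE
  } else {
    sel <- ext[1]
    case <- if (any(sg[-1] == -sg[1])) 2L else 1L
    err <- TRUE
  }
  list(case_id = case, is_error = err, selected = sel)
}

# Construct a trial_window directly (fixture builder).
make_window <- function(times_ms, values, task = "pro", side = "right",
                        signal_kind = "gaze_deg", eye = "left",
                        trial_index = 0L) {
  structure(list(
    trial_index = trial_index, eye = eye, signal_kind = signal_kind,
    task = task, side = side,
    window_ms = if (task == "pro") c(100, 500) else c(125, 750),
    times_ms = times_ms, values = values, velocity = NULL,
    unanalyzable = FALSE
  ), class = "trial_window")
}

# Noise-free raised-cosine trial trace on a regular 120 Hz grid covering
# the task window, with saccade onset `latency_ms` after stimulus onset.
make_saccade_window <- function(latency_ms = 200, amplitude = -8,
                                peak_velocity = 350, task = "pro",
                                side = "right", signal_kind = "gaze_deg",
                                start_value = 0) {
  win <- if (task == "pro") c(100, 500) else c(125, 750)
  t <- seq(win[1], win[2], by = 1000 / 120)
  w <- saccade_waveform(amplitude, peak_velocity, t, onset_ms = latency_ms)
  make_window(t, start_value + w$values, task = task, side = side,
              signal_kind = signal_kind)
}

# One fully valid eye-sample row template, replicated n times.
make_valid_samples <- function(n, t0 = 0, dt = 1000 / 120,
                               angle_deg = rep(0, n)) {
  rad <- angle_deg * pi / 180
  one_eye <- function(eye, sign_x) {
    e <- list()
    e[[paste0(eye, "_validity")]] <- rep(31L, n)
    e[[paste0(eye, "_openness")]] <- rep(1, n)
    e[[paste0(eye, "_pupil_diameter_mm")]] <- rep(4.3, n)
    e[[paste0(eye, "_pupil_pos_x")]] <- 0.5 - angle_deg / 110
    e[[paste0(eye, "_pupil_pos_y")]] <- rep(0.5, n)
    e[[paste0(eye, "_gaze_origin_x_mm")]] <- rep(sign_x * 32, n)
    e[[paste0(eye, "_gaze_origin_y_mm")]] <- rep(0, n)
    e[[paste0(eye, "_gaze_origin_z_mm")]] <- rep(0, n)
    e[[paste0(eye, "_gaze_dir_x")]] <- sin(rad)
    e[[paste0(eye, "_gaze_dir_y")]] <- rep(0, n)
    e[[paste0(eye, "_gaze_dir_z")]] <- cos(rad)
    as.data.frame(e)
  }
  cbind(
    data.frame(frame_sequence = seq_len(n) - 1L,
               device_timestamp_ms = round(t0 + (seq_len(n) - 1L) * dt),
               host_time_ms = t0 + (seq_len(n) - 1L) * dt),
    one_eye("left", -1), one_eye("right", 1)
  )
}

# Random fully populated sample log for I/O round-trip tests.
random_samples <- function(n, seed = 1) {
  set.seed(seed)
  s <- make_valid_samples(n, t0 = 1e12, angle_deg = runif(n, -10, 10))
  for (eye in c("left", "right")) {
    s[[paste0(eye, "_validity")]] <- sample(0:31, n, replace = TRUE)
    s[[paste0(eye, "_pupil_diameter_mm")]] <- runif(n, 2, 8)
    s[[paste0(eye, "_openness")]] <- runif(n)
  }
  s
}
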