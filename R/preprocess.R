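# Preprocessing: validity cleaning, gaze-vector to visual-angle
# conversion, running-median despiking, trial segmentation, and time-aware
# velocity.

#' Horizontal gaze angle from a normalized gaze-direction vector
#'
#' `atan(gd_x / gd_z)` converted from radians to degrees. With the
#' headset's coordinate convention the result is negative when the eyes
#' move to the observer's right and positive when they move left. Samples
#' with `gd_z == 0` have no defined horizontal direction and yield `NA`
#' with a warning; callers drop them.
#'
#' @param gd_x,gd_z normalized gaze-direction components (each in
#'   \[-1, 1\]).
#' @return gaze angle in degrees (vectorized).
#' @export
#' @examples
#' gaze_angle_deg(0, 1)            # straight ahead: 0
#' gaze_angle_deg(tan(8 * pi / 180), 1)  # 8 degrees (leftward)
gaze_angle_deg <- function(gd_x, gd_z) {
  stopifnot(is.numeric(gd_x), is.numeric(gd_z),
            length(gd_x) == length(gd_z))
  bad <- is.finite(gd_z) & gd_z == 0
  if (any(bad)) {
    warning(sprintf(
      "%d sample(s) with gd_z = 0 have undefined gaze direction; set to NA",
      sum(bad)), call. = FALSE)
  }
  out <- atan(gd_x / gd_z) * 180 / pi
  out[bad] <- NA_real_
  out
}

#' Keep only fully valid samples for one eye
#'
#' Data cleaning step: samples whose validity bitmask for the requested
#' eye is less than 31 (any field untrustworthy) are discarded; only
#' mask-31 rows are retained. Retained rows are never altered. The
#' retention ratio is attached as attribute `retention`.
#'
#' @param samples sample-log data frame.
#' @param eye `"left"` or `"right"`.
#' @return the retained rows, with attribute `retention` in \[0, 1\].
#' @export
clean_samples <- function(samples, eye = c("left", "right")) {
  eye <- match.arg(eye)
  vcol <- paste0(eye, "_validity")
  stopifnot(vcol %in% names(samples))
  keep <- samples[[vcol]] == VALID_ALL
  if (!any(keep)) {
    stop_bad("no valid samples: every %s-eye validity mask is below 31", eye)
  }
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retention") <- mean(keep)
  out
}

#' Despike a series with a running median
#'
#' Removes isolated spike noise with a running median of (even) order 10.
#' Interior windows span samples `[i - order/2 + 1, i + order/2]`; ties on
#' even windows break to the lower median, and windows shrink symmetrically
#' at the series boundaries, so the output has the input's length and a
#' constant series passes through unchanged.
#'
#' @param x numeric series (length must exceed `order`).
#' @param order filter order (window length), default 10.
#' @return the filtered series.
#' @export
despike <- function(x, order = 10L) {
  stopifnot(is.numeric(x))
  if (anyNA(x)) stop_bad("despike() requires a series without NA values")
  running_median_lower(as.numeric(x), as.integer(order))
}

# Build the per-eye scalar signal stream used by the detector: host time
# plus either the gaze angle in degrees or the normalized horizontal pupil
# position. Assumes `samples` have already been cleaned for `eye`.
signal_stream <- function(samples, eye = c("left", "right"),
                          signal_kind = c("gaze_deg", "pupil_pos_x")) {
  eye <- match.arg(eye)
  signal_kind <- match.arg(signal_kind)
  if (signal_kind == "gaze_deg") {
    value <- gaze_angle_deg(samples[[paste0(eye, "_gaze_dir_x")]],
                            samples[[paste0(eye, "_gaze_dir_z")]])
  } else {
    value <- samples[[paste0(eye, "_pupil_pos_x")]]
  }
  keep <- is.finite(value)
  data.frame(host_time_ms = samples$host_time_ms[keep], value = value[keep])
}

#' Extract one trial's analysis window
#'
#' Cuts the task-specific search window out of a cleaned, angle-converted,
#' despiked signal stream: `[onset + 100, onset + 500]` ms for pro-saccade
#' trials and `[onset + 125, onset + 750]` ms for anti-saccade trials
#' (closed bounds; a sample exactly on a bound is included). Times are
#' re-expressed relative to the stimulus onset. A window with fewer than
#' `min_samples` samples is marked unanalyzable rather than dropped.
#'
#' @param stream data frame with `host_time_ms` and `value` (from
#'   [signal_stream()], already despiked).
#' @param event one row of a [trial_events()] table.
#' @param task `"pro"` or `"anti"`; defaults to the event's task.
#' @param signal_kind which signal the stream carries.
#' @param eye which eye the stream belongs to (metadata only).
#' @param config a [detection_config()] supplying window bounds and
#'   `min_samples`.
#' @return an object of class `trial_window`: list with `trial_index`,
#'   `eye`, `signal_kind`, `task`, `side`, `times_ms` (relative to onset),
#'   `values`, `velocity` (`NULL` until [add_velocity()]), and
#'   `unanalyzable`.
#' @export
segment_trial <- function(stream, event, task = NULL,
                          signal_kind = c("gaze_deg", "pupil_pos_x"),
                          eye = c("left", "right"),
                          config = detection_config()) {
  signal_kind <- match.arg(signal_kind)
  eye <- match.arg(eye)
  task <- task %||% event$task
  stopifnot(task %in% TASKS)
  win <- if (task == "pro") config$window_pro_ms else config$window_anti_ms
  t0 <- event$onset_host_time_ms
  lo <- t0 + win[1]
  hi <- t0 + win[2]
  idx <- which(stream$host_time_ms >= lo & stream$host_time_ms <= hi)
  w <- structure(list(
    trial_index = event$trial_index,
    eye = eye, signal_kind = signal_kind, task = task, side = event$side,
    window_ms = win,
    times_ms = stream$host_time_ms[idx] - t0,
    values = stream$value[idx],
    velocity = NULL,
    unanalyzable = length(idx) < config$min_samples
  ), class = "trial_window")
  w
}

#' Per-sample signal velocity on actual timestamps
#'
#' Fills the window's `velocity` slot with time-aware two-point
#' differences: `v[i] = (x[i+1] - x[i]) / (t[i+1] - t[i])`, assigned to the
#' left sample of each interval (the last sample repeats its
#' predecessor's value). Units are deg/s for gaze windows and 1/s for
#' normalized pupil position. Repeated timestamps are dropped before
#' differencing. Two-point differences are used rather than wider central
#' stencils because at 120 Hz a centred stencil spans 16.7 ms -- a large
#' fraction of a 30-100 ms saccade -- and systematically flattens the
#' velocity peak.
#'
#' @param window a `trial_window` from [segment_trial()].
#' @return the window with `velocity` filled (and duplicate-timestamp
#'   samples removed).
#' @export
add_velocity <- function(window) {
  stopifnot(inherits(window, "trial_window"))
  t <- window$times_ms
  x <- window$values
  keep <- c(TRUE, diff(t) > 0)
  t <- t[keep]
  x <- x[keep]
  if (length(t) < 3L) {
    window$times_ms <- t
    window$values <- x
    window$velocity <- rep(NA_real_, length(t))
    window$unanalyzable <- TRUE
    return(window)
  }
  # ms -> s: x per second
  v <- diff(x) / (diff(t) / 1000)
  window$times_ms <- t
  window$values <- x
  window$velocity <- c(v, v[length(v)])
  window
}
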