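# Five-case normalized-velocity saccade detector and oculo-metric
# aggregation.

#' Saccade detection configuration
#'
#' Thresholds and windows of the five-case velocity detector. After the
#' per-window velocity is normalized to \[-1, 1\], local extrema with
#' magnitude above `peak_threshold_norm` are candidate saccade peaks; the
#' saccade onset (latency) is where the normalized speed last rose through
#' `onset_threshold_norm` before the selected peak. Windows whose signal
#' range stays within `no_move_deg` (gaze, degrees) or `no_move_pupilpos`
#' (normalized pupil position) are classified as case 5 (task not
#' performed). A wrong-direction excursion beyond
#' `reflexive_excursion_deg` marks a reflexive response.
#'
#' @param peak_threshold_norm normalized-velocity peak threshold
#'   (default 0.5).
#' @param onset_threshold_norm normalized-velocity onset threshold
#'   (default 0.25); must be below the peak threshold.
#' @param no_move_deg no-movement criterion for gaze windows, degrees
#'   (default 1).
#' @param no_move_pupilpos no-movement criterion for pupil-position
#'   windows (default 0.001).
#' @param reflexive_excursion_deg reflexive-response excursion threshold,
#'   degrees (default 3).
#' @param window_pro_ms,window_anti_ms search windows relative to stimulus
#'   onset, ms (defaults (100, 500) and (125, 750)).
#' @param min_samples minimum samples for an analyzable window
#'   (default 10).
#' @return object of class `detection_config`.
#' @export
detection_config <- function(peak_threshold_norm = 0.5,
                             onset_threshold_norm = 0.25,
                             no_move_deg = 1,
                             no_move_pupilpos = 0.001,
                             reflexive_excursion_deg = 3,
                             window_pro_ms = c(100, 500),
                             window_anti_ms = c(125, 750),
                             min_samples = 10L) {
  if (!(onset_threshold_norm > 0 && onset_threshold_norm <
        peak_threshold_norm && peak_threshold_norm <= 1)) {
    stop_bad("need 0 < onset_threshold_norm < peak_threshold_norm <= 1")
  }
  stopifnot(no_move_deg > 0, no_move_pupilpos > 0,
            reflexive_excursion_deg > 0,
            length(window_pro_ms) == 2L, diff(window_pro_ms) > 0,
            length(window_anti_ms) == 2L, diff(window_anti_ms) > 0,
            min_samples >= 3)
  structure(list(
    peak_threshold_norm = peak_threshold_norm,
    onset_threshold_norm = onset_threshold_norm,
    no_move_deg = no_move_deg,
    no_move_pupilpos = no_move_pupilpos,
    reflexive_excursion_deg = reflexive_excursion_deg,
    window_pro_ms = as.numeric(window_pro_ms),
    window_anti_ms = as.numeric(window_anti_ms),
    min_samples = as.integer(min_samples)
  ), class = "detection_config")
}

# Sign of the expected primary-saccade velocity. Gaze degrees are negative
# rightward: a pro-saccade to a right target moves the angle down
# (negative velocity), to a left target up. The anti-saccade rule inverts
# the sign. Normalized pupil position x increases rightward from the
# user's view, so its convention is inverted relative to gaze degrees.
expected_velocity_sign <- function(task, side, signal_kind = "gaze_deg") {
  stopifnot(task %in% TASKS, side %in% SIDES)
  s <- if (side == "right") -1 else 1
  if (task == "anti") s <- -s
  if (signal_kind == "pupil_pos_x") s <- -s
  s
}

# Local extrema of |v| (candidate saccade peaks), in time order. Plateaus
# contribute their first index; the final sample is excluded because its
# velocity duplicates its predecessor's.
find_velocity_peaks <- function(vnorm, threshold) {
  n <- length(vnorm)
  a <- abs(vnorm)
  idx <- integer(0)
  if (n >= 2L && a[1] > a[2]) idx <- c(idx, 1L)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    hit <- a[i] >= a[i - 1L] & a[i] > a[i + 1L]
    idx <- c(idx, i[hit])
  }
  idx <- sort(idx)
  idx[a[idx] > threshold]
}

# Quadratic refinement of the velocity-peak magnitude: fit a parabola in
# time through the peak sample and its neighbours and take the vertex
# value. At 120 Hz the discrete maximum of a 30-100 ms saccade can fall
# half a sample off the true peak; the vertex removes that grid-phase
# error while leaving the (separately documented) finite-difference
# smoothing untouched.
refine_peak_velocity <- function(times_ms, v, i) {
  n <- length(v)
  if (i <= 1L || i >= n - 1L) return(v[i])
  t3 <- times_ms[(i - 1L):(i + 1L)]
  v3 <- v[(i - 1L):(i + 1L)]
  if (!all(sign(v3) == sign(v[i]))) return(v[i])
  co <- tryCatch(solve(cbind(1, t3, t3^2), v3), error = function(e) NULL)
  if (is.null(co) || !is.finite(co[3]) || co[3] == 0) return(v[i])
  tv <- -co[2] / (2 * co[3])
  if (tv < t3[1] || tv > t3[3]) return(v[i])
  vv <- co[1] + co[2] * tv + co[3] * tv^2
  if (!is.finite(vv) || abs(vv) < abs(v[i])) return(v[i])
  # the grid-phase loss the vertex corrects is at most ~14% (shortest
  # physiological saccade, worst sample alignment); larger gains mean the
  # parabola is degenerate, so fall back to the discrete maximum
  if (abs(vv) > 1.15 * abs(v[i])) return(v[i])
  vv
}

empty_result <- function(window, case_id = NA_integer_,
                         unanalyzable = FALSE) {
  data.frame(
    trial_index = window$trial_index,
    task = window$task, side = window$side,
    eye = window$eye, signal_kind = window$signal_kind,
    case_id = case_id,
    latency_ms = NA_real_,
    peak_velocity = NA_real_,
    is_error = NA,
    has_reflexive_onset = NA,
    unanalyzable = unanalyzable,
    stringsAsFactors = FALSE
  )
}

#' Classify one trial window and measure the saccade
#'
#' The five-case velocity detector. If the signal range within the search
#' window stays under the no-movement criterion the trial is case 5 (task
#' not performed; no latency or peak). Otherwise the velocity is
#' normalized by its maximum magnitude in the window and local extrema
#' with |v| above the 0.5 threshold are collected in time order:
#'
#' * first peak matches the expected direction: case 1, or case 2 if a
#'   later opposite-sign (return) peak exists;
#' * first peak mismatches but a later matching peak exists: case 3, or
#'   case 4 with a return peak after the corrective one; the first peak is
#'   a reflexive response and the corrective peak is measured;
#' * no matching peak at all: direction error; the first peak is measured.
#'
#' Latency is the time (relative to stimulus onset) of the sample at which
#' the normalized speed last rose through the 0.25 onset threshold before
#' the selected peak; the signed peak velocity is the unnormalized
#' velocity at the selected peak (quadratic-refined; reported only for
#' gaze windows). Case-5 trials count as direction errors in the error
#' rate, and are additionally reported separately by [aggregate_metrics()]
#' so the opposite convention remains recoverable.
#'
#' @param window a `trial_window` with velocity ([add_velocity()]).
#' @param expected_side stimulus side; defaults to the window's.
#' @param task task type; defaults to the window's.
#' @param config a [detection_config()].
#' @return one-row data frame (a `TrialResult`): `case_id` (1-5),
#'   `latency_ms`, `peak_velocity`, `is_error`, `has_reflexive_onset`,
#'   `unanalyzable`, plus trial metadata.
#' @export
classify_and_detect <- function(window, expected_side = NULL, task = NULL,
                                config = detection_config()) {
  stopifnot(inherits(window, "trial_window"),
            inherits(config, "detection_config"))
  if (!is.null(task)) window$task <- task
  if (!is.null(expected_side)) window$side <- expected_side
  if (is.null(window$velocity)) window <- add_velocity(window)
  if (isTRUE(window$unanalyzable) ||
      length(window$values) < config$min_samples) {
    return(empty_result(window, unanalyzable = TRUE))
  }

  no_move <- if (window$signal_kind == "gaze_deg") {
    config$no_move_deg
  } else {
    config$no_move_pupilpos
  }
  res <- empty_result(window)
  res$has_reflexive_onset <- reflexive_flag(window, config = config)

  if (diff(range(window$values)) < no_move) {
    res$case_id <- 5L
    res$is_error <- TRUE
    return(res)
  }
  v <- window$velocity
  vmax <- max(abs(v))
  if (vmax == 0) {
    res$case_id <- 5L
    res$is_error <- TRUE
    return(res)
  }
  vnorm <- v / vmax
  peaks <- find_velocity_peaks(vnorm, config$peak_threshold_norm)
  if (length(peaks) == 0L) {
    # range moved but no supra-threshold extremum: degenerate, treat as
    # not-performed
    res$case_id <- 5L
    res$is_error <- TRUE
    return(res)
  }
  exp_sign <- expected_velocity_sign(window$task, window$side,
                                     window$signal_kind)
  psign <- sign(v[peaks])
  first <- peaks[1]

  if (psign[1] == exp_sign) {
    sel <- first
    has_return <- any(psign[-1] == -exp_sign)
    res$case_id <- if (has_return) 2L else 1L
    res$is_error <- FALSE
  } else {
    match_later <- which(psign == exp_sign)
    if (length(match_later) > 0L) {
      sel <- peaks[match_later[1]]
      after <- peaks > sel
      has_return <- any(psign[after] == -exp_sign)
      res$case_id <- if (has_return) 4L else 3L
      res$is_error <- FALSE
    } else {
      sel <- first
      has_return <- any(psign[-1] == -psign[1])
      res$case_id <- if (has_return) 2L else 1L
      res$is_error <- TRUE
    }
  }

  # onset: first sample of the contiguous |vnorm| >= 0.25 run ending at
  # the selected peak
  j <- sel
  while (j > 1L && abs(vnorm[j - 1L]) >= config$onset_threshold_norm) {
    j <- j - 1L
  }
  res$latency_ms <- window$times_ms[j]
  if (window$signal_kind == "gaze_deg") {
    res$peak_velocity <- refine_peak_velocity(window$times_ms / 1000, v, sel)
  }
  res
}

#' Reflexive-response flag
#'
#' A reflexive response is an excursion of the signal from its value at
#' the window start toward the erroneous direction (toward the stimulus in
#' an anti-saccade trial, away from it in a pro-saccade trial) exceeding 3
#' degrees. Defined for gaze windows; pupil-position windows return `NA`
#' because the normalized units have no degree conversion.
#'
#' @param window a `trial_window`.
#' @param expected_side,task overrides; default to the window's.
#' @param config a [detection_config()].
#' @return logical (or `NA` for pupil-position windows).
#' @export
reflexive_flag <- function(window, expected_side = NULL, task = NULL,
                           config = detection_config()) {
  stopifnot(inherits(window, "trial_window"))
  if (window$signal_kind != "gaze_deg") return(NA)
  if (length(window$values) < 2L) return(NA)
  task <- task %||% window$task
  side <- expected_side %||% window$side
  err_sign <- -expected_velocity_sign(task, side, "gaze_deg")
  excursion <- max(err_sign * (window$values - window$values[1]))
  excursion > config$reflexive_excursion_deg
}

#' Error rate over a set of trial results
#'
#' Percentage of analyzed (non-unanalyzable) trials whose primary saccade
#' contradicted the task rule. Case-5 (no-movement) trials count as
#' errors.
#'
#' @param results data frame of trial results ([classify_and_detect()]).
#' @return error rate in percent.
#' @export
error_rate <- function(results) {
  analyzed <- !results$unanalyzable
  if (!any(analyzed)) stop_bad("error_rate(): no analyzable trials")
  100 * sum(results$is_error[analyzed]) / sum(analyzed)
}

#' Aggregate trial results into task metrics
#'
#' Mean/SD of latency and of peak-velocity magnitude, error rate,
#' reflexive-response proportion and trial accounting per task x eye x
#' signal kind, plus both-eyes-combined rows obtained by pooling the
#' per-eye trial results (not by averaging eye means). When the raw
#' samples and events are supplied, per-eye pupil-diameter mean/SD over
#' all valid samples recorded during each task's stimulus windows are
#' attached to the per-eye gaze rows.
#'
#' @param results trial-result data frame.
#' @param samples optional sample log for pupil summaries.
#' @param events optional [trial_events()] delimiting the task windows.
#' @return data frame of class `task_metrics`, one row per task x eye
#'   (`left`, `right`, `both`) x signal kind.
#' @export
aggregate_metrics <- function(results, samples = NULL, events = NULL) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  groups <- expand.grid(
    task = intersect(TASKS, unique(results$task)),
    eye = c("left", "right", "both"),
    signal_kind = intersect(SIGNAL_KINDS, unique(results$signal_kind)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- results[results$task == g$task &
                     results$signal_kind == g$signal_kind &
                     (g$eye == "both" | results$eye == g$eye), ,
                   drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    an <- sub[!sub$unanalyzable, , drop = FALSE]
    lat <- an$latency_ms[!is.na(an$latency_ms)]
    pk <- abs(an$peak_velocity[!is.na(an$peak_velocity)])
    refl <- an$has_reflexive_onset[!is.na(an$has_reflexive_onset)]
    data.frame(
      task = g$task, eye = g$eye, signal_kind = g$signal_kind,
      n_trials = nrow(sub),
      n_analyzed = nrow(an),
      n_unanalyzable = sum(sub$unanalyzable),
      n_case5 = sum(an$case_id == 5L, na.rm = TRUE),
      latency_mean_ms = if (length(lat)) mean(lat) else NA_real_,
      latency_sd_ms = if (length(lat) > 1) sd(lat) else NA_real_,
      peak_velocity_mean_dps = if (length(pk)) mean(pk) else NA_real_,
      peak_velocity_sd_dps = if (length(pk) > 1) sd(pk) else NA_real_,
      error_rate_pct = if (nrow(an)) 100 * mean(an$is_error) else NA_real_,
      reflexive_pct = if (length(refl)) 100 * mean(refl) else NA_real_,
      pupil_diameter_mean_mm = NA_real_,
      pupil_diameter_sd_mm = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  if (!is.null(samples) && !is.null(events)) {
    for (task in unique(metrics$task)) {
      ev <- events[events$task == task, , drop = FALSE]
      if (nrow(ev) == 0) next
      in_task <- rep(FALSE, nrow(samples))
      for (k in seq_len(nrow(ev))) {
        in_task <- in_task |
          (samples$host_time_ms >= ev$onset_host_time_ms[k] &
             samples$host_time_ms <= ev$offset_host_time_ms[k])
      }
      for (eye in EYES) {
        vbit <- bitwAnd(as.integer(samples[[paste0(eye, "_validity")]]),
                        VALIDITY_BITS[["pupil_diameter"]]) > 0L
        pd <- samples[[paste0(eye, "_pupil_diameter_mm")]][in_task & vbit]
        pd <- pd[is.finite(pd)]
        sel <- metrics$task == task & metrics$eye == eye
        if (length(pd) && any(sel)) {
          metrics$pupil_diameter_mean_mm[sel] <- mean(pd)
          metrics$pupil_diameter_sd_mm[sel] <- sd(pd)
        }
      }
    }
  }
  class(metrics) <- c("task_metrics", "data.frame")
  metrics
}

#' Write task metrics as TSV and JSON
#'
#' The TSV mirrors the tabular metrics layout (one row per task x eye x
#' signal kind); the JSON adds the detection configuration and package
#' version so reports are self-describing.
#'
#' @param metrics a `task_metrics` data frame.
#' @param path_prefix output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param config the [detection_config()] used.
#' @return invisibly, the two paths.
#' @export
write_metrics <- function(metrics, path_prefix,
                          config = detection_config()) {
  tsv <- paste0(path_prefix, ".tsv")
  js <- paste0(path_prefix, ".json")
  write.table(metrics, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    software = list(package = "antisaccade",
                    version = as.character(packageVersion("antisaccade"))),
    detection_config = unclass(config),
    metrics = metrics
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(tsv = tsv, json = js))
}
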