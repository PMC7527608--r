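# End-to-end session analysis: cleaning -> angle conversion -> despiking
# -> segmentation -> velocity -> five-case detection -> aggregation.

#' Analyze a recorded (or simulated) session
#'
#' Runs the full detection pipeline for each requested eye and signal
#' kind: per-eye validity cleaning, gaze-vector to angle conversion (or
#' pupil-position extraction), whole-stream despiking with the order-10
#' running median, task-window segmentation around each trial event,
#' time-aware velocity, and the five-case classifier. Results are
#' aggregated into task metrics (with pupil summaries) and a sampling
#' diagnostic report.
#'
#' @param samples sample-log data frame ([read_samples()] or
#'   [simulate_session()]).
#' @param events [trial_events()] table.
#' @param config a [detection_config()].
#' @param eyes eyes to analyze.
#' @param signal_kinds signals to analyze (`gaze_deg` always carries peak
#'   velocity; `pupil_pos_x` yields latency and error rate only).
#' @param despike_order running-median order for the despiking filter.
#' @return list of class `session_analysis`: `trial_results` (one row per
#'   trial x eye x signal kind), `metrics` ([aggregate_metrics()]),
#'   `timing` ([timing_report()]), `config`.
#' @export
analyze_session <- function(samples, events, config = detection_config(),
                            eyes = c("left", "right"),
                            signal_kinds = c("gaze_deg", "pupil_pos_x"),
                            despike_order = 10L) {
  stopifnot(all(eyes %in% EYES), all(signal_kinds %in% SIGNAL_KINDS))
  results <- list()
  for (eye in eyes) {
    cleaned <- clean_samples(samples, eye)
    for (kind in signal_kinds) {
      stream <- signal_stream(cleaned, eye, kind)
      if (nrow(stream) > despike_order) {
        stream$value <- despike(stream$value, order = despike_order)
      }
      for (k in seq_len(nrow(events))) {
        w <- segment_trial(stream, events[k, ], signal_kind = kind,
                           eye = eye, config = config)
        w <- add_velocity(w)
        results[[length(results) + 1L]] <-
          classify_and_detect(w, config = config)
      }
    }
  }
  trial_results <- do.call(rbind, results)
  metrics <- aggregate_metrics(trial_results, samples = samples,
                               events = events)
  structure(list(
    trial_results = trial_results,
    metrics = metrics,
    timing = timing_report(samples),
    config = config
  ), class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("Session analysis: %d trial results\n",
              nrow(x$trial_results)))
  show <- x$metrics[x$metrics$eye == "both", c(
    "task", "signal_kind", "latency_mean_ms", "latency_sd_ms",
    "peak_velocity_mean_dps", "error_rate_pct", "reflexive_pct"
  )]
  print(show, digits = 4, row.names = FALSE)
  invisible(x)
}
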