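# Sampling-interval diagnostics: two-clock interval series, smoothing,
# warm-up stabilization, duplicate-frame detection, interval classes.

#' Inter-sample intervals
#'
#' First differences of a timestamp series, in ms. Negative deltas (a
#' non-monotone clock) are preserved -- a diagnostic must not hide faults
#' -- but flagged with a warning and the attribute `n_negative`.
#'
#' @param times_ms timestamp vector (>= 2 samples).
#' @return numeric vector of length `length(times_ms) - 1`.
#' @export
sample_intervals <- function(times_ms) {
  stopifnot(is.numeric(times_ms), length(times_ms) >= 2L)
  d <- diff(times_ms)
  nneg <- sum(d < 0)
  if (nneg > 0) {
    warning(sprintf("%d negative sampling interval(s): clock not monotone",
                    nneg), call. = FALSE)
  }
  attr(d, "n_negative") <- nneg
  d
}

#' Smooth an interval series
#'
#' Host-clock intervals are smoothed with a running median of order 10
#' (robust to the isolated long intervals the host scheduler produces);
#' device-clock intervals with a centered moving average of window 5 (the
#' device clock quantizes to integer ms, so averaging recovers the
#' underlying rate).
#'
#' @param deltas_ms interval series.
#' @param clock `"host"` (median, order 10) or `"device"` (moving
#'   average, window 5).
#' @param order,window filter parameters.
#' @return smoothed series of equal length.
#' @export
smooth_intervals <- function(deltas_ms, clock = c("host", "device"),
                             order = 10L, window = 5L) {
  clock <- match.arg(clock)
  if (clock == "host") {
    despike(deltas_ms, order = order)
  } else {
    moving_average_centered(as.numeric(deltas_ms), as.integer(window))
  }
}

#' Warm-up stabilization index
#'
#' First index of a sustained run (default 50 intervals, about 0.4 s at
#' 120 Hz) of smoothed intervals strictly below `threshold_ms`. A single
#' crossing does not qualify: the criterion marks a regime change, not
#' noise. Returns `NA_integer_` if the series never stabilizes.
#'
#' @param filtered_ms smoothed interval series.
#' @param threshold_ms stabilization threshold (default 8 ms).
#' @param run_length required run length (default 50).
#' @return 1-based index of the first interval of the run, or `NA`.
#' @export
stabilization_index <- function(filtered_ms, threshold_ms = 8,
                                run_length = 50L) {
  below <- filtered_ms < threshold_ms
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0L) return(NA_integer_)
  starts[hit[1]]
}

#' Detect duplicate frames
#'
#' Flags consecutive sample pairs that share the same device timestamp
#' AND frame sequence. Pairs whose remaining payload differs carry the
#' timestamp-bug signature (the tracker SDK re-served a frame header with
#' fresh eye data); pairs identical in every field are true double reads
#' of one frame.
#'
#' @param samples sample-log data frame.
#' @return data frame with `index` (row of the first member of each pair)
#'   and `type` (`"timestamp_bug"` or `"double_read"`).
#' @export
find_duplicates <- function(samples) {
  n <- nrow(samples)
  if (n < 2L) {
    return(data.frame(index = integer(0), type = character(0)))
  }
  i <- which(diff(samples$device_timestamp_ms) == 0 &
               diff(samples$frame_sequence) == 0)
  if (length(i) == 0L) {
    return(data.frame(index = integer(0), type = character(0)))
  }
  payload <- setdiff(names(samples),
                     c("device_timestamp_ms", "host_time_ms"))
  same_payload <- vapply(i, function(k) {
    isTRUE(all.equal(samples[k, payload], samples[k + 1L, payload],
                     check.attributes = FALSE))
  }, logical(1))
  data.frame(index = i,
             type = ifelse(same_payload, "double_read", "timestamp_bug"),
             stringsAsFactors = FALSE)
}

#' Classify device-clock intervals
#'
#' The integer-millisecond device clock yields intervals of 8 or 9 ms at
#' 120 Hz (the 8.33 ms period split by clock granularity) and 16 or 17 ms
#' when a frame is dropped. Intervals are rounded to the nearest integer
#' ms and counted into the classes 8, 9, 16, 17, and `other`.
#'
#' @param deltas_ms device-clock interval series.
#' @return named integer vector over `c("8","9","16","17","other")`,
#'   summing to `length(deltas_ms)`.
#' @export
classify_intervals <- function(deltas_ms) {
  r <- round(deltas_ms)
  classes <- c(8, 9, 16, 17)
  counts <- vapply(classes, function(c) sum(r == c), integer(1))
  out <- c(counts, length(r) - sum(counts))
  names(out) <- c("8", "9", "16", "17", "other")
  out
}

#' Full sampling-interval diagnostic report
#'
#' Computes, for both clocks of a sample log, the raw and smoothed
#' interval series, the warm-up stabilization index and time, the
#' duplicate-frame list, and the device-clock interval classes.
#'
#' @param samples sample-log data frame.
#' @param threshold_ms stabilization threshold (default 8 ms).
#' @param run_length sustained-run length for stabilization (default 50).
#' @return object of class `timing_report`: a list with per-clock
#'   `raw_intervals_ms` / `filtered_intervals_ms`, `stabilization_index`
#'   and `stabilization_time_s` (host clock, relative to the first
#'   sample), `duplicates`, and `interval_class_counts`.
#' @export
timing_report <- function(samples, threshold_ms = 8, run_length = 50L) {
  stopifnot(nrow(samples) >= 2L)
  raw <- list(
    host = suppressWarnings(sample_intervals(samples$host_time_ms)),
    device = suppressWarnings(sample_intervals(samples$device_timestamp_ms))
  )
  filt <- list(
    host = if (length(raw$host) > 10L) {
      smooth_intervals(raw$host, "host")
    } else raw$host,
    device = if (length(raw$device) > 5L) {
      smooth_intervals(raw$device, "device")
    } else raw$device
  )
  stab <- lapply(filt, stabilization_index, threshold_ms = threshold_ms,
                 run_length = run_length)
  stab_time <- lapply(names(stab), function(clk) {
    i <- stab[[clk]]
    if (is.na(i)) return(NA_real_)
    (samples$host_time_ms[i] - samples$host_time_ms[1]) / 1000
  })
  names(stab_time) <- names(stab)
  structure(list(
    n_samples = nrow(samples),
    raw_intervals_ms = raw,
    filtered_intervals_ms = filt,
    stabilization_index = stab,
    stabilization_time_s = stab_time,
    threshold_ms = threshold_ms,
    run_length = as.integer(run_length),
    duplicates = find_duplicates(samples),
    interval_class_counts = classify_intervals(raw$device)
  ), class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf("Sampling diagnostics over %d samples\n", x$n_samples))
  for (clk in c("host", "device")) {
    i <- x$stabilization_index[[clk]]
    cat(sprintf("  %s clock: stabilization (< %g ms for %d intervals): %s\n",
                clk, x$threshold_ms, x$run_length,
                if (is.na(i)) "not reached"
                else sprintf("index %d (t = %.1f s)", i,
                             x$stabilization_time_s[[clk]])))
  }
  cat(sprintf("  duplicate frames: %d (%d timestamp-bug, %d double-read)\n",
              nrow(x$duplicates),
              sum(x$duplicates$type == "timestamp_bug"),
              sum(x$duplicates$type == "double_read")))
  cat("  device interval classes [ms]:\n")
  print(x$interval_class_counts)
  invisible(x)
}

#' Write a timing report as JSON (and optionally the interval TSV)
#'
#' @param report a `timing_report`.
#' @param path_prefix output prefix; writes `<prefix>.json` and, if
#'   `intervals_tsv`, `<prefix>_intervals.tsv` with both clocks' raw and
#'   filtered series for plotting.
#' @param intervals_tsv also write the per-clock interval TSV.
#' @return invisibly, the path(s) written.
#' @export
write_timing_report <- function(report, path_prefix, intervals_tsv = FALSE) {
  js <- paste0(path_prefix, ".json")
  payload <- list(
    n_samples = report$n_samples,
    threshold_ms = report$threshold_ms,
    run_length = report$run_length,
    stabilization_index = report$stabilization_index,
    stabilization_time_s = report$stabilization_time_s,
    n_duplicates = nrow(report$duplicates),
    duplicate_types = as.list(table(report$duplicates$type)),
    interval_class_counts = as.list(report$interval_class_counts)
  )
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- js
  if (intervals_tsv) {
    tsv <- paste0(path_prefix, "_intervals.tsv")
    df <- data.frame(
      host_raw_ms = as.numeric(report$raw_intervals_ms$host),
      host_filtered_ms = as.numeric(report$filtered_intervals_ms$host),
      device_raw_ms = as.numeric(report$raw_intervals_ms$device),
      device_filtered_ms = as.numeric(report$filtered_intervals_ms$device)
    )
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tsv)
  }
  invisible(paths)
}
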