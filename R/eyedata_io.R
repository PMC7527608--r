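# Eye-sample and trial-event log I/O, and per-field validity bitmasks.
#
# A sample log has one row per recorded frame with two clocks (the
# tracker's own integer-millisecond timestamp, untrusted by default, and
# the host's Unix-derived clock in float milliseconds) and, per eye, the
# tracker's verbose output: a 5-bit validity mask, eye openness, pupil
# diameter, normalized pupil position, gaze origin and normalized gaze
# direction.

VALIDITY_FIELDS <- c("gaze_origin", "gaze_direction", "pupil_diameter",
                     "eye_openness", "pupil_position")
VALIDITY_BITS <- c(gaze_origin = 1L, gaze_direction = 2L,
                   pupil_diameter = 4L, eye_openness = 8L,
                   pupil_position = 16L)
VALID_ALL <- 31L

# Per-eye columns, in fixed file order.
eye_field_names <- function(eye) {
  paste0(eye, "_", c(
    "validity", "openness", "pupil_diameter_mm",
    "pupil_pos_x", "pupil_pos_y",
    "gaze_origin_x_mm", "gaze_origin_y_mm", "gaze_origin_z_mm",
    "gaze_dir_x", "gaze_dir_y", "gaze_dir_z"
  ))
}

#' Column layout of an eye-sample log
#'
#' @return character vector with the fixed column order of sample logs:
#'   `frame_sequence`, `device_timestamp_ms`, `host_time_ms`, then eleven
#'   per-eye fields for the left and the right eye.
#' @export
eye_sample_columns <- function() {
  c("frame_sequence", "device_timestamp_ms", "host_time_ms",
    eye_field_names("left"), eye_field_names("right"))
}

#' Decode / encode a per-eye validity bitmask
#'
#' Each recorded eye carries a 5-bit validity mask; bit values 1, 2, 4, 8,
#' 16 mark gaze origin, gaze direction, pupil diameter, eye openness and
#' pupil position as trustworthy. A fully valid sample has mask 31.
#'
#' @param v integer vector of bitmasks in \[0, 31\].
#' @param flags data frame or named logical vector (or list) with the five
#'   flag fields.
#' @return `decode_validity()` returns a data frame with one logical
#'   column per field; `encode_validity()` the integer bitmask(s).
#' @export
#' @examples
#' decode_validity(31)   # all five fields valid
#' encode_validity(data.frame(gaze_origin = TRUE, gaze_direction = FALSE,
#'                            pupil_diameter = TRUE, eye_openness = FALSE,
#'                            pupil_position = FALSE))  # 5
decode_validity <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v)) ||
      any(v < 0) || any(v > 31)) {
    stop_bad("validity bitmask must be an integer in [0, 31]")
  }
  v <- as.integer(v)
  out <- lapply(VALIDITY_BITS, function(b) bitwAnd(v, b) > 0L)
  as.data.frame(out)
}

#' @rdname decode_validity
#' @export
encode_validity <- function(flags) {
  if (is.logical(flags)) flags <- as.list(flags)
  if (!all(VALIDITY_FIELDS %in% names(flags))) {
    stop_bad("flags must name all of: %s",
             paste(VALIDITY_FIELDS, collapse = ", "))
  }
  acc <- 0L
  for (f in VALIDITY_FIELDS) {
    acc <- acc + VALIDITY_BITS[[f]] * as.integer(flags[[f]])
  }
  as.integer(acc)
}

validate_samples <- function(samples, file = NULL, line_offset = 1L) {
  need <- eye_sample_columns()
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop_bad("sample log is missing columns: %s", paste(miss, collapse = ", "))
  }
  where <- if (is.null(file)) "" else sprintf(" in '%s'", file)
  for (col in c("frame_sequence", "host_time_ms")) {
    bad <- which(!is.finite(samples[[col]]))
    if (length(bad) > 0) {
      stop_bad("malformed row%s: line %d has missing %s",
               where, bad[1] + line_offset, col)
    }
  }
  for (eye in EYES) {
    vcol <- paste0(eye, "_validity")
    v <- samples[[vcol]]
    bad <- which(!is.finite(v) | v < 0 | v > 31 | v != floor(v))
    if (length(bad) > 0) {
      stop_bad("malformed row%s: line %d has %s = %s (must be 0..31)",
               where, bad[1] + line_offset, vcol, format(v[bad[1]]))
    }
  }
  if (is.unsorted(samples$host_time_ms)) {
    warning("host_time_ms is not monotone non-decreasing; rows kept as read",
            call. = FALSE)
  }
  invisible(samples)
}

#' Write / read an eye-sample log
#'
#' Tab-separated, one row per frame, mandatory header, fixed column order
#' ([eye_sample_columns()]); unknown trailing columns are preserved
#' verbatim. Per-eye values whose validity bit is unset may be `NA`.
#' Doubles are written with 17 significant digits, so write-then-read is
#' the identity on every field. A `#`-prefixed header line records the
#' host-clock unit: the writer always stores float milliseconds, and the
#' reader also accepts logs whose host clock is raw 100-ns tick counts
#' (`host_time_unit = ticks`), converting them to milliseconds by 1e-4.
#'
#' @param samples data frame in sample-log layout.
#' @param path file path.
#' @return `write_samples()` returns `path` invisibly; `read_samples()`
#'   the validated samples data frame (host clock in ms).
#' @export
write_samples <- function(samples, path) {
  validate_samples(samples)
  extra <- setdiff(names(samples), eye_sample_columns())
  out <- samples[, c(eye_sample_columns(), extra), drop = FALSE]
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      s <- sprintf("%.17g", out[[col]])
      s[is.na(out[[col]])] <- "NA"
      out[[col]] <- s
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# antisaccade sample log; host_time_unit = ms", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_bad("sample log '%s' does not exist", path)
  first <- readLines(path, n = 1L)
  unit <- "ms"
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("host_time_unit\\s*=\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L) unit <- m[2]
  }
  df <- as.data.frame(data.table::fread(
    path, sep = "\t", skip = skip, header = TRUE, na.strings = "NA",
    showProgress = FALSE
  ))
  if (unit == "ticks") {
    df$host_time_ms <- df$host_time_ms / 1e4
  } else if (unit != "ms") {
    stop_bad("unknown host_time_unit '%s' in '%s'", unit, path)
  }
  # fixed column types: integer frame/validity, double everything else
  int_cols <- c("frame_sequence", "left_validity", "right_validity")
  for (col in intersect(eye_sample_columns(), names(df))) {
    df[[col]] <- if (col %in% int_cols) as.integer(df[[col]])
                 else as.numeric(df[[col]])
  }
  validate_samples(df, file = path, line_offset = skip + 1L)
  df
}

#' Build a trial-event table
#'
#' One row per analysis trial: when the lateral (red) target of trial `i`
#' appeared (`onset_host_time_ms`, host clock) and disappeared. The
#' stimulus is nominally shown for 1 s; events must not overlap.
#'
#' @param trial_index integer trial indices (0-based, protocol order).
#' @param task `"pro"` or `"anti"` per trial.
#' @param side `"right"` or `"left"` per trial.
#' @param onset_host_time_ms stimulus onset, host clock (ms).
#' @param offset_host_time_ms stimulus offset; defaults to onset + 1000 ms.
#' @return data frame of class `trial_events`, sorted by onset.
#' @export
trial_events <- function(trial_index, task, side, onset_host_time_ms,
                         offset_host_time_ms = onset_host_time_ms + 1000) {
  stopifnot(all(task %in% TASKS), all(side %in% SIDES))
  ev <- data.frame(
    trial_index = as.integer(trial_index),
    task = task, side = side,
    onset_host_time_ms = as.numeric(onset_host_time_ms),
    offset_host_time_ms = as.numeric(offset_host_time_ms),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$onset_host_time_ms), , drop = FALSE]
  rownames(ev) <- NULL
  if (any(ev$offset_host_time_ms <= ev$onset_host_time_ms)) {
    stop_bad("event offset must be after onset")
  }
  n <- nrow(ev)
  if (n > 1L &&
      any(ev$onset_host_time_ms[-1] < ev$offset_host_time_ms[-n])) {
    stop_bad("overlapping trial events: stimulus windows must be disjoint")
  }
  class(ev) <- c("trial_events", "data.frame")
  ev
}

#' Write / read a trial-event log
#'
#' TSV with columns `trial_index`, `task`, `side`, `onset_host_time_ms`,
#' `offset_host_time_ms`; events are validated (sorted, non-overlapping)
#' on both paths.
#'
#' @param events a `trial_events` data frame.
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   validated `trial_events`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "data.frame"))
  out <- events
  for (col in c("onset_host_time_ms", "offset_host_time_ms")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_bad("event log '%s' does not exist", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial_index", "task", "side", "onset_host_time_ms",
            "offset_host_time_ms")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_bad("event log '%s' is missing columns: %s", path,
             paste(miss, collapse = ", "))
  }
  trial_events(df$trial_index, df$task, df$side,
               df$onset_host_time_ms, df$offset_host_time_ms)
}
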