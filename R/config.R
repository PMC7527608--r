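# Minimal INI-style key-value config files used as sidecars for protocols,
# simulation runs, and analysis reports.

#' Write / read a flat key-value config file
#'
#' One `key = value` pair per line, `#` comments ignored. Values are kept
#' as strings on read; numeric fields are converted by the callers that
#' know their types. Numeric values are written with 17 significant digits
#' so they round-trip exactly.
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a named list of character scalars.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)), all(names(config) != ""))
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  lines <- vapply(names(config), function(n) {
    sprintf("%s = %s", n, fmt(config[[n]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_bad("config file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  trim <- function(s) gsub("^\\s+|\\s+$", "", s)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop_bad("malformed config line: '%s'", ln)
    }
    key <- trim(sub("=.*$", "", ln))
    val <- trim(sub("^[^=]*=", "", ln))
    if (key == "") stop_bad("malformed config line: '%s'", ln)
    out[[key]] <- val
  }
  out
}
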