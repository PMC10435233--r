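#' Uniformly sampled time series
#'
#' The universal signal carrier of the package: ROI luminosity, GCaMP
#' fluorescence and tail displacement are all handled as a uniformly sampled
#' series of (time, value) pairs. Time is in seconds, values are in arbitrary
#' units unless stated otherwise.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing and
#'   uniformly spaced (relative tolerance 1e-9 on the spacing).
#' @param v Numeric vector of sample values, same length as `t`.
#' @param label Optional character label (e.g. `"heart"`, `"atrium"`).
#' @return An object of class `"TimeSeries"`: a list with elements `t`, `v`,
#'   `fps` (samples per second) and `label`.
#' @examples
#' ts <- time_series(seq(0, 1, by = 0.1), sin(seq(0, 1, by = 0.1)))
#' ts$fps
#' @export
time_series <- function(t, v, label = NULL) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    stop("time and value vectors must have equal length", call. = FALSE)
  }
  if (length(t) < 2) {
    stop("a TimeSeries needs at least two samples", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > 1e-9 * max(step, 1))) {
    stop("sampling must be uniform (relative tolerance 1e-9)", call. = FALSE)
  }
  structure(
    list(t = t, v = v, fps = 1 / step, label = label),
    class = "TimeSeries"
  )
}

#' @export
print.TimeSeries <- function(x, ...) {
  cat(sprintf(
    "<TimeSeries%s: %d samples, %.6g fps, t = [%.4g, %.4g] s>\n",
    if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
    length(x$t), x$fps, x$t[1], x$t[length(x$t)]
  ))
  invisible(x)
}

#' @export
as.data.frame.TimeSeries <- function(x, ...) {
  data.frame(time_s = x$t, value = x$v)
}

#' @export
length.TimeSeries <- function(x) length(x$t)

is_time_series <- function(x) inherits(x, "TimeSeries")

#' Read a two-column trace CSV
#'
#' Reads a CSV with header columns `time_s` and `value` (comma separated,
#' `.` decimal, UTF-8). Leading lines starting with `#` (provenance headers
#' written by [write_trace_csv()]) are skipped. Non-uniform or non-monotone
#' time axes are rejected.
#'
#' @param path Path to the CSV file.
#' @param label Optional label attached to the returned series.
#' @return A [time_series()] object.
#' @export
read_trace_csv <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", check.names = TRUE)
  if (nrow(df) == 0) {
    stop("empty trace file (header only): ", path, call. = FALSE)
  }
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("trace CSV must have columns 'time_s' and 'value': ", path,
      call. = FALSE
    )
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$value))
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed row %d in %s (non-numeric or missing field)",
      bad[1], path
    ), call. = FALSE)
  }
  time_series(df$time_s, df$value, label = label)
}

#' Write a trace to CSV
#'
#' Writes `time_s,value` rows after an optional `# key: value` provenance
#' header. Full double precision is kept so that write/read round-trips are
#' lossless to better than 1e-12 relative error.
#'
#' @param ts A [time_series()] object.
#' @param path Output path.
#' @param header Named character vector written as `# name: value` comment
#'   lines before the CSV header (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(ts, path, header = NULL) {
  stopifnot(is_time_series(ts))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header), as.character(header)), con)
  }
  writeLines("time_s,value", con)
  writeLines(
    paste(
      formatC(ts$t, format = "g", digits = 17),
      formatC(ts$v, format = "g", digits = 17),
      sep = ","
    ),
    con
  )
  invisible(path)
}
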