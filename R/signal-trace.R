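#' Construct a uniformly sampled signal trace
#'
#' A signal trace is the package's container for one physiological channel
#' (plethysmograph airflow, EEG or EMG): a tibble with columns `time_s` and
#' `value`, plus attributes recording the sample rate, channel label and
#' physical units.
#'
#' @param samples numeric vector of samples in physical units.
#' @param rate_hz sample rate in Hz (> 0).
#' @param start_time_s time of the first sample, seconds from recording start.
#' @param label channel name.
#' @param units unit string (e.g. `"a.u."`, `"uV"`).
#' @return A tibble of class `signal_trace` with columns `time_s`, `value`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 2 * seq(0, 1, by = 0.01)), rate_hz = 100)
#' trace_rate(tr)
#' @export
signal_trace <- function(samples, rate_hz, start_time_s = 0,
                         label = "signal", units = "a.u.") {
  abort_if(!is.numeric(samples) || length(samples) < 1L,
           "`samples` must be a non-empty numeric vector")
  abort_if(!is.finite(rate_hz) || rate_hz <= 0, "`rate_hz` must be > 0")
  abort_if(any(!is.finite(samples)), "`samples` contains non-finite values")
  out <- tibble::tibble(
    time_s = start_time_s + (seq_along(samples) - 1) / rate_hz,
    value  = as.numeric(samples)
  )
  attr(out, "rate_hz") <- rate_hz
  attr(out, "label") <- label
  attr(out, "units") <- units
  class(out) <- c("signal_trace", class(out))
  out
}

#' @rdname signal_trace
#' @param trace a `signal_trace`.
#' @export
trace_rate <- function(trace) attr(trace, "rate_hz")

#' @rdname signal_trace
#' @export
trace_duration <- function(trace) nrow(trace) / trace_rate(trace)

#' Read a delimited time-series file into a signal trace
#'
#' Expects a delimited file with a time column (seconds) and a value column.
#' The sample rate is inferred from the median time step; sampling must be
#' uniform within 1% jitter.
#'
#' @param path file path.
#' @param time_col,value_col column names (defaults `time_s`, the second
#'   column for values).
#' @param label,units channel metadata for the returned trace.
#' @return A [signal_trace()].
#' @export
read_timeseries_csv <- function(path, time_col = "time_s", value_col = NULL,
                                label = "signal", units = "a.u.") {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  abort_if(!time_col %in% names(df),
           paste0("time column `", time_col, "` not found"))
  if (is.null(value_col)) value_col <- setdiff(names(df), time_col)[1]
  abort_if(is.na(value_col) || !value_col %in% names(df),
           "value column not found")
  t <- df[[time_col]]
  v <- df[[value_col]]
  abort_if(any(!is.finite(t)) || any(!is.finite(v)),
           "non-finite values in time-series file")
  abort_if(length(t) < 2L, "need at least 2 samples")
  dt <- diff(t)
  abort_if(any(dt <= 0), "time column must be strictly increasing")
  med <- stats::median(dt)
  abort_if(any(abs(dt - med) > 0.01 * med),
           "non-uniform sampling beyond 1% jitter")
  signal_trace(v, rate_hz = 1 / med, start_time_s = t[1],
               label = label, units = units)
}

#' Write a signal trace as a two-column CSV
#'
#' @param trace a [signal_trace()].
#' @param path output path.
#' @param value_col name of the value column (default `"flow"`, the airflow
#'   convention `time_s,flow`).
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(trace, path, value_col = "flow") {
  df <- tibble::tibble(time_s = trace$time_s)
  df[[value_col]] <- trace$value
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
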