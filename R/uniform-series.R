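#' Uniformly sampled time series
#'
#' The common currency of the pipeline: a numeric vector on a uniform time
#' grid (default 5 Hz) with a channel label and units. All derived
#' physiological and musical feature series share this representation and a
#' common session clock.
#'
#' @param values numeric vector, length >= 2, all finite
#' @param rate sampling rate in Hz (default 5)
#' @param start time of the first sample in seconds
#' @param channel channel label
#' @param units unit string (e.g. "s", "mmHg", "ms^2", "Hz")
#' @return object of class `uniform_series`
#' @export
uniform_series <- function(values, rate = 5, start = 0, channel = "", units = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("uniform_series needs length >= 2")
  if (!all(is.finite(values))) stop("uniform_series values must be finite")
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  structure(list(values = values, rate = rate, start = start,
                 channel = channel, units = units),
            class = "uniform_series")
}

#' Time stamps of a uniform series
#' @param x a `uniform_series`
#' @return numeric vector of sample times in seconds
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$start + (seq_along(x$values) - 1) / x$rate
}

#' Linear interpolation of a uniform series at arbitrary times
#' @param x a `uniform_series`
#' @param at times in seconds (must lie within the series support)
#' @param rule extrapolation rule passed to [stats::approx()]
#' @return numeric vector of interpolated values
#' @export
series_at <- function(x, at, rule = 2) {
  stats::approx(series_time(x), x$values, xout = at, rule = rule)$y
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> channel=%s units=%s rate=%g Hz n=%d [%.2f, %.2f] s\n",
              x$channel, x$units, x$rate, length(x$values),
              x$start, max(series_time(x))))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Mean of series values over a half-open time window
#'
#' @param x a `uniform_series`
#' @param from,to window bounds in seconds; samples with `from < t <= to`
#'   are used when `right = TRUE`, `from <= t < to` otherwise
#' @param right use the right-closed convention (post-event windows)
#' @return mean of the selected samples, or `NA` if none fall in the window
#' @export
series_window_mean <- function(x, from, to, right = TRUE) {
  t <- series_time(x)
  keep <- if (right) t > from & t <= to else t >= from & t < to
  if (!any(keep)) return(NA_real_)
  mean(x$values[keep])
}

# internal: common grid check
same_grid <- function(a, b, tol = 1e-9) {
  abs(a$rate - b$rate) < tol && abs(a$start - b$start) < tol &&
    length(a$values) == length(b$values)
}
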