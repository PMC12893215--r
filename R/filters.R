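# Butterworth IIR design (bilinear transform with frequency pre-warping) and
# zero-phase forward-backward filtering. Implemented here because no DSP
# package is assumed; verified against analytic magnitude responses in tests.

# polynomial coefficients from roots (complex), leading coefficient 1
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p) * rt
  p
}

#' Butterworth filter coefficients
#'
#' Designs a digital Butterworth low- or high-pass filter by bilinear
#' transform of the analog prototype, with cutoff pre-warping.
#'
#' @param order filter order (4 throughout the pipeline)
#' @param cutoff_hz cutoff frequency in Hz
#' @param rate sampling rate in Hz
#' @param type `"low"` or `"high"`
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1)
#' @export
butter_coeffs <- function(order, cutoff_hz, rate, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2)
    stop("cutoff must lie strictly inside (0, rate/2)")
  fs <- 2                                     # normalized bilinear rate
  wn <- cutoff_hz / (rate / 2)                # fraction of Nyquist
  warped <- 2 * fs * tan(pi * wn / fs)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LP prototype poles
  if (type == "low") {
    poles <- warped * proto
    zeros <- complex(0)
    gain <- warped^order
  } else {
    poles <- warped / proto
    zeros <- rep(0 + 0i, order)
    gain <- 1
  }
  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + poles) / (fs2 - poles)
  xd <- (fs2 + zeros) / (fs2 - zeros)
  gain <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  xd <- c(xd, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(poly_from_roots(xd)) * gain
  a <- Re(poly_from_roots(zd))
  list(b = b / a[1], a = a / a[1])
}

# steady-state initial filter state for a unit step (scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  n <- m - 1
  comp <- matrix(0, n, n)                     # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  iminusa <- diag(n) - t(comp)
  bvec <- b[-1] - a[-1] * b[1]
  solve(iminusa, bvec)
}

# single-pass IIR filter (zero or supplied initial state)
lfilter <- function(b, a, x, zi = NULL) {
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (is.null(zi)) zi <- rep(0, m - 1)
  .iir_filter(b, a, x, zi)
}

#' Zero-phase Butterworth filtering
#'
#' Applies the filter forward and backward (squaring the magnitude response,
#' cancelling phase) with odd-reflection end padding and steady-state initial
#' conditions, so change-point locations are not lagged by filtering.
#'
#' @param x numeric vector
#' @param b,a filter coefficients from [butter_coeffs()]
#' @return filtered vector, same length as `x`
#' @export
filtfilt <- function(x, b, a) {
  n <- length(x)
  padlen <- 3 * (max(length(a), length(b)) - 1)
  if (n <= padlen + 1)
    stop("series too short for zero-phase filtering (need > ", padlen + 1,
         " samples)")
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' High-pass filter an RR-interval series
#'
#' Removes very-low-frequency drift and the DC level from a uniformly
#' resampled RR series with a zero-phase 4th-order Butterworth high-pass
#' filter (default cutoff 0.03 Hz) ahead of spectral HRV analysis. The
#' series mean is removed before filtering so a constant input maps to an
#' exactly zero output.
#'
#' @param series a 5 Hz [uniform_series()] of RR values (seconds)
#' @param cutoff_hz high-pass cutoff in Hz
#' @param order filter order
#' @return detrended `uniform_series`
#' @export
highpass_rr <- function(series, cutoff_hz = 0.03, order = 4) {
  stopifnot(inherits(series, "uniform_series"))
  co <- butter_coeffs(order, cutoff_hz, series$rate, "high")
  y <- filtfilt(series$values - mean(series$values), co$b, co$a)
  uniform_series(y, rate = series$rate, start = series$start,
                 channel = series$channel, units = series$units)
}
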