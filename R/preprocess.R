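# Beat-wise to uniform-grid preprocessing: artifact filtering, tachogram
# resampling, respiration interval detection, blood-pressure channels.

#' Automated ectopic/artifact filtering of RR intervals
#'
#' Reproducible stand-in for manual ectopic-beat editing: a beat is removed
#' when its relative deviation from a 5-beat running median exceeds
#' `threshold` (default 25%). If more than `unreliable_frac` of beats are
#' removed the result is flagged unreliable.
#'
#' @param rr numeric vector of RR intervals in seconds (positive)
#' @param threshold relative deviation threshold
#' @param unreliable_frac removal fraction above which the result is flagged
#' @return list with `rr` (cleaned), `removed` (indices into the input),
#'   `unreliable` flag
#' @export
clean_rr <- function(rr, threshold = 0.25, unreliable_frac = 0.2) {
  if (any(rr <= 0)) stop("RR intervals must be positive")
  n <- length(rr)
  if (n < 5) return(list(rr = rr, removed = integer(0), unreliable = FALSE))
  med <- stats::runmed(rr, 5, endrule = "median")
  bad <- which(abs(rr - med) / med > threshold)
  out <- list(rr = if (length(bad)) rr[-bad] else rr, removed = bad,
              unreliable = length(bad) / n > unreliable_frac)
  if (out$unreliable)
    warning(sprintf("%.0f%% of beats removed; series flagged unreliable",
                    100 * length(bad) / n))
  out
}

#' Resample an RR tachogram to a uniform grid
#'
#' Cubic-spline interpolation of the beat-wise RR sequence (located at
#' cumulative beat-onset times) onto a uniform grid, endpoints held.
#'
#' @param rr RR intervals in seconds
#' @param rate target rate in Hz (default 5)
#' @param start session time of the first beat in seconds
#' @return a [uniform_series()] of RR values in seconds
#' @export
resample_rr <- function(rr, rate = 5, start = 0) {
  if (length(rr) < 4) stop("need at least 4 beats to resample")
  tb <- start + cumsum(c(0, rr[-length(rr)]))
  grid <- seq(start, tb[length(tb)], by = 1 / rate)
  f <- stats::splinefun(tb, rr, method = "natural")
  v <- f(grid)
  v[grid <= tb[1]] <- rr[1]                  # hold endpoints
  v[grid >= tb[length(tb)]] <- rr[length(rr)]
  uniform_series(v, rate = rate, start = start, channel = "rr", units = "s")
}

# simple local-maximum peak finder with a refractory distance
find_peaks <- function(x, min_dist) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > stats::median(x)]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || min(abs(keep - i)) >= min_dist) keep <- c(keep, i)
  sort(keep)
}

#' Respiratory interval detection
#'
#' Detrends the respiration waveform (linear fit removed), low-pass filters
#' it (zero-phase 4th-order Butterworth, 1 Hz cutoff), detects breath peaks
#' and returns peak-to-peak intervals plus the instantaneous respiratory
#' frequency Fr(t) interpolated on the uniform analysis grid.
#'
#' @param resp a [uniform_series()] respiration waveform (>= 5 Hz)
#' @param out_rate analysis grid rate in Hz
#' @param min_period_s shortest physiologically admissible breath period
#' @return list with `peak_times` (s), `intervals` (s, one per breath pair),
#'   `interval_series` (intervals on the grid), `fr` (Fr(t), Hz, on the grid)
#' @export
detect_resp_intervals <- function(resp, out_rate = 5, min_period_s = 1.5) {
  stopifnot(inherits(resp, "uniform_series"))
  if (resp$rate < 5) stop("respiration waveform must be sampled at >= 5 Hz")
  t <- series_time(resp)
  detr <- stats::lm.fit(cbind(1, t), resp$values)$residuals
  co <- butter_coeffs(4, 1, resp$rate, "low")
  filt <- filtfilt(detr, co$b, co$a)
  pk <- find_peaks(filt, min_dist = ceiling(min_period_s * resp$rate))
  if (length(pk) < 3) stop("no respiratory peaks found")
  # sub-sample refinement: parabola through the peak and its neighbours
  pt <- vapply(pk, function(i) {
    if (i <= 1 || i >= length(filt)) return(t[i])
    den <- filt[i - 1] - 2 * filt[i] + filt[i + 1]
    off <- if (abs(den) > 1e-12) 0.5 * (filt[i - 1] - filt[i + 1]) / den else 0
    t[i] + max(min(off, 0.5), -0.5) / resp$rate
  }, numeric(1))
  iv <- diff(pt)
  mid <- (pt[-1] + pt[-length(pt)]) / 2
  grid <- seq(resp$start, max(t), by = 1 / out_rate)
  ivg <- stats::approx(mid, iv, xout = grid, rule = 2)$y
  list(peak_times = pt, intervals = iv,
       interval_series = uniform_series(ivg, rate = out_rate,
                                        start = resp$start,
                                        channel = "resp", units = "s"),
       fr = uniform_series(1 / ivg, rate = out_rate, start = resp$start,
                           channel = "fr", units = "Hz"))
}

#' Blood-pressure channels on the uniform grid
#'
#' Computes beat-wise pulse pressure PP = SYS - DIA and interpolates all
#' three channels (cubic spline on beat times) onto the analysis grid.
#'
#' @param sys,dia aligned beat-wise systolic/diastolic pressures (mmHg)
#' @param beat_times beat times in seconds (same length)
#' @param rate analysis grid rate in Hz
#' @return named list of three [uniform_series()]: `sys`, `dia`, `pp`
#' @export
bp_channels <- function(sys, dia, beat_times, rate = 5) {
  stopifnot(length(sys) == length(dia), length(sys) == length(beat_times))
  bad <- which(sys <= dia)
  if (length(bad))
    stop("SYS <= DIA at beat index ", bad[1])
  grid <- seq(beat_times[1], beat_times[length(beat_times)], by = 1 / rate)
  onto <- function(v, ch) {
    f <- stats::splinefun(beat_times, v, method = "natural")
    g <- f(grid)
    g[grid <= beat_times[1]] <- v[1]
    g[grid >= beat_times[length(beat_times)]] <- v[length(v)]
    uniform_series(g, rate = rate, start = grid[1], channel = ch,
                   units = "mmHg")
  }
  list(sys = onto(sys, "sys"), dia = onto(dia, "dia"),
       pp = onto(sys - dia, "pp"))
}
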