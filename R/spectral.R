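# Time-varying spectral HRV: STFT spectrogram of the filtered RR series and
# instantaneous LF/HF band powers and peak frequencies, with the HF band
# centred on the instantaneous respiratory frequency Fr(t).

#' STFT spectrogram of an RR series
#'
#' Magnitude-squared short-time Fourier transform with a 50-sample Hamming
#' window and 50% overlap, scaled as a one-sided power spectral density in
#' ms^2/Hz (RR input in seconds is converted to ms).
#'
#' @param series filtered 5 Hz [uniform_series()] of RR values (seconds)
#' @param window_samples STFT window length (samples)
#' @param overlap_samples window overlap (samples); default 50%
#' @return object of class `spectrogram`: `time` (s), `freq` (Hz), `power`
#'   (freq x time matrix, ms^2/Hz), plus window metadata
#' @export
spectrogram_rr <- function(series, window_samples = 50,
                           overlap_samples = window_samples %/% 2) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values * 1000          # s -> ms
  n <- length(x)
  L <- window_samples
  if (n <= L) stop("series shorter than one STFT window")
  hop <- L - overlap_samples
  fs <- series$rate
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))   # Hamming
  starts <- seq(1, n - L + 1, by = hop)
  nf <- L %/% 2 + 1
  freq <- (0:(nf - 1)) * fs / L
  pw <- matrix(0, nf, length(starts))
  scale <- 1 / (fs * sum(w^2))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + L - 1)] * w
    sp <- stats::fft(seg)[1:nf]
    p <- Mod(sp)^2 * scale
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]       # one-sided density
    if (L %% 2 == 1) p[nf] <- 2 * p[nf]
    pw[, j] <- p
  }
  structure(list(time = series$start + (starts - 1 + (L - 1) / 2) / fs,
                 freq = freq, power = pw, window = L,
                 overlap = overlap_samples, rate = fs),
            class = "spectrogram")
}

#' Instantaneous LF/HF band powers and peak frequencies
#'
#' At each spectrogram time slice: PLF and FLF are the integrated power and
#' argmax frequency over the standard LF band (0.04-0.15 Hz); PHF and FHF
#' likewise over the respiration-guided HF band `Fr(t) +- hf_halfwidth`.
#' When `Fr(t) - hf_halfwidth` falls below 0.15 Hz the band keeps its
#' Fr-centred edges (it replaces, not intersects, the fixed band); when Fr
#' is missing the fixed 0.15-0.4 Hz band is used as fallback. Metrics are
#' interpolated back onto the uniform analysis grid.
#'
#' @param spec a `spectrogram` from [spectrogram_rr()]
#' @param fr instantaneous respiratory frequency as a [uniform_series()]
#'   (Hz), or `NULL` for the fixed-band fallback throughout
#' @param hf_halfwidth half-width of the HF band around Fr(t), Hz
#' @param out_rate analysis grid rate, Hz
#' @return object of class `band_metrics`: uniform series `plf`, `phf`
#'   (ms^2), `flf`, `fhf` (Hz), logical vector `hf_missing` per STFT slice
#' @export
band_metrics <- function(spec, fr = NULL, hf_halfwidth = 0.125, out_rate = 5) {
  stopifnot(inherits(spec, "spectrogram"))
  df <- spec$freq[2] - spec$freq[1]
  nt <- length(spec$time)
  frt <- if (is.null(fr)) rep(NA_real_, nt) else series_at(fr, spec$time)
  lf_bins <- which(spec$freq >= 0.04 & spec$freq <= 0.15)
  plf <- flf <- phf <- fhf <- rep(NA_real_, nt)
  hf_missing <- logical(nt)
  for (j in seq_len(nt)) {
    p <- spec$power[, j]
    if (length(lf_bins)) {
      plf[j] <- sum(p[lf_bins]) * df
      flf[j] <- spec$freq[lf_bins[which.max(p[lf_bins])]]
    }
    if (is.na(frt[j])) {
      lo <- 0.15; hi <- 0.4
    } else {
      lo <- max(frt[j] - hf_halfwidth, df / 2)   # keep Fr-centred lower edge
      hi <- frt[j] + hf_halfwidth
    }
    hf_bins <- which(spec$freq >= lo & spec$freq <= hi & spec$freq > 0)
    if (!length(hf_bins)) {
      hf_missing[j] <- TRUE
    } else {
      phf[j] <- sum(p[hf_bins]) * df
      fhf[j] <- spec$freq[hf_bins[which.max(p[hf_bins])]]
    }
  }
  grid <- seq(spec$time[1], spec$time[nt], by = 1 / out_rate)
  onto <- function(v, ch, un) {
    ok <- !is.na(v)
    if (sum(ok) < 2) stop("band metric '", ch, "' undefined almost everywhere")
    uniform_series(stats::approx(spec$time[ok], v[ok], xout = grid, rule = 2)$y,
                   rate = out_rate, start = grid[1], channel = ch, units = un)
  }
  structure(list(plf = onto(plf, "plf", "ms^2"),
                 phf = onto(phf, "phf", "ms^2"),
                 flf = onto(flf, "flf", "Hz"),
                 fhf = onto(fhf, "fhf", "Hz"),
                 hf_missing = hf_missing, stft_time = spec$time),
            class = "band_metrics")
}
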