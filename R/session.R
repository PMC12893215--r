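# Per-session derivation of the nine physiological analysis channels.

#' Derive the nine analysis channels for one listening session
#'
#' Chains the preprocessing stages: RR artifact filtering and 5 Hz
#' resampling; respiratory interval detection and Fr(t); blood-pressure
#' channels; high-pass RR filtering, STFT spectrogram and Fr-guided band
#' metrics.
#'
#' @param session one session of a `listener_record` (fields `rr`,
#'   `beat_times`, `resp`, `sys`, `dia`)
#' @param rate analysis grid rate in Hz
#' @return named list of nine [uniform_series()] (`rr`, `resp`, `sys`,
#'   `dia`, `pp`, `plf`, `phf`, `flf`, `fhf`) plus `fr` and the RR
#'   `unreliable` flag
#' @export
preprocess_session <- function(session, rate = 5) {
  cl <- clean_rr(session$rr)
  rr_s <- resample_rr(cl$rr, rate = rate, start = session$beat_times[1])
  resp <- detect_resp_intervals(session$resp, out_rate = rate)
  bp <- bp_channels(session$sys, session$dia, session$beat_times, rate = rate)
  hp <- highpass_rr(rr_s)
  spec <- spectrogram_rr(hp)
  bm <- band_metrics(spec, resp$fr, out_rate = rate)
  list(rr = rr_s, resp = resp$interval_series, sys = bp$sys, dia = bp$dia,
       pp = bp$pp, plf = bm$plf, phf = bm$phf, flf = bm$flf, fhf = bm$fhf,
       fr = resp$fr, unreliable = cl$unreliable)
}

#' Preprocess every session of a cohort
#'
#' @param cohort a `cohort` from [generate_cohort()]
#' @param rate analysis grid rate in Hz
#' @return list over listeners of lists over sessions of channel sets
#' @export
preprocess_cohort <- function(cohort, rate = 5) {
  lapply(cohort$listeners, function(l)
    lapply(l$sessions, preprocess_session, rate = rate))
}
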