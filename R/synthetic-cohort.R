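# Synthetic cohort generator. Emulates the four study inputs -- musical
# feature series, interpretation-map annotations, per-listener physiology,
# cohort manifest -- with planted ground truth: change points in every
# musical channel, event-locked physiological transients whose direction
# depends on the listener's baseline autonomic archetype, and three
# archetypes (parasympathetic-dominant, balanced, sympathetic-dominant).

# run expr under a derived seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(master, ...) {
  key <- 0
  for (k in list(...)) {
    kv <- if (is.character(k)) sum(utf8ToInt(k)) else as.numeric(k)
    key <- (key * 131 + kv) %% 1e6
  }
  as.integer((as.numeric(master) * 1000003 + key) %% 2147483629 + 1)
}

#' Simulation configuration
#'
#' Stated world of the synthetic cohort. Defaults emulate the study design:
#' eight pieces, nine-performance playlists whose first and last items are
#' different versions of the same piece, three baseline autonomic
#' archetypes, and event-locked physiological couplings whose direction
#' follows the archetype (parasympathetic-dominant listeners lengthen RR at
#' salient events, sympathetic-dominant listeners shorten it; respiratory
#' intervals shorten for everyone).
#'
#' Planted transient amplitudes are window-mean calibrated: an amplitude of
#' -0.15 s means the expected 10-s post-event window mean shifts by -0.15 s
#' relative to the pre-event window (see [response_kernel()]).
#'
#' @param n_pieces number of distinct pieces
#' @param piece_duration_s duration of each piece, seconds
#' @param n_listeners cohort size (>= 3 when three archetypes are mixed)
#' @param playlist_length performances per listener (default 9)
#' @param archetype_mix proportions over (pns, balanced, sns); must sum to 1
#' @param n_versions versions per piece (1 original + altered renditions)
#' @param noise_sd named per-channel white-noise SDs (channel units)
#' @param cps_per_channel planted change points per acoustic channel
#' @param step_snr planted step size as a multiple of the channel noise SD
#' @param annotation_counts named per-piece target counts over the retained
#'   interpretation-map categories
#' @param min_event_gap_s minimum gap between annotation events (>= 2x the
#'   event window so pre/post windows never overlap)
#' @param coupling_spec list of couplings, each a list with `category`
#'   (event category), `channel` (physiological channel), `amplitude`
#'   (channel units, window-mean calibrated), `latency_s`, and `sign` (named
#'   archetype multipliers)
#' @param resp_period_s mean respiratory period, seconds (0.25 Hz breathing)
#' @param seed master seed; every stage derives its own sub-seed from it
#' @return a `sim_config` object
#' @export
sim_config <- function(n_pieces = 8, piece_duration_s = 300, n_listeners = 12,
                       playlist_length = 9,
                       archetype_mix = c(pns = 0.2, balanced = 0.6, sns = 0.2),
                       n_versions = 2,
                       noise_sd = c(tempo = 4, loudness = 2,
                                    spectral_centroid = 100, mfcc = 0.5,
                                    diameter = 0.2),
                       cps_per_channel = 3, step_snr = 2,
                       annotation_counts = c("Novel Melody" = 3,
                                             "Significant Melody" = 3,
                                             "Return" = 2,
                                             "Melodic Interaction" = 2,
                                             "Standout Articulation" = 2,
                                             "Runs/Fast Sequence" = 1,
                                             "Resolve/Release" = 1),
                       min_event_gap_s = 20,
                       coupling_spec = default_coupling(),
                       resp_period_s = 4, seed = 1L) {
  if (piece_duration_s <= 0) stop("piece duration must be > 0")
  if (any(noise_sd < 0)) stop("noise SDs must be >= 0")
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    stop("archetype proportions must sum to 1")
  if (is.null(names(archetype_mix)))
    names(archetype_mix) <- c("pns", "balanced", "sns")
  if (playlist_length > n_pieces * n_versions)
    stop("playlist longer than the available performance pool")
  if (any(annotation_counts < 0)) stop("annotation counts must be >= 0")
  bad <- setdiff(names(annotation_counts), annotation_categories())
  if (length(bad)) stop("unknown annotation categories: ",
                        paste(bad, collapse = ", "))
  structure(list(n_pieces = n_pieces, piece_duration_s = piece_duration_s,
                 n_listeners = n_listeners, playlist_length = playlist_length,
                 archetype_mix = archetype_mix, n_versions = n_versions,
                 noise_sd = noise_sd, cps_per_channel = cps_per_channel,
                 step_snr = step_snr, annotation_counts = annotation_counts,
                 min_event_gap_s = min_event_gap_s,
                 coupling_spec = coupling_spec,
                 resp_period_s = resp_period_s, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default event-physiology couplings
#'
#' Novel melodies shorten respiratory intervals in every archetype and move
#' RR intervals in an archetype-dependent direction (lengthening for
#' parasympathetic-dominant, shortening for sympathetic-dominant
#' listeners). Amplitudes are free parameters of the synthetic world, not
#' estimates of any study effect.
#' @return list of coupling entries (see [sim_config()])
#' @export
default_coupling <- function() {
  list(list(category = "Novel Melody", channel = "resp", amplitude = -0.15,
            latency_s = 1, sign = c(pns = 1, balanced = 1, sns = 1)),
       list(category = "Novel Melody", channel = "rr", amplitude = 0.05,
            latency_s = 1, sign = c(pns = 1, balanced = 0.3, sns = -1)))
}

#' Gamma-shaped event response kernel
#'
#' Causal transient added to a physiological channel after a coupled event:
#' zero before `latency_s`, then a gamma-shaped bump (shape 2). The kernel
#' is normalized so that its mean over the standard 10-s post-event window
#' equals 1; a planted amplitude therefore equals the expected pre/post
#' window-mean difference measured by the event-response analysis. The
#' kernel decays to < 2% of its peak by 10 s so that events spaced 20 s
#' or more apart do not contaminate each other's windows.
#'
#' @param t times since event onset, seconds
#' @param latency_s response latency
#' @param shape,scale gamma shape/scale of the transient
#' @param window_s calibration window length
#' @return kernel values at `t`
#' @export
response_kernel <- function(t, latency_s = 1, shape = 2, scale = 1.5,
                            window_s = 10) {
  # window mean of the unnormalized gamma bump, in closed form:
  # (1/W) * integral_0^{W - latency} (u/s)^(k-1) exp(-u/s) du
  norm <- scale * gamma(shape) *
    stats::pgamma(window_s - latency_s, shape = shape, scale = scale) / window_s
  u <- t - latency_s
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- (u[pos] / scale)^(shape - 1) * exp(-u[pos] / scale) / norm
  out
}

# archetype parameter table (baseline RR mean, RSA amplitude, beat noise,
# resting blood pressure). RSA amplitude orders RMSSD: pns > balanced > sns.
archetype_params <- function(archetype) {
  switch(archetype,
    pns      = list(mean_rr = 1.00, rsa_amp = 0.060, beat_sd = 0.020,
                    sys = 115, dia = 72),
    balanced = list(mean_rr = 0.85, rsa_amp = 0.035, beat_sd = 0.015,
                    sys = 122, dia = 76),
    sns      = list(mean_rr = 0.70, rsa_amp = 0.012, beat_sd = 0.008,
                    sys = 132, dia = 84),
    stop("unknown archetype: ", archetype))
}

#' Generate one piece's musical feature set
#'
#' Each acoustic channel is a piecewise-constant mean process (steps of
#' `step_snr` x noise SD at planted change-point times, random sign) plus
#' white noise on the 5 Hz grid. Altered versions apply global gain/tempo
#' scalings to the original's channel values; planted change-point times
#' are version-invariant.
#'
#' @param config a [sim_config()]
#' @param piece_id integer piece id
#' @param version version number (1 = original)
#' @param planted optional explicit plan: data.frame with `time_s`,
#'   `channel`, `amplitude` (signed step height in channel units); when
#'   given, it replaces random placement for the listed channels
#' @return a `music_feature_set`: `piece_id`, `version`, `channels` (named
#'   list of [uniform_series()]), `truth_changepoints` (data.frame with
#'   `time_s`, `channel`, `direction`)
#' @export
generate_music <- function(config, piece_id, version = 1, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  base <- c(tempo = 100, loudness = 20, spectral_centroid = 1500, mfcc = 0,
            diameter = 1.2)
  dur <- config$piece_duration_s
  grid <- seq(0, dur, by = 0.2)
  with_seed(derive_seed(config$seed, "music", piece_id), {
    truth <- NULL
    channels <- list()
    for (ch in acoustic_channels()) {
      if (!is.null(planted)) {
        pl <- planted[planted$channel == ch, , drop = FALSE]
        times <- pl$time_s
        amps <- pl$amplitude
        k <- length(times)
      } else {
        k <- config$cps_per_channel
        times <- plant_times(k, dur, gap = 20, margin = 15)
        amps <- sample(c(-1, 1), k, replace = TRUE) * config$step_snr *
          max(config$noise_sd[[ch]], 1e-12)
      }
      signs <- sign(amps)
      sdv <- config$noise_sd[[ch]]
      mu <- rep(base[[ch]], length(grid))
      for (i in seq_len(k))
        mu[grid >= times[i]] <- mu[grid >= times[i]] + amps[i]
      v <- mu + stats::rnorm(length(grid), 0, sdv)
      channels[[ch]] <- uniform_series(v, rate = 5, start = 0, channel = ch,
                                       units = "")
      if (k > 0)
        truth <- rbind(truth, data.frame(time_s = times, channel = ch,
                                         direction = ifelse(signs > 0, "up", "down"),
                                         stringsAsFactors = FALSE))
    }
    # version alterations: global gain/tempo scalings, truth times unchanged
    if (version > 1) {
      gain <- 1 + 0.15 * (version - 1)
      channels$loudness$values <- channels$loudness$values * gain
      channels$tempo$values <- channels$tempo$values * (1 + 0.08 * (version - 1))
    }
    structure(list(piece_id = piece_id, version = version,
                   channels = channels,
                   truth_changepoints = truth),
              class = "music_feature_set")
  })
}

# k event times in [margin, dur - margin] with pairwise gaps >= gap
plant_times <- function(k, dur, gap, margin) {
  if (k == 0) return(numeric(0))
  slack <- dur - 2 * margin - (k - 1) * gap
  if (slack < 0)
    stop("cannot place ", k, " events with gap ", gap, " s in ", dur, " s")
  u <- sort(stats::runif(k, 0, slack))
  margin + u + (seq_len(k) - 1) * gap
}

#' Generate interpretation-map annotations for a piece
#'
#' Places the configured number of events per category with a minimum
#' inter-event gap of `min_event_gap_s` (>= twice the event window length),
#' so event-locked pre/post windows never overlap by construction.
#'
#' @param config a [sim_config()]
#' @param piece_id integer piece id
#' @return an `annotation_set`: `piece_id`, `events` (data.frame `onset_s`,
#'   `category`, strictly increasing onsets)
#' @export
generate_annotations <- function(config, piece_id) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$annotation_counts
  n <- sum(counts)
  with_seed(derive_seed(config$seed, "ann", piece_id), {
    events <- if (n == 0) {
      data.frame(onset_s = numeric(0), category = character(0),
                 stringsAsFactors = FALSE)
    } else {
      times <- plant_times(n, config$piece_duration_s,
                           gap = config$min_event_gap_s, margin = 12)
      cats <- sample(rep(names(counts), counts))
      data.frame(onset_s = times, category = cats, stringsAsFactors = FALSE)
    }
    structure(list(piece_id = piece_id, events = events),
              class = "annotation_set")
  })
}

# onsets of a (possibly directed) event category in one performance
event_onsets <- function(music, ann, category) {
  if (category %in% annotation_categories())
    return(ann$events$onset_s[ann$events$category == category])
  tc <- music$truth_changepoints
  m <- regmatches(category, regexec("^(.*)_(up|down)$", category))[[1]]
  if (length(m) == 3)
    return(tc$time_s[tc$channel == m[2] & tc$direction == m[3]])
  numeric(0)
}

#' Generate one listener's record
#'
#' Baseline RR (>= 5 min) is drawn from archetype-specific mean and
#' variability. Session signals per performance comprise: a respiration
#' waveform (slowly frequency-modulated oscillation near 1/`resp_period_s`
#' Hz) with truth breath intervals; beat-wise RR carrying respiratory sinus
#' arrhythmia at the instantaneous respiratory frequency plus AR(1) beat
#' noise; and beat-wise SYS/DIA with positive pulse pressure. Every coupled
#' event adds a causal [response_kernel()] transient to its channel with
#' the archetype's sign.
#'
#' @param config a [sim_config()]
#' @param listener_id integer id
#' @param archetype one of `"pns"`, `"balanced"`, `"sns"`
#' @param performances list of lists with `music` ([generate_music()]) and
#'   `ann` ([generate_annotations()]) for each playlist item
#' @return a `listener_record`
#' @export
generate_listener <- function(config, listener_id, archetype, performances) {
  pars <- archetype_params(archetype)
  with_seed(derive_seed(config$seed, "listener", listener_id), {
    baseline_rr <- make_rr_beats(320, pars, config, music = NULL, ann = NULL,
                                 archetype)
    demographics <- list(age = round(stats::runif(1, 21, 79)),
                         gender = sample(c("F", "M"), 1),
                         musician = stats::runif(1) < 0.21,
                         classical_pref = stats::runif(1) < 0.33)
    sessions <- lapply(performances, function(pf)
      make_session(config, pars, archetype, pf$music, pf$ann))
    structure(list(listener_id = listener_id, archetype = archetype,
                   baseline_rr = baseline_rr$rr,
                   demographics = demographics,
                   playlist = data.frame(
                     piece = vapply(performances, function(p) p$music$piece_id, 1),
                     version = vapply(performances, function(p) p$music$version, 1)),
                   sessions = sessions),
              class = "listener_record")
  })
}

# instantaneous respiratory period with coupled transients
resp_period_fun <- function(config, archetype, music, ann, fm_phase) {
  cs <- config$coupling_spec
  function(t) {
    p <- config$resp_period_s + 0.35 * sin(2 * pi * t / 63 + fm_phase)
    if (!is.null(music)) for (cp in cs) {
      if (cp$channel != "resp") next
      s <- unname(cp$sign[archetype]); if (!is.finite(s) || s == 0) next
      for (on in event_onsets(music, ann, cp$category))
        p <- p + cp$amplitude * s * response_kernel(t - on, cp$latency_s)
    }
    p
  }
}

# RR beat sequence over dur seconds; returns beats and their onset times.
# RSA rides on the respiration phase supplied by `phase_fun` (NULL =
# autonomous 0.25 Hz breathing during baseline).
make_rr_beats <- function(dur, pars, config, music, ann, archetype,
                          phase_fun = NULL) {
  cs <- config$coupling_spec
  t <- 0; rr <- numeric(0); tb <- numeric(0)
  e <- 0; phi <- 0.6
  nu_sd <- pars$beat_sd * sqrt(1 - phi^2)
  while (t < dur) {
    ph <- if (is.null(phase_fun)) 2 * pi * t / config$resp_period_s
          else phase_fun(t)
    val <- pars$mean_rr + pars$rsa_amp * sin(ph) + e
    if (!is.null(music)) for (cp in cs) {
      if (cp$channel != "rr") next
      s <- unname(cp$sign[archetype]); if (!is.finite(s) || s == 0) next
      for (on in event_onsets(music, ann, cp$category))
        if (t - on > 0 && t - on < 25)
          val <- val + cp$amplitude * s * response_kernel(t - on, cp$latency_s)
    }
    val <- min(max(val, 0.31), 1.99)
    rr <- c(rr, val); tb <- c(tb, t)
    t <- t + val
    e <- phi * e + stats::rnorm(1, 0, nu_sd)
  }
  list(rr = rr, beat_times = tb)
}

# one listening session: respiration waveform + truth intervals, RR beats,
# beat-wise SYS/DIA
make_session <- function(config, pars, archetype, music, ann) {
  dur <- config$piece_duration_s
  fm_phase <- stats::runif(1, 0, 2 * pi)
  pfun <- resp_period_fun(config, archetype, music, ann, fm_phase)
  dt <- 0.2
  tg <- seq(0, dur, by = dt)
  period <- pfun(tg)
  phase <- cumsum(2 * pi * dt / period)
  wave <- sin(phase) + stats::rnorm(length(tg), 0, 0.02)
  # truth breath boundaries: phase crossings of pi/2 + 2k pi (waveform peaks)
  peaks <- numeric(0)
  targ <- pi / 2
  for (i in seq_len(length(tg) - 1)) {
    while (phase[i + 1] >= targ) {
      frac <- (targ - phase[i]) / (phase[i + 1] - phase[i])
      peaks <- c(peaks, tg[i] + frac * dt)
      targ <- targ + 2 * pi
    }
  }
  phase_at <- stats::approxfun(tg, phase, rule = 2)
  beats <- make_rr_beats(dur, pars, config, music, ann, archetype,
                         phase_fun = phase_at)
  nb <- length(beats$rr)
  wander <- cumsum(stats::rnorm(nb, 0, 0.4)); wander <- wander - mean(wander)
  sys <- pars$sys + wander + stats::rnorm(nb, 0, 1.5)
  dia <- pars$dia + 0.6 * wander + stats::rnorm(nb, 0, 1.2)
  for (cp in config$coupling_spec) {
    if (!cp$channel %in% c("sys", "dia", "pp")) next
    s <- unname(cp$sign[archetype]); if (!is.finite(s) || s == 0) next
    for (on in event_onsets(music, ann, cp$category)) {
      k <- cp$amplitude * s * response_kernel(beats$beat_times - on, cp$latency_s)
      if (cp$channel == "sys") sys <- sys + k
      if (cp$channel == "dia") dia <- dia + k
      if (cp$channel == "pp") { sys <- sys + k / 2; dia <- dia - k / 2 }
    }
  }
  dia <- pmin(dia, sys - 15)               # PP > 0 everywhere
  list(piece_id = music$piece_id, version = music$version,
       rr = beats$rr, beat_times = beats$beat_times,
       resp = uniform_series(wave, rate = 1 / dt, start = 0,
                             channel = "resp_wave", units = "au"),
       truth_resp_intervals = diff(peaks), truth_resp_peaks = peaks,
       sys = sys, dia = dia)
}

#' Generate a full synthetic cohort
#'
#' Builds all pieces and versions, annotations, listener records with
#' archetype counts matching `archetype_mix` (largest-remainder rounding),
#' playlists whose first and last items are different versions of the same
#' piece, and a truth ledger recording every planted change point,
#' annotation event, coupling and archetype.
#'
#' @param config a [sim_config()]
#' @return a `cohort` object: `config`, `music` (piece -> version ->
#'   feature set), `annotations`, `listeners`, `performances` (data.frame),
#'   `truth` ledger
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_listeners < 3 && sum(config$archetype_mix > 0) == 3)
    stop("need at least 3 listeners for 3 archetypes")
  music <- lapply(seq_len(config$n_pieces), function(p)
    lapply(seq_len(config$n_versions), function(v)
      generate_music(config, p, v)))
  anns <- lapply(seq_len(config$n_pieces), function(p)
    generate_annotations(config, p))
  # archetype counts: largest remainder
  n <- config$n_listeners
  raw <- config$archetype_mix * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  archetypes <- rep(names(cnt), cnt)
  listeners <- vector("list", n)
  for (i in seq_len(n)) {
    pl <- make_playlist(config, i)
    perfs <- lapply(seq_len(nrow(pl)), function(j)
      list(music = music[[pl$piece[j]]][[pl$version[j]]],
           ann = anns[[pl$piece[j]]]))
    listeners[[i]] <- generate_listener(config, i, archetypes[i], perfs)
  }
  perf_tab <- unique(do.call(rbind, lapply(listeners, `[[`, "playlist")))
  perf_tab <- perf_tab[order(perf_tab$piece, perf_tab$version), ]
  rownames(perf_tab) <- NULL
  truth <- list(
    changepoints = do.call(rbind, lapply(seq_len(config$n_pieces), function(p)
      cbind(piece = p, music[[p]][[1]]$truth_changepoints))),
    annotations = do.call(rbind, lapply(anns, function(a)
      if (nrow(a$events)) cbind(piece = a$piece_id, a$events) else NULL)),
    couplings = config$coupling_spec,
    archetypes = data.frame(listener = seq_len(n), archetype = archetypes,
                            stringsAsFactors = FALSE))
  structure(list(config = config, music = music, annotations = anns,
                 listeners = listeners, performances = perf_tab,
                 truth = truth),
            class = "cohort")
}

# playlist: first and last are different versions of the same piece; the
# bookend piece cycles over pieces so all versions get listeners
make_playlist <- function(config, listener_id) {
  np <- config$n_pieces; L <- config$playlist_length
  bookend <- ((listener_id - 1) %% np) + 1
  with_seed(derive_seed(config$seed, "playlist", listener_id), {
    if (L < 2)
      return(data.frame(piece = bookend, version = 1))
    others <- setdiff(seq_len(np), bookend)
    mid <- if (length(others))
      sample(others, max(0, min(L - 2, length(others)))) else integer(0)
    v2 <- if (config$n_versions > 1) 2 else 1
    data.frame(piece = c(bookend, mid, bookend),
               version = c(1, rep(1, length(mid)), v2))
  })
}
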