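# Ensemble change-point detection: two detector families (Gaussian
# mean-shift, empirical-distribution nonparametric) x two segmentation
# methods (PELT, binary segmentation) run over a grid of penalties,
# normalization options and sampling resolutions; per-configuration onsets
# are pooled into an occurrence-probability series, thresholded, and merged
# under a minimum-spacing constraint.

#' Detector configuration
#'
#' One cell of the ensemble grid.
#'
#' @param family `"mean"` (Gaussian mean-shift cost) or `"nonparametric"`
#'   (empirical-CDF cost over ceiling(log n) quantile bins, rank-based)
#' @param method `"pelt"` (exact pruned dynamic programming) or `"binseg"`
#' @param penalty_mult segmentation penalty as a multiple of log n
#'   (1 = BIC-like)
#' @param normalize for the mean family: estimate the noise scale robustly
#'   (MAD of first differences) rather than by the sample SD of differences
#' @param resolution_hz sampling resolution the series is decimated to
#'   before detection; must divide the series rate
#' @return a `detector_config` object
#' @export
detector_config <- function(family = c("mean", "nonparametric"),
                            method = c("pelt", "binseg"),
                            penalty_mult = 2, normalize = TRUE,
                            resolution_hz = 5) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (penalty_mult <= 0) stop("penalty must be > 0")
  structure(list(family = family, method = method,
                 penalty_mult = penalty_mult, normalize = normalize,
                 resolution_hz = resolution_hz), class = "detector_config")
}

#' Default ensemble detector grid
#'
#' The default 64-configuration grid: both families x both methods x
#' penalties (0.5, 1, 2, 3) x log n x normalization on/off x resolutions
#' 5 Hz and 1 Hz.
#'
#' @param penalty_mults penalty multipliers of log n
#' @param resolutions_hz sampling resolutions in Hz
#' @return list of [detector_config()] objects
#' @export
detector_grid <- function(penalty_mults = c(0.5, 1, 2, 3),
                          resolutions_hz = c(5, 1)) {
  g <- expand.grid(family = c("mean", "nonparametric"),
                   method = c("pelt", "binseg"),
                   pen = penalty_mults, norm = c(TRUE, FALSE),
                   res = resolutions_hz, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    detector_config(g$family[i], g$method[i], g$pen[i], g$norm[i], g$res[i]))
}

# decimate a uniform series to a lower resolution by block means
decimate_values <- function(series, resolution_hz) {
  if (abs(resolution_hz - series$rate) < 1e-9) return(series$values)
  fac <- series$rate / resolution_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop("resolution must divide the series rate")
  fac <- as.integer(round(fac))
  v <- series$values
  nb <- length(v) %/% fac
  colMeans(matrix(v[seq_len(nb * fac)], nrow = fac))
}

#' Single-configuration mean-shift detection
#'
#' Segmentation minimizing the Gaussian mean-shift cost plus penalty,
#' solved exactly by PELT or approximately by binary segmentation. The
#' series is scaled by a noise-SD estimate from first differences so that
#' log-n penalties are unit-free.
#'
#' @param series a [uniform_series()]
#' @param config a [detector_config()] with `family = "mean"`
#' @return numeric vector of onset times in seconds
#' @export
detect_mean <- function(series, config = detector_config("mean")) {
  x <- decimate_values(series, config$resolution_hz)
  if (!all(is.finite(x))) stop("non-finite values in series")
  if (length(x) < 10) stop("series too short at this resolution")
  d <- diff(x)
  sig <- if (config$normalize) stats::mad(d) / sqrt(2) else stats::sd(d) / sqrt(2)
  if (!is.finite(sig) || sig <= 0) sig <- max(stats::sd(x), .Machine$double.eps)
  beta <- config$penalty_mult * log(length(x))
  idx <- if (config$method == "pelt")
    .cpt_mean_pelt(x / sig, beta) else .cpt_mean_binseg(x / sig, beta)
  series$start + idx / config$resolution_hz
}

#' Single-configuration nonparametric detection
#'
#' Segmentation under the empirical-distribution cost (nonparametric
#' likelihood over K = ceiling(log n) quantile bins); rank-based, hence
#' invariant under monotone transforms of the data. Because each segment
#' contributes K binomial likelihood terms, the penalty is scaled per
#' parameter: beta = penalty_mult x K x log n (so penalty_mult = 1 is
#' BIC-like for this cost, on the same footing as the mean family).
#'
#' @inheritParams detect_mean
#' @return numeric vector of onset times in seconds
#' @export
detect_np <- function(series, config = detector_config("nonparametric")) {
  x <- decimate_values(series, config$resolution_hz)
  if (!all(is.finite(x))) stop("non-finite values in series")
  if (length(x) < 10) stop("series too short at this resolution")
  if (config$normalize) x <- (x - mean(x)) / max(stats::sd(x), 1e-12)
  K <- ceiling(log(length(x)))
  beta <- config$penalty_mult * K * log(length(x))
  idx <- if (config$method == "pelt")
    .cpt_np_pelt(x, beta) else .cpt_np_binseg(x, beta)
  series$start + idx / config$resolution_hz
}

detect_one <- function(series, config) {
  if (config$family == "mean") detect_mean(series, config)
  else detect_np(series, config)
}

#' Ensemble consensus change-point detection
#'
#' Runs every configuration in the grid, accumulates onsets into a
#' time-binned occurrence frequency (each configuration votes for all times
#' within `tolerance` of its onsets), keeps local maxima whose frequency
#' reaches the consensus threshold, and merges onsets closer than
#' `min_spacing` to their frequency-weighted mean time.
#'
#' @param series a [uniform_series()]
#' @param grid list of [detector_config()]s (default [detector_grid()])
#' @param consensus threshold tau in (0, 1]: minimum fraction of
#'   configurations supporting an onset
#' @param min_spacing delta, minimum spacing between reported onsets (s)
#' @param tolerance vote window half-width (s)
#' @param direction_window window length for the direction label (s)
#' @return a `change_point_set` data.frame: `channel`, `onset_s`,
#'   `probability`, `direction`, `category`, `flagged`
#' @export
ensemble_detect <- function(series, grid = detector_grid(), consensus = 0.5,
                            min_spacing = 5, tolerance = 1,
                            direction_window = 10) {
  if (!length(grid)) stop("empty detector grid")
  if (consensus <= 0 || consensus > 1) stop("consensus must be in (0, 1]")
  if (min_spacing <= 0) stop("min_spacing must be > 0")
  onsets_by_cfg <- lapply(grid, function(cfg) detect_one(series, cfg))
  tmax <- max(series_time(series))
  bins <- seq(series$start, tmax, by = 0.2)
  freq <- numeric(length(bins))
  for (ons in onsets_by_cfg) {
    if (!length(ons)) next
    hit <- vapply(bins, function(b) any(abs(ons - b) <= tolerance), logical(1))
    freq <- freq + hit
  }
  freq <- freq / length(grid)
  all_onsets <- unlist(onsets_by_cfg)
  above <- freq >= consensus
  cand_t <- numeric(0); cand_p <- numeric(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      lo <- bins[starts[k]] - tolerance; hi <- bins[ends[k]] + tolerance
      contrib <- all_onsets[all_onsets >= lo & all_onsets <= hi]
      cand_t <- c(cand_t, if (length(contrib)) mean(contrib)
                  else mean(bins[starts[k]:ends[k]]))
      cand_p <- c(cand_p, max(freq[starts[k]:ends[k]]))
    }
  }
  # delta-merge to frequency-weighted mean times
  w <- cand_p
  ord <- order(cand_t); cand_t <- cand_t[ord]; cand_p <- cand_p[ord]; w <- w[ord]
  while (length(cand_t) > 1 && min(diff(cand_t)) < min_spacing) {
    i <- which.min(diff(cand_t))
    tm <- (cand_t[i] * w[i] + cand_t[i + 1] * w[i + 1]) / (w[i] + w[i + 1])
    pm <- max(cand_p[i], cand_p[i + 1]); wm <- w[i] + w[i + 1]
    cand_t <- c(cand_t[seq_len(i - 1)], tm, cand_t[-seq_len(i + 1)])
    cand_p <- c(cand_p[seq_len(i - 1)], pm, cand_p[-seq_len(i + 1)])
    w <- c(w[seq_len(i - 1)], wm, w[-seq_len(i + 1)])
  }
  dirs <- directionize(series, cand_t, w = direction_window)
  cat_lab <- if (length(cand_t))
    paste0(series$channel, ifelse(dirs$direction == "up", "_up", "_down"))
  else character(0)
  out <- data.frame(channel = rep(series$channel, length(cand_t)),
                    onset_s = cand_t, probability = cand_p,
                    direction = dirs$direction, category = cat_lab,
                    flagged = dirs$flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("change_point_set", "data.frame")
  out
}

#' Direction labels for change points
#'
#' Labels each onset up/down by the sign of (mean over `w` seconds after)
#' minus (mean over `w` seconds before). Onsets too close to an edge use
#' truncated windows and are flagged; an exact zero difference is labelled
#' up and flagged (deterministic tie rule).
#'
#' @param series a [uniform_series()]
#' @param onsets onset times in seconds, within the series support
#' @param w window length in seconds
#' @return list with character `direction` ("up"/"down"), numeric `diff`,
#'   logical `flagged`
#' @export
directionize <- function(series, onsets, w = 10) {
  t0 <- series$start; t1 <- max(series_time(series))
  if (length(onsets) && (any(onsets < t0) || any(onsets > t1)))
    stop("onset outside series support")
  n <- length(onsets)
  dirs <- character(n); dif <- numeric(n); flg <- logical(n)
  for (i in seq_len(n)) {
    on <- onsets[i]
    trunc <- on - w < t0 || on + w > t1
    pre <- series_window_mean(series, max(on - w, t0), on, right = FALSE)
    post <- series_window_mean(series, on, min(on + w, t1), right = TRUE)
    d <- post - pre
    dirs[i] <- if (isTRUE(d < 0)) "down" else "up"
    dif[i] <- d
    flg[i] <- trunc || isTRUE(d == 0) || is.na(d)
  }
  list(direction = dirs, diff = dif, flagged = flg)
}

#' F1 score of detected onsets against planted truth
#'
#' Greedy one-to-one matching within a temporal tolerance; used to score
#' detector operating characteristics on synthetic series.
#'
#' @param detected,truth onset times in seconds
#' @param tol matching tolerance in seconds
#' @return list with `precision`, `recall`, `f1`, `matched`
#' @export
changepoint_f1 <- function(detected, truth, tol = 2) {
  matched <- 0L
  avail <- detected
  for (tt in truth) {
    if (!length(avail)) break
    j <- which.min(abs(avail - tt))
    if (abs(avail[j] - tt) <= tol) { matched <- matched + 1L; avail <- avail[-j] }
  }
  prec <- if (length(detected)) matched / length(detected) else
    as.numeric(length(truth) == 0)
  rec <- if (length(truth)) matched / length(truth) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, matched = matched)
}
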