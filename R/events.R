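# Event-locked pre/post difference analysis: physiological window means
# around musical change points, normality-gated paired tests, Bonferroni
# control over all category x signal combinations.

#' Pre/post window difference at an event onset
#'
#' mean over (onset, onset + w\] minus mean over \[onset - w, onset). Returns
#' `NA` when either full window does not fit inside the recording (such
#' events are skipped and counted upstream).
#'
#' @param series a [uniform_series()]
#' @param onset event time in seconds
#' @param w window length in seconds
#' @return difference in the series' units, or `NA`
#' @export
window_diff <- function(series, onset, w = 10) {
  t0 <- series$start; t1 <- max(series_time(series))
  if (onset - w < t0 - 1e-9 || onset + w > t1 + 1e-9) return(NA_real_)
  series_window_mean(series, onset, onset + w, right = TRUE) -
    series_window_mean(series, onset - w, onset, right = FALSE)
}

#' Normality-gated paired test of event differences
#'
#' Shapiro-Wilk on the differences at `normality_alpha`: normal
#' distributions use the paired t-test (one-sample t on differences),
#' otherwise the Wilcoxon signed-rank test. Two-sided.
#'
#' @param diffs per-(participant, event) differences (n >= 5)
#' @param normality_alpha Shapiro-Wilk gate level
#' @return list: `statistic`, `p`, `test` ("paired-t"/"wilcoxon"),
#'   `degenerate` flag (all differences zero)
#' @export
category_test <- function(diffs, normality_alpha = 0.05) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 5) stop("need >= 5 paired differences")
  if (all(diffs == 0))
    return(list(statistic = 0, p = 1, test = "degenerate", degenerate = TRUE))
  ns <- length(diffs)
  swp <- stats::shapiro.test(if (ns > 4999) sample(diffs, 4999) else diffs)$p.value
  if (swp > normality_alpha) {
    tt <- stats::t.test(diffs)
    list(statistic = unname(tt$statistic), p = tt$p.value, test = "paired-t",
         degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(diffs))
    list(statistic = unname(wt$statistic), p = wt$p.value, test = "wilcoxon",
         degenerate = FALSE)
  }
}

#' Bonferroni-corrected significance threshold
#' @param alpha family-wise level
#' @param m number of comparisons
#' @return per-comparison threshold alpha / m
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 153) alpha / m

# 95% CI: t-interval when the t-test was used, bootstrap percentile otherwise
diff_ci <- function(diffs, test, boot_n = 1000, seed = 1L, level = 0.95) {
  diffs <- diffs[is.finite(diffs)]
  m <- mean(diffs)
  if (test == "paired-t") {
    se <- stats::sd(diffs) / sqrt(length(diffs))
    hw <- stats::qt(1 - (1 - level) / 2, length(diffs) - 1) * se
    c(m - hw, m + hw)
  } else {
    bs <- with_seed(seed, vapply(seq_len(boot_n), function(b)
      mean(sample(diffs, replace = TRUE)), numeric(1)))
    unname(stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
}

#' Event-locked difference table
#'
#' For each (category, physiological signal) cell: pools per-(listener,
#' event) window differences, applies [category_test()], and assigns a
#' significance tier -- `significant` at the Bonferroni threshold over all
#' m = categories x signals cells, `trend` at p < alpha, `none` otherwise.
#'
#' @param diffs_by_cell named list (category -> signal -> numeric vector of
#'   differences); build with [collect_event_diffs()]
#' @param w window length (recorded in the table)
#' @param alpha family-wise level before correction
#' @param categories,signals cell universe (defaults: the 17 musical
#'   categories and 9 physiological channels, m = 153)
#' @param seed seed for bootstrap CIs
#' @return `event_diff_table` data.frame: category, signal, n, skipped,
#'   mean_diff, ci_lo, ci_hi, test, p, tier, window_s
#' @export
event_diff_table <- function(diffs_by_cell, w = 10, alpha = 0.05,
                             categories = event_categories(),
                             signals = physio_channels(), seed = 1L) {
  m <- length(categories) * length(signals)
  thr <- bonferroni_alpha(alpha, m)
  rows <- list()
  for (cat in categories) for (sig in signals) {
    d <- diffs_by_cell[[cat]][[sig]]
    nall <- length(d)
    d <- d[is.finite(d)]
    skipped <- nall - length(d)
    if (length(d) < 5) {
      rows[[length(rows) + 1]] <- data.frame(
        category = cat, signal = sig, n = length(d), skipped = skipped,
        mean_diff = if (length(d)) mean(d) else NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, test = NA_character_,
        p = NA_real_, tier = "none", window_s = w)
      next
    }
    ct <- category_test(d)
    ci <- diff_ci(d, ct$test, seed = seed)
    tier <- if (is.na(ct$p)) "none" else if (ct$p <= thr) "significant"
            else if (ct$p < alpha) "trend" else "none"
    rows[[length(rows) + 1]] <- data.frame(
      category = cat, signal = sig, n = length(d), skipped = skipped,
      mean_diff = mean(d), ci_lo = ci[1], ci_hi = ci[2], test = ct$test,
      p = ct$p, tier = tier, window_s = w)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("event_diff_table", "data.frame")
  out
}

#' Collect event-locked differences across a cohort
#'
#' Pools window differences per (category, signal) cell over all listeners,
#' sessions and event onsets. Pairing unit: one difference per (listener,
#' event); a per-listener-mean alternative is available via `pool`.
#'
#' @param channel_sets list over listeners of lists over sessions of named
#'   9-channel lists of [uniform_series()]
#' @param events_fn function(listener_index, session_index, category) ->
#'   onset times in seconds
#' @param w window length, seconds
#' @param categories,signals cell universe
#' @param pool `"event"` (default) or `"listener"` (mean per listener first)
#' @return nested list category -> signal -> numeric vector (NAs mark
#'   skipped edge events)
#' @export
collect_event_diffs <- function(channel_sets, events_fn, w = 10,
                                categories = event_categories(),
                                signals = physio_channels(),
                                pool = c("event", "listener")) {
  pool <- match.arg(pool)
  out <- stats::setNames(vector("list", length(categories)), categories)
  for (cat in categories) {
    out[[cat]] <- stats::setNames(vector("list", length(signals)), signals)
    for (sig in signals) {
      per_listener <- list()
      for (li in seq_along(channel_sets)) {
        dl <- numeric(0)
        for (si in seq_along(channel_sets[[li]])) {
          ser <- channel_sets[[li]][[si]][[sig]]
          if (is.null(ser)) next
          ons <- events_fn(li, si, cat)
          if (length(ons))
            dl <- c(dl, vapply(ons, function(on) window_diff(ser, on, w),
                               numeric(1)))
        }
        per_listener[[li]] <- dl
      }
      out[[cat]][[sig]] <- if (pool == "event") unlist(per_listener)
        else vapply(Filter(function(v) any(is.finite(v)), per_listener),
                    function(v) mean(v, na.rm = TRUE), numeric(1))
    }
  }
  out
}

#' Run the event-response analysis at several window lengths
#'
#' @inheritParams collect_event_diffs
#' @param windows window lengths in seconds (default 8, 10, 12 for the
#'   sensitivity analysis)
#' @param alpha family-wise level
#' @param seed bootstrap seed
#' @return named list of [event_diff_table()]s, one per window length
#' @export
run_event_response <- function(channel_sets, events_fn,
                               windows = c(8, 10, 12), alpha = 0.05,
                               categories = event_categories(),
                               signals = physio_channels(), seed = 1L) {
  stats::setNames(lapply(windows, function(w) {
    d <- collect_event_diffs(channel_sets, events_fn, w, categories, signals)
    event_diff_table(d, w = w, alpha = alpha, categories = categories,
                     signals = signals, seed = seed)
  }), paste0("w", windows))
}
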