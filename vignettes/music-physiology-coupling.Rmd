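---
title: "Change-point-driven analysis of music-physiology coupling"
author: "musicphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change-point-driven analysis of music-physiology coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musicphys)
```

## The model

Expressive music does not act on the autonomic nervous system as a constant
"relaxing" influence; it acts through discrete events — a novel melody, a
tempo shift, a swell in loudness. `musicphys` implements an event-based
analysis that treats *change points* — times at which the distributional
properties of a signal shift — as the common currency of musical and
physiological dynamics, and then asks how the two event streams co-vary.

The pipeline has five stages.

1. **Signal preparation.** All signals live on a uniform 5 Hz grid
   (`uniform_series`). Beat-wise RR intervals are artifact-filtered
   (`clean_rr`), spline-resampled (`resample_rr`), and high-pass filtered at
   0.03 Hz with a zero-phase 4th-order Butterworth filter (`highpass_rr`).
   Respiration is detrended, low-pass filtered at 1 Hz, and reduced to breath
   intervals and an instantaneous respiratory frequency Fr(t)
   (`detect_resp_intervals`). Blood pressure contributes SYS, DIA and pulse
   pressure PP = SYS − DIA (`bp_channels`). A 50-sample Hamming STFT
   (`spectrogram_rr`) yields instantaneous LF/HF band powers and peak
   frequencies (`band_metrics`); the HF band is *time-varying*,
   Fr(t) ± 0.125 Hz, so respiratory sinus arrhythmia is integrated over the
   band where it actually lives rather than a fixed 0.15–0.4 Hz window. The
   nine physiological analysis channels are RR, respiratory intervals, SYS,
   DIA, PP, PLF, PHF, FLF, FHF.

2. **Ensemble change-point detection** (`ensemble_detect`). Two detector
   families — a Gaussian mean-shift cost (`detect_mean`) and a rank-based
   empirical-distribution cost over ⌈log n⌉ quantile levels (`detect_np`) —
   are each run with PELT (exact pruned dynamic programming) and binary
   segmentation over a grid of penalties, normalization options and sampling
   resolutions (64 configurations by default, `detector_grid()`). Onsets are
   pooled into an occurrence-frequency series (each configuration votes for
   all times within ±1 s of its onsets); local maxima with consensus ≥ τ
   (default 0.5) are retained, and onsets closer than δ = 5 s are merged to
   their frequency-weighted mean time. Consensus across many
   parameterizations, rather than any single tuned detector, is what makes
   the detected events reproducible.

3. **Gaussian-kernel event densities and the CCA matrices** (`gkf`,
   `assemble_cca_inputs`). Every change point contributes a unit-peak
   Gaussian bump (σ = 2 s by default); their sum is a continuous
   event-proximity series per channel or annotation category. One row of the
   canonical correlation inputs corresponds to one *musical* change point:
   X (n × 12; 5 acoustic channels + 7 interpretation-map categories) and
   Y (n × 9) hold each channel's kernel series sampled at that onset, with
   physiological series averaged across the listeners of the performance
   (`average_listeners`).

4. **Canonical correlation analysis** (`fit_cca`). Columns are standardized
   and the canonical system is solved by SVD of the whitened
   cross-correlation matrix. We report canonical correlations, within-set
   *loadings* (the interpretable quantity), a relative-covariance share per
   variate (r²ᵢ / Σr²ⱼ), Wilks' lambda p-values (Bartlett approximation),
   surrogate-based retention (a variate is kept only if its correlation
   exceeds the maximum mean correlation across row-permutation surrogates
   and its Wilks p < 0.05), and permutation p-values. Retained variates are
   drawn as *change-point connectivity graphs* (`build_graph`,
   `render_graph`): concentric rings, music left / physiology right, red
   positive and blue negative loadings, |loading| > 0.3 shown.

5. **Event-locked differences and individual effects.** Each (category ×
   physiological signal) cell pools per-(listener, event) differences of
   10-s window means before/after the onset (`window_diff`), tested with a
   paired t or Wilcoxon test depending on Shapiro–Wilk normality
   (`category_test`), Bonferroni-corrected across all 17 × 9 = 153 cells
   (threshold 0.05/153 ≈ 0.00033), with 8-s and 12-s sensitivity windows.
   Listener-level heterogeneity is quantified by subject-wise CCA
   (`subjectwise_cca`), cosine similarity of individual first-variate
   loadings to the group pattern (`cosine_similarity`), and a Gaussian GAM
   of similarity on baseline autonomic indices and demographics with
   B-spline smooths and Benjamini–Hochberg correction (`fit_gam`).

Baseline stratification sits alongside: 5-min baseline RR yields
time-domain and Poincaré statistics (`hrv_summary`), cohort-standardized
PNS/SNS composite indices (`pns_sns_indices`), and a k-means split into
parasympathetic-dominant / balanced / sympathetic-dominant clusters
(`cluster_autonomic`), each analysed separately by the pipeline.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| analysis rate | 5 | Hz | common grid for all derived signals |
| RR high-pass cutoff | 0.03 | Hz | removes drift below the HRV bands |
| STFT window / overlap | 50 / 25 | samples | 0.1 Hz bins at 5 Hz; 10-s slices |
| HF half-width | 0.125 | Hz | Fr(t)-centred band for RSA |
| detector penalties | 0.5–3 × log n | — | BIC neighbourhood, both directions |
| consensus τ | 0.5 | — | majority of configurations |
| vote tolerance | ±1 | s | detector jitter allowance |
| min spacing δ | 5 | s | temporal resolution of distinct events |
| kernel σ | 2 | s | event proximity scale; checked at 1 and 3 s |
| display threshold | 0.3 | loading | interpretable-loading convention |
| windows | 8/10/12 | s | event-locked means; 10 s primary |
| Bonferroni m | 153 | cells | 17 categories × 9 signals |

## Numerical choices

* **Penalty scaling.** The mean-shift cost is variance-normalized via the
  SD of first differences (robust MAD version when `normalize = TRUE`), so
  multiples of log n act like BIC. The empirical-distribution cost sums
  K = ⌈log n⌉ binomial likelihood terms per segment, so its penalty is
  scaled *per parameter*: β = mult · K · log n. Without this scaling the
  nonparametric members of the ensemble over-segment by an order of
  magnitude and poison the consensus.
* **PELT with a minimum segment length.** The textbook pruning rule is
  unsafe when a minimum segment length is enforced (the dominating
  candidate is not yet a legal change point at horizons closer than the
  minimum); candidates are therefore pruned only after domination persists
  for `minlen` consecutive steps. Exactness is verified against an
  exhaustive O(n²) dynamic program on every fixture up to length 60.
* **Zero-phase filtering.** All Butterworth filters are applied
  forward–backward with odd-reflection padding and steady-state initial
  conditions, so filtering never lags change-point locations. The series
  mean is removed before high-pass filtering, making a constant input map
  to exactly zero.
* **Degenerate CCA samples.** When n ≤ p + q the whitening is
  ridge-regularized (ε = 10⁻⁶ on correlation matrices) with a warning;
  needed for subject-wise fits on short playlists. Variate signs are
  canonicalized (largest-|loading| musical loading positive), making
  results backend-independent; direction ties in `directionize` break to
  "up" with a flag.
* **Surrogates.** Row permutation of Y is the default surrogate: it breaks
  music–physiology alignment while preserving each set's covariance
  exactly. A circular-shift alternative (preserving Y's autocorrelation) is
  available via `method = "shift"`.
* **CIs.** 95% intervals are t-based when the normality gate passes,
  seeded bootstrap percentile (1000 resamples) otherwise; this gate-tied
  rule is the package's own convention.

## The synthetic cohort: what it does and does not emulate

Raw listening-session recordings of this kind are rarely shareable, so
`generate_cohort` builds a
cohort with *known ground truth*: per-piece acoustic channels with planted
mean-shift change points (step = SNR × channel noise SD, default SNR 2);
annotation events placed with a minimum gap of twice the event window so
pre/post windows never overlap; and per-listener physiology — baseline RR
drawn from one of three autonomic archetypes (mean RR 1.00/0.85/0.70 s
with decreasing RSA amplitude, ordering RMSSD), respiration as a slowly
frequency-modulated 0.25 Hz oscillation, RR carrying respiratory sinus
arrhythmia at the instantaneous respiratory phase plus AR(1) beat noise,
and beat-wise SYS/DIA with positive pulse pressure. Playlists mirror the
design: nine performances whose first and last items are different
versions of the same piece; altered versions are global gain/tempo
scalings.

Event-locked responses are planted as causal gamma-shaped transients
(`response_kernel`), *normalized so the kernel's mean over the 10-s
post-event window is 1*: a planted amplitude of −0.15 s **is** the
expected pre/post window-mean difference, which is exactly what the
event-response analysis estimates. Response direction follows the
archetype (RR lengthens for parasympathetic-dominant listeners, shortens
for sympathetic-dominant ones; respiratory intervals shorten for all).
Amplitudes and latencies are free parameters of this stated world —
no empirical estimates of response shape exist for this design — so green
recovery tests establish that the *pipeline* recovers what was planted,
not that any real cohort's effect sizes are reproduced. The generator also does not emulate: ectopic beats and
sensor artifacts beyond white/AR noise, circadian or posture drift,
inter-piece carry-over, or any audio-level structure (channels are
synthesized directly, never derived from sound).

RR synthesis is a direct sequence construction (mean + RSA modulation +
AR(1) noise) rather than an integral-pulse-frequency-modulation model — a
stated simplification, sufficient for the spectral-band and
event-recovery properties the tests check.

## Design choices where the design was open

* **Index standardization.** The PNS/SNS composites are within-cohort
  z-score means; the population-normalized variant used by commercial HRV
  software is proprietary. Absolute index values therefore differ, but
  ordering and clustering — all that the analysis consumes — do not.
* **Baevsky stress index** is computed from first principles (AMo% with
  50 ms bins / (2 · Mo · MxDMn)) since only the constituents are named.
* **Cluster separation warning.** Forcing k = 3 on a single 2-D blob of
  (PNS, SNS) points yields mean silhouettes of 0.35–0.5 regardless of
  scale (silhouette is scale-invariant), while well-separated archetypes
  sit at 0.7+; the low-separation warning therefore fires below 0.45
  (`min_silhouette`), a threshold chosen from those measurements rather
  than from convention.
* **Detector grid, τ, δ, σ.** No canonical values exist for these; they
  are exposed as configuration with the documented defaults above, and the kernel-σ
  robustness is checked at 1 s and 3 s in the tests.
* **Row universe.** CCA rows are the δ-merged union of all acoustic
  consensus onsets plus annotation onsets per piece; physiological kernels
  are sampled at the onset itself (a lag option exists in the assembly
  layer's inputs but is not a default).
* **Pairing unit for event tests** is one difference per (listener,
  event) — chosen for power; per-listener means are available via
  `pool = "listener"`.
* **Similarity** uses the first retained group variate's concatenated
  loadings, with the CCA sign indeterminacy resolved by flipping the
  individual vector when that raises similarity (effectively |cos|); raw
  signed similarity via `align = FALSE`.
* **Edge events** lacking full windows are excluded and counted in the
  table's `skipped` column.

## Known limitations

* Spectral peak frequencies are quantized to 0.1 Hz bins (50-sample STFT
  at 5 Hz); FLF/FHF contrasts finer than one bin are not resolvable.
* The ensemble's consensus probability is a frequency over a finite,
  user-chosen grid, not a posterior probability.
* Subject-wise CCA on short playlists is ridge-regularized and its
  absolute correlations are optimistic; only the loading *pattern* is used
  downstream.
* Family-wise error control is per window length; no correction across
  the 8/10/12-s sensitivity family is applied (each window is reported as
  its own table).

## A small worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  sim = list(n_pieces = 2, n_listeners = 4, playlist_length = 2,
             piece_duration_s = 300),
  windows = 10, n_surrogates = 20, n_perm = 20,
  penalty_mults = 2, resolutions_hz = 1, seed = 1,
  out_dir = "musicphys_out")
bundle <- run_pipeline(cfg)
bundle$cca$all$result          # correlations, loadings, Wilks p
bundle$event_tables$w10        # 153-cell difference table
```

Every number above is produced by the same code paths the test suite
exercises; the vignette states no empirical result that
`tests/testthat/test-acceptance.R` or `scripts/acceptance.R` does not
itself compute.
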