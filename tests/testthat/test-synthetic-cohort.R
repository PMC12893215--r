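test_that("generate_music honours planted steps exactly in the noiseless limit", {
  cfg <- tiny_sim(noise_sd = c(tempo = 0, loudness = 0, spectral_centroid = 0,
                               mfcc = 0, diameter = 0))
  plan <- data.frame(time_s = 30, channel = "loudness", amplitude = 2)
  ms <- generate_music(cfg, 1, planted = plan)
  s <- ms$channels$loudness
  t <- series_time(s)
  expect_equal(mean(s$values[t >= 30]) - mean(s$values[t < 30]), 2)
  expect_equal(ms$truth_changepoints$direction[
    ms$truth_changepoints$channel == "loudness"], "up")
  # other channels got no events under the planted plan
  expect_equal(sum(ms$truth_changepoints$channel == "tempo"), 0)
})

test_that("generate_music is deterministic and truth onsets lie in range", {
  cfg <- tiny_sim()
  m1 <- generate_music(cfg, 1)
  m2 <- generate_music(cfg, 1)
  expect_identical(m1, m2)
  tc <- m1$truth_changepoints
  expect_equal(nrow(tc), cfg$cps_per_channel * length(acoustic_channels()))
  expect_true(all(tc$time_s >= 0 & tc$time_s <= cfg$piece_duration_s))
  # versions share truth times but alter gain
  v2 <- generate_music(cfg, 1, version = 2)
  expect_equal(v2$truth_changepoints$time_s, tc$time_s)
  expect_gt(mean(v2$channels$loudness$values), mean(m1$channels$loudness$values))
})

test_that("a 4-step plant is recovered by the ensemble detector at high SNR", {
  cfg <- tiny_sim(seed = 3)
  plan <- data.frame(time_s = c(50, 110, 180, 250), channel = "tempo",
                     amplitude = c(16, -16, 16, -16))  # 4 x noise sd = SNR 4
  ms <- generate_music(cfg, 1, planted = plan)
  expect_equal(nrow(ms$truth_changepoints), 4)
  cp <- ensemble_detect(ms$channels$tempo)
  f1 <- changepoint_f1(cp$onset_s, plan$time_s, tol = 2)
  expect_equal(f1$matched, 4)
})

test_that("annotations respect counts, gaps and emptiness", {
  cfg <- tiny_sim(annotation_counts = c("Novel Melody" = 5),
                  min_event_gap_s = 20)
  a <- generate_annotations(cfg, 1)
  expect_equal(nrow(a$events), 5)
  expect_true(all(diff(a$events$onset_s) >= 20))
  expect_true(!is.unsorted(a$events$onset_s, strictly = TRUE))

  cfg0 <- tiny_sim(annotation_counts = c("Novel Melody" = 0))
  expect_equal(nrow(generate_annotations(cfg0, 1)$events), 0)

  cfg2 <- tiny_sim(annotation_counts = c("Novel Melody" = 10, "Return" = 10),
                   piece_duration_s = 600, min_event_gap_s = 20)
  a2 <- generate_annotations(cfg2, 1)
  expect_equal(as.vector(table(a2$events$category)[c("Novel Melody", "Return")]),
               c(10, 10))

  # unsatisfiable counts error out
  cfg_bad <- tiny_sim(annotation_counts = c("Novel Melody" = 40),
                      min_event_gap_s = 20)
  expect_error(generate_annotations(cfg_bad, 1), "cannot place")
})

test_that("listener signals satisfy the physiological gates", {
  cfg <- tiny_sim()
  coh <- generate_cohort(cfg)
  for (l in coh$listeners) {
    expect_true(all(l$baseline_rr > 0.3 & l$baseline_rr < 2.0))
    expect_gte(sum(l$baseline_rr), 300)
    for (s in l$sessions) {
      expect_true(all(s$rr > 0.3 & s$rr < 2.0))
      expect_true(all(s$sys - s$dia > 0))
    }
  }
  expect_error(generate_listener(cfg, 1, "vagal", list()), "unknown archetype")
})

test_that("zero coupling leaves event-locked RR differences centred on zero", {
  cfg <- tiny_sim(seed = 21, coupling_spec = list(), n_listeners = 6,
                  archetype_mix = c(pns = 0, balanced = 1, sns = 0))
  coh <- generate_cohort(cfg)
  diffs <- c()
  for (l in coh$listeners) for (j in seq_along(l$sessions)) {
    s <- l$sessions[[j]]
    rr <- resample_rr(s$rr, start = s$beat_times[1])
    ann <- coh$annotations[[l$playlist$piece[j]]]
    ons <- ann$events$onset_s[ann$events$category == "Novel Melody"]
    diffs <- c(diffs, vapply(ons, function(o) window_diff(rr, o), numeric(1)))
  }
  diffs <- diffs[is.finite(diffs)]
  expect_gt(length(diffs), 10)
  # no planted effect: mean difference within 3 SEs of zero
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("planted respiratory response is recovered by event-triggered averaging", {
  # -0.15 s Novel-Melody response; pool > 40 events across listeners and
  # verify the post-pre window mean difference on the truth interval series
  cfg <- tiny_sim(seed = 8, n_listeners = 6,
                  annotation_counts = c("Novel Melody" = 6),
                  archetype_mix = c(pns = 0, balanced = 1, sns = 0))
  coh <- generate_cohort(cfg)
  diffs <- c()
  for (l in coh$listeners) for (j in seq_along(l$sessions)) {
    s <- l$sessions[[j]]
    mid <- (s$truth_resp_peaks[-1] + s$truth_resp_peaks[-length(s$truth_resp_peaks)]) / 2
    iv <- uniform_series(approx(mid, s$truth_resp_intervals,
                                xout = seq(0, 300, 0.2), rule = 2)$y, rate = 5)
    ann <- coh$annotations[[l$playlist$piece[j]]]
    ons <- ann$events$onset_s[ann$events$category == "Novel Melody"]
    diffs <- c(diffs, vapply(ons, function(o) window_diff(iv, o), numeric(1)))
  }
  diffs <- diffs[is.finite(diffs)]
  expect_gt(length(diffs), 40)
  expect_lt(abs(mean(diffs) - (-0.15)), 0.03)
})

test_that("archetypes order RMSSD as planted", {
  cfg <- tiny_sim()
  rmssd <- function(arch, n) {
    vapply(seq_len(n), function(i) {
      l <- generate_listener(tiny_sim(seed = 100 + i), i, arch, list())
      hrv_summary(l$baseline_rr)$rmssd
    }, numeric(1))
  }
  expect_gt(mean(rmssd("pns", 12)), mean(rmssd("sns", 12)))
})

test_that("cohort counts, playlists and serialization behave", {
  cfg <- sim_config(n_pieces = 4, n_listeners = 10, playlist_length = 4,
                    piece_duration_s = 300,
                    archetype_mix = c(pns = 0.2, balanced = 0.6, sns = 0.2),
                    seed = 2)
  coh <- generate_cohort(cfg)
  tab <- table(coh$truth$archetypes$archetype)
  expect_equal(as.vector(tab[c("pns", "balanced", "sns")]), c(2, 6, 2))
  for (l in coh$listeners) {
    pl <- l$playlist
    expect_equal(pl$piece[1], pl$piece[nrow(pl)])
    expect_false(pl$version[1] == pl$version[nrow(pl)])
  }
  # every performance in the pool is heard by at least one listener
  heard <- do.call(rbind, lapply(coh$listeners, `[[`, "playlist"))
  expect_true(all(paste(coh$performances$piece, coh$performances$version) %in%
                    paste(heard$piece, heard$version)))
  expect_error(generate_cohort(sim_config(n_listeners = 2, seed = 1)),
               "at least 3 listeners")
})

test_that("same seed gives byte-identical serialized cohorts", {
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(generate_cohort(tiny_sim(seed = 4)), d1)
  write_cohort(generate_cohort(tiny_sim(seed = 4)), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  # and a different seed changes the data
  d3 <- file.path(tempdir(), "coh_c")
  write_cohort(generate_cohort(tiny_sim(seed = 5)), d3)
  expect_false(identical(readBin(file.path(d1, f1[1]), "raw", 2e6),
                         readBin(file.path(d3, f1[1]), "raw", 2e6)))
  # round trip preserves signals
  rt <- read_cohort(d1)
  expect_equal(rt$listeners[[1]]$baseline_rr,
               generate_cohort(tiny_sim(seed = 4))$listeners[[1]]$baseline_rr,
               tolerance = 1e-12)
})
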