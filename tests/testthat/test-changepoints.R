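test_that("a noiseless step yields the unique optimal onset", {
  s <- uniform_series(c(rep(0, 150), rep(2, 150)), rate = 5)
  expect_equal(detect_mean(s, detector_config("mean", "pelt")), 30)
  expect_equal(detect_mean(s, detector_config("mean", "binseg")), 30)
  expect_equal(detect_np(s, detector_config("nonparametric", "pelt")), 30)
  corrupt <- uniform_series(rnorm(100), rate = 5)
  corrupt$values[3] <- NaN
  expect_error(detect_mean(corrupt), "non-finite")
})

test_that("white noise rarely triggers the default detectors", {
  set.seed(10)
  fp_mean <- fp_np <- 0
  for (i in 1:100) {
    s <- uniform_series(rnorm(300), rate = 5)
    if (length(detect_mean(s)) > 0) fp_mean <- fp_mean + 1
    if (length(detect_np(s)) > 0) fp_np <- fp_np + 1
  }
  expect_lte(fp_mean, 5)
  expect_lte(fp_np, 5)
})

test_that("PELT equals the exhaustive dynamic-programming oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    x <- rnorm(n) + rep(c(0, sample(c(-2, 0, 2), 1)), c(n %/% 2, n - n %/% 2))
    for (beta in c(0.5, 1, 2) * log(n)) {
      got <- musicphys:::.cpt_mean_pelt(x / 1, beta)
      oracle <- dp_mean_oracle(x, beta)
      expect_equal(as.integer(got), as.integer(oracle$cps))
      expect_equal(musicphys:::.cpt_mean_cost(x, got, beta), oracle$cost,
                   tolerance = 1e-9)
    }
  }
})

test_that("nonparametric cost is invariant under monotone transforms", {
  set.seed(12)
  x <- c(rnorm(150, 0), rnorm(150, 3))
  s1 <- uniform_series(x, rate = 5)
  s2 <- uniform_series(exp(x / 2), rate = 5)        # strictly monotone map
  cfg <- detector_config("nonparametric", "pelt", 1)
  expect_equal(detect_np(s1, cfg), detect_np(s2, cfg))
})

test_that("nonparametric detector finds a variance change", {
  set.seed(13)
  hits <- 0
  for (i in 1:20) {
    x <- c(rnorm(200, 0, 1), rnorm(200, 0, 2))
    s <- uniform_series(x, rate = 5)
    on <- detect_np(s, detector_config("nonparametric", "pelt", 1))
    if (length(on) >= 1 && any(abs(on * 5 - 200) <= 5)) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("ensemble consensus thresholds and merges onsets", {
  set.seed(14)
  s <- uniform_series(c(rep(0, 750), rep(2, 750)) + rnorm(1500), rate = 5)
  cp <- ensemble_detect(s)
  expect_s3_class(cp, "change_point_set")
  expect_true(all(cp$probability >= 0.5))
  expect_true(all(diff(cp$onset_s) >= 5))
  i <- which.min(abs(cp$onset_s - 150))
  expect_lt(abs(cp$onset_s[i] - 150), 2)
  expect_equal(cp$probability[i], 1)            # all configurations agree
  expect_equal(cp$direction[i], "up")
  expect_error(ensemble_detect(s, grid = list()), "empty")

  # threshold: onsets supported by few configurations are dropped
  cp_all <- ensemble_detect(s, consensus = 1e-6)
  cp_maj <- ensemble_detect(s, consensus = 0.5)
  expect_gte(nrow(cp_all), nrow(cp_maj))
})

test_that("consensus monotonicity: raising tau never adds onsets", {
  set.seed(15)
  x <- c(rep(0, 400), rep(1.2, 400), rep(0.4, 700)) + rnorm(1500)
  s <- uniform_series(x, rate = 5)
  taus <- c(0.2, 0.4, 0.6, 0.8)
  counts <- vapply(taus, function(tau)
    nrow(ensemble_detect(s, consensus = tau)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("delta-merge lands on the frequency-weighted mean", {
  m <- merge_onsets(c(100, 102), delta = 5, weights = c(1, 1))
  expect_equal(m, 101)
  m2 <- merge_onsets(c(100, 102), delta = 5, weights = c(3, 1))
  expect_equal(m2, (100 * 3 + 102) / 4)
  m3 <- merge_onsets(c(10, 30), delta = 5)
  expect_equal(m3, c(10, 30))                   # far apart: untouched
})

test_that("direction labels follow the post-pre sign with flagged ties", {
  up <- uniform_series(c(rep(0, 150), rep(1, 150)), rate = 5)
  d <- directionize(up, 30)
  expect_equal(d$direction, "up")
  expect_false(d$flagged)

  down <- uniform_series(seq(10, 0, length.out = 300), rate = 5)
  expect_equal(directionize(down, 30)$direction, "down")
  # ramp of slope m: difference is m * w in continuous time; the half-open
  # sample windows put the window centres (w + dt) apart, exactly
  m <- (0 - 10) / (299 / 5)
  expect_equal(directionize(down, 30)$diff, m * (10 + 0.2), tolerance = 1e-9)
  expect_equal(directionize(down, 30)$diff, m * 10, tolerance = 0.03)

  flat <- uniform_series(rep(2, 300), rate = 5)
  dt <- directionize(flat, 30)
  expect_equal(dt$direction, "up")              # documented tie rule
  expect_true(dt$flagged)
  edge <- directionize(up, 3)                   # truncated pre window
  expect_true(edge$flagged)
  expect_error(directionize(up, 300), "support")
})

test_that("operating characteristics: F1 at SNR 2 within +-2 s", {
  set.seed(16)
  f1 <- vapply(1:30, function(i) {
    cp <- runif(1, 60, 240)
    t <- seq(0, 299.8, by = 0.2)
    x <- ifelse(t >= cp, 2, 0) + rnorm(length(t))
    det <- ensemble_detect(uniform_series(x, rate = 5))
    changepoint_f1(det$onset_s, cp, tol = 2)$f1
  }, numeric(1))
  expect_gte(mean(f1), 0.9)
})
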