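test_that("window_diff matches closed forms", {
  t <- seq(0, 299.8, by = 0.2)
  step <- uniform_series(ifelse(t > 150, 5, 0), rate = 5)
  expect_equal(window_diff(step, 150), 5)
  expect_equal(window_diff(uniform_series(rep(3, 1500), rate = 5), 150), 0)
  m <- 0.4
  ramp <- uniform_series(m * t, rate = 5)
  # slope m over window w: m * w in continuous time, exactly m * (w + dt)
  # for the half-open sampled windows
  expect_equal(window_diff(ramp, 150), m * (10 + 0.2), tolerance = 1e-9)
  expect_equal(window_diff(ramp, 150), m * 10, tolerance = m * 0.25)
  # events without full windows are NA (skipped upstream)
  expect_true(is.na(window_diff(step, 4)))
  expect_true(is.na(window_diff(step, 298)))
})

test_that("category_test gates on normality and is antisymmetric", {
  set.seed(40)
  strong <- rnorm(50, 0.5, 0.1)
  ct <- category_test(strong)
  expect_lt(ct$p, 1e-3)
  expect_equal(ct$test, "paired-t")

  skewed <- rexp(60) - 0.2
  ct2 <- category_test(skewed)
  expect_equal(ct2$test, "wilcoxon")

  d <- rnorm(30, 0.3)
  a <- category_test(d); b <- category_test(-d)
  expect_equal(a$p, b$p)                        # sign flip never changes p
  if (a$test == "paired-t") {
    expect_equal(a$statistic, -b$statistic)
  } else {
    # Wilcoxon V reflects around n(n+1)/2 under negation
    expect_equal(a$statistic + b$statistic, 30 * 31 / 2)
  }

  expect_error(category_test(rnorm(3)), ">= 5")
  dz <- category_test(rep(0, 10))
  expect_true(dz$degenerate)

  # null calibration: p approximately uniform over 200 replicates
  set.seed(41)
  ps <- vapply(1:200, function(i) category_test(rnorm(30))$p, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bonferroni_alpha reproduces the printed threshold", {
  expect_equal(round(bonferroni_alpha(0.05, 153), 5), 0.00033)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
})

test_that("the category x signal grid has 153 cells with consistent tiers", {
  expect_equal(length(event_categories()) * length(physio_channels()), 153)
  expect_equal(length(event_categories()), 17)

  # small synthetic table: planted strong cell, weak cell, null cell
  set.seed(42)
  diffs <- list()
  for (cat in event_categories()) {
    diffs[[cat]] <- list()
    for (sig in physio_channels()) diffs[[cat]][[sig]] <- numeric(0)
  }
  diffs[["Novel Melody"]][["resp"]] <- rnorm(60, -0.15, 0.05)   # strong
  diffs[["Return"]][["rr"]] <- rnorm(30, 0.02, 0.05)            # trend-ish
  diffs[["Runs/Fast Sequence"]][["pp"]] <- rnorm(40, 0, 0.05)   # null
  tab <- event_diff_table(diffs, w = 10)
  expect_s3_class(tab, "event_diff_table")
  expect_equal(nrow(tab), 153)
  nm <- tab[tab$category == "Novel Melody" & tab$signal == "resp", ]
  expect_equal(nm$tier, "significant")
  expect_true(nm$ci_lo <= nm$mean_diff && nm$mean_diff <= nm$ci_hi)
  # tier consistency across the table
  thr <- bonferroni_alpha(0.05, 153)
  with_p <- tab[!is.na(tab$p), ]
  expect_true(all(with_p$p[with_p$tier == "significant"] <= thr))
  expect_true(all(with_p$p[with_p$tier == "trend"] < 0.05 &
                    with_p$p[with_p$tier == "trend"] > thr))
})

test_that("collect_event_diffs pools and counts skipped edge events", {
  t <- seq(0, 299.8, by = 0.2)
  ser <- uniform_series(ifelse(t > 100, 2, 0), rate = 5)
  chans <- list(list(list(rr = ser)))           # one listener, one session
  ev_fn <- function(li, si, cat)
    if (cat == "Novel Melody") c(5, 100, 200) else numeric(0)
  d <- collect_event_diffs(chans, ev_fn, w = 10,
                           categories = "Novel Melody", signals = "rr")
  v <- d[["Novel Melody"]][["rr"]]
  expect_equal(length(v), 3)
  expect_true(is.na(v[1]))                      # edge event skipped
  tab <- event_diff_table(d, categories = "Novel Melody", signals = "rr")
  expect_equal(tab$skipped, 1)

  # per-listener pooling collapses each listener to one mean
  chans2 <- list(list(list(rr = ser)), list(list(rr = ser)))
  d2 <- collect_event_diffs(chans2, ev_fn, w = 10,
                            categories = "Novel Melody", signals = "rr",
                            pool = "listener")
  expect_equal(length(d2[["Novel Melody"]][["rr"]]), 2)
})

test_that("window sensitivity keeps planted signs across 8/10/12 s", {
  t <- seq(0, 299.8, by = 0.2)
  resp <- uniform_series(4 - 0.15 * response_kernel(t - 150), rate = 5)
  chans <- list(list(list(resp = resp)))
  ev_fn <- function(li, si, cat)
    if (cat == "Novel Melody") 150 else numeric(0)
  for (w in c(8, 10, 12)) {
    d <- collect_event_diffs(chans, ev_fn, w = w,
                             categories = "Novel Melody", signals = "resp")
    expect_lt(d[["Novel Melody"]][["resp"]], 0)
  }
  # and the 10-s window-mean calibration of the kernel is exact
  d10 <- collect_event_diffs(chans, ev_fn, w = 10,
                             categories = "Novel Melody", signals = "resp")
  expect_equal(unname(d10[["Novel Melody"]][["resp"]]), -0.15, tolerance = 0.01)
})
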