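test_that("cosine similarity handles identity, sign flips and orthogonality", {
  a <- c(0.5, -0.3, 0.8)
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(-a, a), 1)       # sign-aligned
  expect_equal(cosine_similarity(-a, a, align = FALSE), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(3 * a, a), 1)    # scale invariance
  expect_error(cosine_similarity(a, a[1:2]))
})

test_that("subjectwise_cca skips short inputs with a reason", {
  set.seed(50)
  X <- matrix(rnorm(5 * 3), 5); Y <- matrix(rnorm(5 * 3), 5)
  colnames(X) <- paste0("x", 1:3); colnames(Y) <- paste0("y", 1:3)
  sw <- subjectwise_cca(list(X = X, Y = Y))
  expect_false(sw$fitted)
  expect_match(sw$reason, "rows")

  X2 <- matrix(rnorm(20 * 3), 20); Y2 <- X2 + matrix(rnorm(60, 0, 0.2), 20)
  colnames(X2) <- paste0("x", 1:3); colnames(Y2) <- paste0("y", 1:3)
  sw2 <- subjectwise_cca(list(X = X2, Y = Y2))
  expect_true(sw2$fitted)
  expect_gt(sw2$result$cor[1], 0.8)
  # deterministic
  sw3 <- subjectwise_cca(list(X = X2, Y = Y2))
  expect_identical(sw2$result$cor, sw3$result$cor)
})

test_that("a cohort-average listener is the best-aligned listener", {
  set.seed(51)
  n <- 60
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, 0, 0.3), b = rnorm(n), c = rnorm(n))
  make_y <- function(noise) cbind(p = z + rnorm(n, 0, noise), q = rnorm(n),
                                  r = rnorm(n))
  group <- fit_cca(X, make_y(0.3))
  avg_sim <- cosine_similarity(
    loading_vector(subjectwise_cca(list(X = X, Y = make_y(0.3)))$result),
    loading_vector(group))
  pert_sim <- cosine_similarity(
    loading_vector(subjectwise_cca(list(X = X, Y = make_y(3)))$result),
    loading_vector(group))
  expect_gte(avg_sim, pert_sim)
})

gam_records <- function(n, slope = 0, noise = 0.1, seed = 1) {
  set.seed(seed)
  data.frame(similarity = NA, pns = rnorm(n), sns = rnorm(n),
             sys = rnorm(n, 120, 10), dia = rnorm(n, 78, 7),
             age = runif(n, 21, 79),
             gender = factor(sample(c("F", "M"), n, TRUE)),
             musician = runif(n) < 0.2,
             classical_pref = runif(n) < 0.3) |>
    transform(similarity = slope * pns + rnorm(n, 0, noise))
}

test_that("BH step-up matches the hand-computed oracle", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(bh_adjust(p), bh_oracle(p))
  set.seed(52)
  pr <- runif(20)
  expect_equal(bh_adjust(pr), bh_oracle(pr))
  expect_true(all(bh_adjust(pr) >= pr))
})

test_that("fit_gam detects a planted PNS slope and falls back linearly", {
  hits <- 0
  for (i in 1:15) {
    rep <- fit_gam(gam_records(100, slope = -0.3, seed = 60 + i))
    q <- rep$terms$q[rep$terms$term == "pns"]
    if (q < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 14)

  expect_warning(small <- fit_gam(gam_records(20, seed = 1)), "linear")
  expect_false(small$smooth)
  # linear fallback reproduces ordinary least squares exactly
  rec <- gam_records(25, slope = 0.2, seed = 2)
  lf <- fit_gam(rec, smooth = FALSE)
  ols <- lm(similarity ~ pns + sns + sys + dia + age + gender + musician +
              classical_pref, data = rec)
  expect_equal(lf$terms$value[lf$terms$term == "pns"],
               unname(coef(ols)["pns"]), tolerance = 1e-6)
  expect_error(fit_gam(rec[, -2]), "missing predictors")
})

test_that("null GAMs keep the false-positive rate near nominal", {
  set.seed(53)
  qs <- c()
  for (i in 1:40) {
    rep <- suppressWarnings(fit_gam(gam_records(80, slope = 0, seed = 500 + i)))
    qs <- c(qs, rep$terms$q)
  }
  expect_lte(mean(qs < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(qs)) + 0.02)
})

test_that("the PNS partial effect is decreasing under a planted negative slope", {
  rep <- fit_gam(gam_records(150, slope = -0.3, seed = 77))
  pe <- gam_partial_effect(rep, "pns")
  expect_lt(cor(pe$pns, pe$effect), -0.9)
})
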