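rand_xy <- function(n, p, q, seed, couple = 0) {
  set.seed(seed)
  z <- rnorm(n)
  X <- matrix(rnorm(n * p), n) + couple * z
  Y <- matrix(rnorm(n * q), n) + couple * z
  colnames(X) <- paste0("x", 1:p); colnames(Y) <- paste0("y", 1:q)
  list(X = X, Y = Y, z = z)
}

test_that("identity coupling gives unit correlations", {
  d <- rand_xy(300, 4, 4, 1)
  fit <- fit_cca(d$X, d$X)
  expect_true(all(abs(fit$cor - 1) < 1e-8))
})

test_that("loadings equal brute-force correlations and are bounded", {
  d <- rand_xy(200, 5, 3, 2, couple = 0.5)
  fit <- fit_cca(d$X, d$Y)
  Xs <- scale(d$X); Ys <- scale(d$Y)
  for (i in seq_along(fit$cor)) {
    expect_lt(max(abs(fit$loadings_x[, i] - loading_oracle(Xs, fit$U[, i]))),
              1e-10)
    expect_lt(max(abs(fit$loadings_y[, i] - loading_oracle(Ys, fit$V[, i]))),
              1e-10)
  }
  expect_true(all(abs(fit$loadings_x) <= 1 + 1e-12))
  ld <- cca_loadings(fit)
  expect_identical(ld$x, fit$loadings_x)

  # single-column X: its loading on U1 is +1 after sign canonicalization
  x1 <- d$X[, 1, drop = FALSE]
  f1 <- fit_cca(x1, d$Y)
  expect_equal(unname(f1$loadings_x[1, 1]), 1, tolerance = 1e-10)
})

test_that("relative covariance shares behave", {
  fake <- structure(list(cor = c(0.8, 0, 0)), class = "cca_result")
  expect_equal(relative_covariance(fake), c(100, 0, 0))
  fake$cor <- rep(0.5, 3)
  expect_equal(relative_covariance(fake), rep(100 / 3, 3))
  d <- rand_xy(150, 4, 3, 3)
  expect_equal(sum(fit_cca(d$X, d$Y)$relcov), 100, tolerance = 1e-9)
})

test_that("Wilks' lambda endpoints and an independent fixture computation", {
  w0 <- wilks_test(r = c(0, 0), n = 100, p = 3, q = 2)
  expect_equal(w0$lambda, c(1, 1))
  expect_equal(w0$p, c(1, 1))
  w1 <- wilks_test(r = c(0.99999, 0.1), n = 100, p = 3, q = 2)
  expect_lt(w1$p[1], 1e-10)

  # independent route: stats::cancor correlations + textbook Bartlett formula
  d <- rand_xy(80, 3, 2, 4, couple = 0.6)
  r <- cancor(scale(d$X), scale(d$Y))$cor
  lam2 <- 1 - r[2]^2
  lam1 <- (1 - r[1]^2) * lam2
  stat1 <- -(80 - 1 - (3 + 2 + 1) / 2) * log(lam1)
  p1 <- pchisq(stat1, 3 * 2, lower.tail = FALSE)
  got <- wilks_test(fit_cca(d$X, d$Y))
  expect_equal(got$p[1], p1, tolerance = 1e-8)
  expect_equal(got$lambda[2], lam2, tolerance = 1e-8)
})

test_that("null r1 stays below the Bartlett 95% quantile most of the time", {
  n <- 500; p <- 3; q <- 3
  crit <- qchisq(0.95, p * q)
  below <- 0
  for (i in 1:100) {
    d <- rand_xy(n, p, q, 100 + i)
    r1 <- fit_cca(d$X, d$Y)$cor[1]
    stat <- -(n - 1 - (p + q + 1) / 2) * log(1 - r1^2)  # first-variate bound
    if (stat < crit) below <- below + 1
  }
  expect_gte(below, 90)
})

test_that("a planted shared factor is recovered", {
  set.seed(20)
  n <- 400
  z <- rnorm(n)
  wx <- c(1, -1, 0.5, 0, 0) / sqrt(2.25)
  wy <- c(0.8, -0.6, 0.2) / sqrt(1.04)
  X <- z %o% wx + matrix(rnorm(n * 5, 0, 0.5), n)
  Y <- z %o% wy + matrix(rnorm(n * 3, 0, 0.5), n)
  colnames(X) <- paste0("x", 1:5); colnames(Y) <- paste0("y", 1:3)
  fit <- fit_cca(X, Y)
  cos_x <- abs(sum(fit$loadings_x[, 1] * wx) /
                 sqrt(sum(fit$loadings_x[, 1]^2) * sum(wx^2)))
  cos_y <- abs(sum(fit$loadings_y[, 1] * wy) /
                 sqrt(sum(fit$loadings_y[, 1]^2) * sum(wy^2)))
  expect_gte(cos_x, 0.95)
  expect_gte(cos_y, 0.95)
})

test_that("variates are orthogonal and results scale-invariant", {
  d <- rand_xy(250, 5, 4, 5, couple = 0.4)
  fit <- fit_cca(d$X, d$Y)
  cu <- cor(fit$U); cv <- cor(fit$V)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)

  X2 <- d$X; X2[, 2] <- X2[, 2] * 37
  fit2 <- fit_cca(X2, d$Y)
  expect_lt(max(abs(fit2$cor - fit$cor)), 1e-8)
  expect_lt(max(abs(fit2$loadings_x - fit$loadings_x)), 1e-8)
})

test_that("anti-coupled variables get opposite-sign loadings", {
  set.seed(21)
  n <- 300
  z <- rnorm(n)
  X <- cbind(a = z, b = rnorm(n)) + matrix(rnorm(2 * n, 0, 0.3), n)
  Y <- cbind(c = -z, d = rnorm(n)) + matrix(rnorm(2 * n, 0, 0.3), n)
  fit <- fit_cca(X, Y)
  expect_lt(fit$loadings_x["a", 1] * fit$loadings_y["c", 1], 0)
})

test_that("degenerate samples engage the ridge and zero-variance columns drop", {
  d <- rand_xy(8, 4, 4, 6)                      # n <= p + q
  expect_warning(fit <- fit_cca(d$X, d$Y), "ridge")
  expect_true(fit$regularized)
  X <- d$X; X[, 2] <- 7
  w <- capture_warnings(f2 <- fit_cca(X, d$Y))
  expect_true(any(grepl("zero-variance", w)))
  expect_equal(f2$p, 3)
})

test_that("surrogate selection is calibrated and detects planted coupling", {
  null_kept <- 0
  for (i in 1:40) {
    d <- rand_xy(60, 3, 3, 200 + i)
    sel <- surrogate_selection(d$X, d$Y, n_surrogates = 20, seed = i)
    if (!any(sel$retained)) null_kept <- null_kept + 1
  }
  expect_gte(null_kept, 36)                     # >= 90% of null runs keep 0

  strong_first <- 0
  for (i in 1:20) {
    d <- rand_xy(120, 3, 3, 300 + i, couple = 1)
    sel <- surrogate_selection(d$X, d$Y, n_surrogates = 20, seed = i)
    if (sel$retained[1] && !any(sel$retained[-1])) strong_first <- strong_first + 1
  }
  expect_gte(strong_first, 18)
  expect_error(surrogate_selection(d$X, d$Y, n_surrogates = 5), "20")

  # monotone: strengthening the coupling never unretains variate 1
  kept <- vapply(c(0.6, 1, 1.6), function(cp) {
    d <- rand_xy(120, 3, 3, 777, couple = cp)
    surrogate_selection(d$X, d$Y, n_surrogates = 20, seed = 1)$retained[1]
  }, logical(1))
  expect_true(all(diff(kept) >= 0))

  # circular-shift surrogate route also runs
  d <- rand_xy(80, 3, 3, 9, couple = 1)
  sel2 <- surrogate_selection(d$X, d$Y, 20, seed = 2, method = "shift")
  expect_true(sel2$retained[1])
})

test_that("permutation p-values are valid and bounded", {
  d <- rand_xy(150, 3, 3, 7, couple = 2)
  p <- permutation_pvalues(d$X, d$Y, n_perm = 99, seed = 1)
  expect_equal(p[1], 1 / 100)                   # extreme rank
  expect_true(all(p >= 1 / 100 & p <= 1))
})
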