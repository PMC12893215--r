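# Canonical correlation analysis: SVD of the whitened cross-correlation
# matrix, canonical loadings, relative covariance shares, Wilks' lambda,
# surrogate-based variate retention, and permutation p-values.

std_cols <- function(M) {
  mu <- colMeans(M)
  sdv <- apply(M, 2, stats::sd)
  keep <- sdv > .Machine$double.eps^0.5
  Ms <- sweep(sweep(M[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  list(M = Ms, keep = keep)
}

mat_inv_sqrt <- function(S, ridge = 0) {
  S <- S + diag(ridge, nrow(S))
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Fit a canonical correlation analysis
#'
#' Columns of both matrices are standardized to zero mean and unit SD
#' (zero-variance columns dropped with a warning); the canonical system is
#' solved by singular value decomposition of
#' Rxx^(-1/2) Rxy Ryy^(-1/2). Variates are unit-variance, canonical
#' correlations non-increasing in \[0, 1\], and signs are canonicalized so
#' each variate's largest-magnitude musical (X) loading is positive, making
#' results deterministic across linear-algebra backends. When n <= p + q
#' the whitening is ridge-regularized (epsilon on the correlation
#' matrices) with a warning.
#'
#' @param X,Y numeric matrices with the same number of rows (column names
#'   recommended)
#' @param k number of variate pairs to return (default min(p, q))
#' @param ridge ridge added to the correlation matrices when the sample is
#'   degenerate
#' @return a `cca_result`: weights `wx`, `wy`; variates `U`, `V`;
#'   correlations `cor`; loadings `loadings_x`, `loadings_y`; relative
#'   covariance `relcov` (%); Wilks p-values `wilks_p`; dims `n`, `p`, `q`;
#'   `regularized` flag
#' @export
fit_cca <- function(X, Y, k = NULL, ridge = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X)
  sx <- std_cols(X); sy <- std_cols(Y)
  if (!all(sx$keep)) warning("dropped zero-variance X columns: ",
                             paste(colnames(X)[!sx$keep], collapse = ", "))
  if (!all(sy$keep)) warning("dropped zero-variance Y columns: ",
                             paste(colnames(Y)[!sy$keep], collapse = ", "))
  Xs <- sx$M; Ys <- sy$M
  p <- ncol(Xs); q <- ncol(Ys)
  regularized <- n <= p + q
  if (regularized)
    warning("n <= p + q: ridge-regularized whitening engaged")
  eps <- if (regularized) ridge else 0
  Rxx <- stats::cor(Xs); Ryy <- stats::cor(Ys); Rxy <- stats::cor(Xs, Ys)
  Wx <- mat_inv_sqrt(Rxx, eps); Wy <- mat_inv_sqrt(Ryy, eps)
  sv <- svd(Wx %*% Rxy %*% Wy)
  if (is.null(k)) k <- min(p, q)
  k <- min(k, min(p, q))
  r <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  wx <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  wy <- Wy %*% sv$v[, seq_len(k), drop = FALSE]
  U <- Xs %*% wx; V <- Ys %*% wy
  for (i in seq_len(k)) {                    # unit-variance variates
    su <- stats::sd(U[, i]); sv2 <- stats::sd(V[, i])
    if (su > 0) { U[, i] <- U[, i] / su; wx[, i] <- wx[, i] / su }
    if (sv2 > 0) { V[, i] <- V[, i] / sv2; wy[, i] <- wy[, i] / sv2 }
  }
  lx <- stats::cor(Xs, U)
  for (i in seq_len(k)) {                    # sign canonicalization
    j <- which.max(abs(lx[, i]))
    if (lx[j, i] < 0) {
      wx[, i] <- -wx[, i]; wy[, i] <- -wy[, i]
      U[, i] <- -U[, i]; V[, i] <- -V[, i]
    }
  }
  lx <- stats::cor(Xs, U); ly <- stats::cor(Ys, V)
  rownames(lx) <- colnames(Xs); rownames(ly) <- colnames(Ys)
  res <- structure(list(wx = wx, wy = wy, U = U, V = V, cor = r,
                        loadings_x = lx, loadings_y = ly,
                        n = n, p = p, q = q, regularized = regularized,
                        x_names = colnames(Xs), y_names = colnames(Ys)),
                   class = "cca_result")
  res$relcov <- relative_covariance(res)
  res$wilks_p <- wilks_test(res)$p
  res
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> n=%d p=%d q=%d%s\n", x$n, x$p, x$q,
              if (x$regularized) " (ridge-regularized)" else ""))
  print(round(data.frame(cor = x$cor, relcov_pct = x$relcov,
                         wilks_p = x$wilks_p), 4))
  invisible(x)
}

#' Canonical loadings
#'
#' Within-set correlations between each original column and its own set's
#' canonical variates (structural coefficients).
#'
#' @param result a `cca_result`
#' @return list with matrices `x` (p x k) and `y` (q x k)
#' @export
cca_loadings <- function(result) {
  stopifnot(inherits(result, "cca_result"))
  list(x = result$loadings_x, y = result$loadings_y)
}

#' Relative covariance per canonical variate
#'
#' Share of squared canonical correlation: 100 * r_i^2 / sum_j r_j^2. The
#' shares sum to 100%.
#'
#' @param result a `cca_result`
#' @return numeric vector of percentages
#' @export
relative_covariance <- function(result) {
  r2 <- result$cor^2
  if (sum(r2) == 0) return(rep(0, length(r2)))
  100 * r2 / sum(r2)
}

#' Wilks' lambda sequence test
#'
#' Lambda_k = prod_(i >= k) (1 - r_i^2) with Bartlett's chi-square
#' approximation, df = (p - k + 1)(q - k + 1), testing that canonical
#' correlations from the k-th onwards are jointly zero.
#'
#' @param result a `cca_result`, or `NULL` if `r`, `n`, `p`, `q` are given
#' @param r canonical correlations (used when `result` is `NULL`)
#' @param n,p,q sample size and variable counts
#' @return data.frame with `lambda`, `statistic`, `df`, `p` per variate
#' @export
wilks_test <- function(result = NULL, r = result$cor, n = result$n,
                       p = result$p, q = result$q) {
  k <- length(r)
  lam <- rev(cumprod(rev(1 - r^2)))
  stat <- -(n - 1 - (p + q + 1) / 2) * log(pmax(lam, 1e-300))
  df <- (p - seq_len(k) + 1) * (q - seq_len(k) + 1)
  pv <- stats::pchisq(pmax(stat, 0), df, lower.tail = FALSE)
  pv[lam >= 1] <- 1
  data.frame(variate = seq_len(k), lambda = lam, statistic = pmax(stat, 0),
             df = df, p = pv)
}

#' Surrogate-based variate retention
#'
#' Refits the CCA on surrogates in which the rows of Y are independently
#' permuted (breaking the music-physiology alignment while preserving each
#' set's covariance exactly). A variate is retained iff its canonical
#' correlation exceeds the maximum over variate positions of the mean
#' surrogate correlation AND its Wilks p-value is below `alpha`.
#' A circular-shift surrogate is available as an alternative.
#'
#' @param X,Y input matrices
#' @param n_surrogates number of surrogates (>= 20)
#' @param seed RNG seed
#' @param alpha Wilks significance level
#' @param method `"permute"` (row permutation) or `"shift"` (circular row
#'   shift of Y by a random offset)
#' @return list: logical `retained`, numeric `threshold`, matrix
#'   `surrogate_cor` (surrogate x variate), the fitted `result`
#' @export
surrogate_selection <- function(X, Y, n_surrogates = 100, seed = 1L,
                                alpha = 0.05, method = c("permute", "shift")) {
  method <- match.arg(method)
  if (n_surrogates < 20) stop("need at least 20 surrogates")
  fit <- fit_cca(X, Y)
  n <- nrow(Y)
  sur <- with_seed(seed, {
    t(vapply(seq_len(n_surrogates), function(s) {
      idx <- if (method == "permute") sample.int(n) else
        (seq_len(n) + sample.int(n - 1, 1) - 1) %% n + 1
      suppressWarnings(fit_cca(X, Y[idx, , drop = FALSE])$cor)
    }, numeric(length(fit$cor))))
  })
  threshold <- max(colMeans(sur))
  retained <- fit$cor > threshold & fit$wilks_p < alpha
  list(retained = retained, threshold = threshold, surrogate_cor = sur,
       result = fit)
}

#' Permutation p-values for canonical correlations
#'
#' p_i = (1 + #\{perm: r_i^perm >= r_i\}) / (1 + n_perm) under row
#' permutation of Y.
#'
#' @param X,Y input matrices
#' @param n_perm number of permutations
#' @param seed RNG seed
#' @return numeric p-value per variate
#' @export
permutation_pvalues <- function(X, Y, n_perm = 199, seed = 1L) {
  fit <- fit_cca(X, Y)
  n <- nrow(Y)
  with_seed(seed, {
    exceed <- numeric(length(fit$cor))
    for (b in seq_len(n_perm)) {
      rp <- suppressWarnings(fit_cca(X, Y[sample.int(n), , drop = FALSE])$cor)
      exceed <- exceed + (rp >= fit$cor)
    }
    (1 + exceed) / (1 + n_perm)
  })
}
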