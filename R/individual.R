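# Individual-level analysis: subject-wise CCA, cosine similarity of
# individual loading patterns to the group pattern, and generalized
# additive models relating similarity to baseline autonomic and demographic
# predictors, with Benjamini-Hochberg correction.

#' Subject-wise canonical correlation analysis
#'
#' Fits the same CCA pipeline on a single listener's unaveraged
#' physiological GKF values, restricted to the pieces in their playlist;
#' matrix size is therefore set by the musical change points of that
#' playlist. Ridge regularization engages automatically when n <= p + q.
#' Listeners providing fewer than `min_rows` rows are skipped with a
#' recorded reason.
#'
#' @param inputs list with matrices `X`, `Y` for this listener (from
#'   [assemble_cca_inputs()] on their playlist)
#' @param min_rows minimum usable row count
#' @return list with `fitted` flag, and either `result` (a `cca_result`)
#'   or `reason` plus the offending `n`
#' @export
subjectwise_cca <- function(inputs, min_rows = 12) {
  n <- nrow(inputs$X)
  if (is.null(n) || n < min_rows)
    return(list(fitted = FALSE, n = if (is.null(n)) 0L else n,
                reason = sprintf("only %d rows (< %d)",
                                 if (is.null(n)) 0L else n, min_rows)))
  res <- suppressWarnings(fit_cca(inputs$X, inputs$Y))
  list(fitted = TRUE, n = n, result = res)
}

#' Cosine similarity between loading patterns
#'
#' dot(a, b) / (|a| |b|) on the concatenated music + physiology loadings of
#' the first retained variate. The CCA sign indeterminacy is resolved by
#' flipping the individual vector when that raises the similarity
#' (`align = TRUE`, default), making the similarity effectively in
#' \[0, 1\]; set `align = FALSE` for the raw signed value.
#'
#' @param individual,group numeric loading vectors, same variable order
#' @param align resolve the sign indeterminacy by flipping
#' @return cosine similarity
#' @export
cosine_similarity <- function(individual, group, align = TRUE) {
  stopifnot(length(individual) == length(group))
  na <- sqrt(sum(individual^2)); nb <- sqrt(sum(group^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cs <- sum(individual * group) / (na * nb)
  if (align) abs(cs) else cs
}

# concatenated named loading vector for one variate of a cca_result
loading_vector <- function(result, variate = 1) {
  c(stats::setNames(result$loadings_x[, variate], rownames(result$loadings_x)),
    stats::setNames(result$loadings_y[, variate], rownames(result$loadings_y)))
}

# align an individual loading vector onto the group's variable order;
# columns dropped from a degenerate subject-wise fit contribute 0
align_loadings <- function(ind, group_names) {
  out <- stats::setNames(rep(0, length(group_names)), group_names)
  common <- intersect(names(ind), group_names)
  out[common] <- ind[common]
  out
}

#' Per-listener similarity records
#'
#' Runs [subjectwise_cca()] for every listener and computes the cosine
#' similarity of each individual first-variate loading pattern to the
#' group-level pattern.
#'
#' @param listener_inputs named list (listener id -> `X`/`Y` input list)
#' @param group_result group-level `cca_result`
#' @param variate group variate to compare against
#' @return list with data.frame `records` (listener, similarity, n) and
#'   data.frame `skipped` (listener, n, reason)
#' @export
similarity_records <- function(listener_inputs, group_result, variate = 1) {
  grp <- loading_vector(group_result, variate)
  recs <- NULL; skipped <- NULL
  for (id in names(listener_inputs)) {
    sw <- subjectwise_cca(listener_inputs[[id]])
    if (!sw$fitted) {
      skipped <- rbind(skipped, data.frame(listener = id, n = sw$n,
                                           reason = sw$reason))
      next
    }
    ind <- align_loadings(loading_vector(sw$result, 1), names(grp))
    recs <- rbind(recs, data.frame(listener = id,
                                   similarity = cosine_similarity(ind, grp),
                                   n = sw$n))
  }
  list(records = recs, skipped = skipped)
}

#' GAM analysis of similarity predictors
#'
#' Identity-link Gaussian GAM of cosine similarity on baseline and
#' demographic predictors: cubic B-spline smooths (basis dimension `k`,
#' GCV-selected smoothing) for the PNS/SNS indices, baseline SYS/DIA and
#' age; linear terms for gender, musicianship and classical preference.
#' Per-term p-values are Benjamini-Hochberg adjusted across all terms.
#' With fewer than `min_smooth_n` records (or `smooth = FALSE`) all terms
#' enter linearly, with a warning.
#'
#' @param records data.frame with columns `similarity`, `pns`, `sns`,
#'   `sys`, `dia`, `age`, `gender`, `musician`, `classical_pref`
#' @param k B-spline basis dimension
#' @param smooth use smooth terms when the sample allows
#' @param min_smooth_n minimum records for smooth terms
#' @return a `gam_report`: data.frame `terms` (term, type, p, q, edf or
#'   coefficient), the fitted `model`, `smooth` flag
#' @export
fit_gam <- function(records, k = 5, smooth = TRUE, min_smooth_n = 30) {
  need <- c("similarity", "pns", "sns", "sys", "dia", "age", "gender",
            "musician", "classical_pref")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  records <- records[stats::complete.cases(records[, need]), ]
  use_smooth <- smooth && nrow(records) >= min_smooth_n
  if (!use_smooth && smooth)
    warning("fewer than ", min_smooth_n,
            " records: falling back to linear terms")
  sm <- c("pns", "sns", "sys", "dia", "age")
  lin <- c("gender", "musician", "classical_pref")
  if (use_smooth) {
    fml <- stats::as.formula(paste(
      "similarity ~",
      paste(sprintf("s(%s, bs = 'bs', k = %d, m = c(3, 2))", sm, k),
            collapse = " + "),
      "+", paste(lin, collapse = " + ")))
    fit <- mgcv::gam(fml, data = records, method = "GCV.Cp")
    s_tab <- summary(fit)$s.table
    p_tab <- summary(fit)$p.table
    terms <- rbind(
      data.frame(term = sm, type = "smooth",
                 value = s_tab[, "edf"], p = s_tab[, "p-value"]),
      data.frame(term = rownames(p_tab)[-1], type = "linear",
                 value = p_tab[-1, "Estimate"], p = p_tab[-1, "Pr(>|t|)"]))
  } else {
    fml <- stats::as.formula(paste("similarity ~",
                                   paste(c(sm, lin), collapse = " + ")))
    fit <- stats::lm(fml, data = records)
    cf <- summary(fit)$coefficients
    terms <- data.frame(term = rownames(cf)[-1], type = "linear",
                        value = cf[-1, "Estimate"], p = cf[-1, "Pr(>|t|)"])
  }
  terms$q <- stats::p.adjust(terms$p, method = "BH")
  rownames(terms) <- NULL
  structure(list(terms = terms, model = fit, smooth = use_smooth,
                 n = nrow(records)), class = "gam_report")
}

#' Partial-effect curve of a smooth term
#'
#' Fitted partial effect of one smooth predictor over its observed range,
#' other predictors held at their means/modes; used for plotting and for
#' the direction-consistency checks.
#'
#' @param report a `gam_report` from a smooth fit
#' @param term predictor name (e.g. `"pns"`)
#' @param n_grid evaluation points
#' @return data.frame with the predictor grid and `effect`
#' @export
gam_partial_effect <- function(report, term, n_grid = 50) {
  stopifnot(inherits(report, "gam_report"))
  if (!report$smooth) stop("partial effects require a smooth fit")
  dat <- report$model$model
  grid <- seq(min(dat[[term]]), max(dat[[term]]), length.out = n_grid)
  base <- dat[rep(1, n_grid), ]
  for (v in names(dat)) {
    if (v == term || v == "similarity") next
    base[[v]] <- if (is.numeric(dat[[v]])) mean(dat[[v]])
                 else dat[[v]][which.max(table(dat[[v]]))[1]]
  }
  base[[term]] <- grid
  eff <- stats::predict(report$model, newdata = base, type = "response")
  out <- data.frame(grid, effect = as.numeric(eff))
  names(out)[1] <- term
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, explicit wrapper kept for the analysis tables; identical to
#' `p.adjust(p, "BH")`.
#' @param p p-values
#' @return q-values (monotone under the step-up rule, q >= p)
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
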