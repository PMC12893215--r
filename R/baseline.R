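# Baseline HRV summaries, PNS/SNS composite indices, and k-means
# stratification of listeners into three autonomic clusters.

#' Baseline HRV summary statistics
#'
#' Time-domain and Poincare descriptors of a baseline RR recording:
#' mean RR / mean HR, RMSSD, SDNN, SD1/SD2 (with normalized-unit shares)
#' and Baevsky's stress index computed from a 50 ms RR histogram
#' (SI = AMo% / (2 * Mo * MxDMn), Mo the modal bin centre in s, MxDMn the
#' RR range in s).
#'
#' @param rr baseline RR intervals in seconds (>= 120 beats)
#' @param bin_ms histogram bin width for the stress index, ms
#' @return object of class `hrv_summary` with fields `mean_rr` (s),
#'   `mean_hr` (bpm), `rmssd`, `sdnn`, `sd1`, `sd2` (ms), `sd1nu`, `sd2nu`
#'   (%), `baevsky_si`, and a `degenerate` flag for constant input
#' @export
hrv_summary <- function(rr, bin_ms = 50) {
  if (length(rr) < 120) stop("need >= 120 baseline beats")
  mean_rr <- mean(rr)
  d <- diff(rr) * 1000                       # ms
  sdnn <- stats::sd(rr) * 1000
  degenerate <- sdnn < .Machine$double.eps^0.5
  rmssd <- sqrt(mean(d^2))
  sd1 <- stats::sd(d) / sqrt(2)
  sd2sq <- 2 * sdnn^2 - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  tot <- sd1 + sd2
  sd1nu <- if (tot > 0) 100 * sd1 / tot else NA_real_
  sd2nu <- if (tot > 0) 100 * sd2 / tot else NA_real_
  # Baevsky stress index on a 50 ms histogram
  bw <- bin_ms / 1000
  br <- seq(floor(min(rr) / bw) * bw, max(rr) + bw, by = bw)
  h <- table(cut(rr, br, right = FALSE))
  amo <- 100 * max(h) / length(rr)
  mo <- br[which.max(h)] + bw / 2
  mxdmn <- max(rr) - min(rr)
  si <- if (mxdmn > 0) amo / (2 * mo * mxdmn) else Inf
  structure(list(mean_rr = mean_rr, mean_hr = 60 / mean_rr, rmssd = rmssd,
                 sdnn = sdnn, sd1 = sd1, sd2 = sd2, sd1nu = sd1nu,
                 sd2nu = sd2nu, baevsky_si = si, degenerate = degenerate),
            class = "hrv_summary")
}

#' Cohort-standardized PNS and SNS indices
#'
#' Composite autonomic indices as means of cohort z-scores: PNS from
#' (mean RR, RMSSD, SD1nu), SNS from (mean HR, Baevsky SI, SD2nu). A
#' zero-variance constituent is dropped with a warning. Standardization is
#' within-cohort (not against population norms), so values are comparable
#' within a cohort only.
#'
#' @param summaries list of [hrv_summary()] objects (>= 3 listeners)
#' @return data.frame with columns `pns`, `sns`, one row per listener
#' @export
pns_sns_indices <- function(summaries) {
  if (length(summaries) < 3) stop("need >= 3 listeners")
  get <- function(f) vapply(summaries, `[[`, numeric(1), f)
  zs <- function(v, name) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("constituent '", name, "' has zero variance; dropped")
      return(NULL)
    }
    (v - mean(v)) / s
  }
  comp <- function(fields) {
    zl <- Filter(Negate(is.null), lapply(fields, function(f) zs(get(f), f)))
    if (!length(zl)) return(rep(0, length(summaries)))
    rowMeans(do.call(cbind, zl))
  }
  data.frame(pns = comp(c("mean_rr", "rmssd", "sd1nu")),
             sns = comp(c("mean_hr", "baevsky_si", "sd2nu")))
}

#' k-means stratification into three autonomic clusters
#'
#' Clusters listeners on (PNS, SNS) with k = 3 and multiple restarts, then
#' relabels clusters by descending mean(PNS - SNS) so label 1 is always the
#' parasympathetic-dominant group, 2 balanced, 3 sympathetic-dominant -
#' independent of k-means initialization. Warns when the clustering is
#' poorly separated (mean silhouette below `min_silhouette`; forcing k = 3
#' on a single 2-D blob yields silhouettes around 0.35-0.5, well-separated
#' archetypes 0.7+, hence the 0.45 default).
#'
#' @param indices data.frame from [pns_sns_indices()]
#' @param seed RNG seed for the k-means restarts
#' @param nstart number of random restarts
#' @param k number of clusters (3 in the analysis design)
#' @param min_silhouette separation warning threshold
#' @return list with integer `cluster` labels, cluster `centers`, mean
#'   `silhouette`, and `low_separation` flag
#' @export
cluster_autonomic <- function(indices, seed = 1L, nstart = 25L, k = 3L,
                              min_silhouette = 0.45) {
  x <- as.matrix(indices[, c("pns", "sns")])
  if (nrow(x) < k) stop("need at least k = ", k, " listeners")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  ord <- order(km$centers[, "pns"] - km$centers[, "sns"], decreasing = TRUE)
  relab <- match(km$cluster, ord)
  sil <- mean_silhouette(x, relab)
  low <- is.finite(sil) && sil < min_silhouette
  if (low) warning(sprintf("low cluster separation (silhouette %.2f)", sil))
  list(cluster = relab, centers = km$centers[ord, , drop = FALSE],
       silhouette = sil, low_separation = low)
}

# save/restore .Random.seed so seeded helpers do not disturb callers
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Mean silhouette width
#'
#' Plain-definition silhouette (Euclidean distances) used as a separation
#' diagnostic for the autonomic clustering.
#' @param x numeric matrix of observations
#' @param labels integer cluster labels
#' @return mean silhouette width over all points
#' @export
mean_silhouette <- function(x, labels) {
  n <- nrow(x)
  if (length(unique(labels)) < 2 || n < 3) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions corrected for chance; used to score
#' cluster recovery against planted archetypes.
#' @param a,b integer label vectors of equal length
#' @return ARI in \[-1, 1\] (1 = identical partitions)
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  expected <- si * sj / n2
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}
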