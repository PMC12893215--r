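# Gaussian-kernel event-density series and assembly of the CCA input
# matrices: X (musical channels + annotation categories) and Y
# (physiological channels), sampled at musical change-point onsets.

#' Gaussian-kernel series from event onsets
#'
#' Sum of unit-peak Gaussian kernels centred at the onsets:
#' value(t) = sum_k exp(-(t - t_k)^2 / (2 sigma^2)). An isolated onset
#' attains exactly 1 at its centre, so values read as event proximity in
#' \[0, number of overlapping events\]. An empty onset list yields the
#' all-zero series.
#'
#' @param onsets event times in seconds
#' @param sigma kernel SD in seconds (> 0)
#' @param start,end,rate grid specification (seconds, seconds, Hz)
#' @param channel channel/category label
#' @return a `gkf_series` (subclass of [uniform_series()]) with `sigma`
#' @export
gkf <- function(onsets, sigma = 2, start = 0, end, rate = 5, channel = "") {
  if (sigma <= 0) stop("sigma must be > 0")
  t <- seq(start, end, by = 1 / rate)
  v <- numeric(length(t))
  for (on in onsets) v <- v + exp(-(t - on)^2 / (2 * sigma^2))
  s <- uniform_series(v, rate = rate, start = start, channel = channel,
                      units = "")
  s$sigma <- sigma
  class(s) <- c("gkf_series", class(s))
  s
}

#' Average physiological GKF series across listeners
#'
#' Pointwise mean of per-listener GKF series for one performance on their
#' common grid; the listener count is recorded on the result.
#'
#' @param series_list list of `gkf_series` on identical grids (>= 1)
#' @return a `gkf_series` with attribute `n_listeners`
#' @export
average_listeners <- function(series_list) {
  if (!length(series_list)) stop("need at least one listener")
  ref <- series_list[[1]]
  for (s in series_list[-1])
    if (!same_grid(ref, s)) stop("grid mismatch between listeners")
  out <- ref
  out$values <- rowMeans(vapply(series_list, `[[`, numeric(length(ref)),
                                "values"))
  attr(out, "n_listeners") <- length(series_list)
  out
}

#' Merge nearby onsets
#'
#' Deduplicates a pooled onset list with the same minimum-spacing rule as
#' the ensemble detector: while two onsets are closer than `delta` they are
#' replaced by their (weight-)mean time.
#'
#' @param times onset times in seconds
#' @param delta minimum spacing in seconds
#' @param weights optional merge weights (default equal)
#' @return sorted merged onset times
#' @export
merge_onsets <- function(times, delta, weights = NULL) {
  if (!length(times)) return(numeric(0))
  if (is.null(weights)) weights <- rep(1, length(times))
  o <- order(times); t <- times[o]; w <- weights[o]
  while (length(t) > 1 && min(diff(t)) < delta) {
    i <- which.min(diff(t))
    tm <- (t[i] * w[i] + t[i + 1] * w[i + 1]) / (w[i] + w[i + 1])
    wm <- w[i] + w[i + 1]
    t <- c(t[seq_len(i - 1)], tm, t[-seq_len(i + 1)])
    w <- c(w[seq_len(i - 1)], wm, w[-seq_len(i + 1)])
  }
  t
}

#' Assemble CCA input matrices
#'
#' One row per musical change point. For each piece entry, the row universe
#' is the delta-merged union of the musical onsets supplied; every column
#' value is that channel's GKF series evaluated at the row's onset time.
#'
#' @param pieces list with one entry per piece/performance, each a list
#'   with: `piece`, `version`, `onsets` (musical change-point onset times,
#'   seconds), `x_gkf` (named list of musical `gkf_series`), `y_gkf` (named
#'   list of physiological `gkf_series`, typically listener-averaged)
#' @param delta minimum onset spacing for row deduplication (s)
#' @return list with matrices `X` (n x p), `Y` (n x q) carrying column
#'   names, and `index` (data.frame piece, version, onset_s), rows ordered
#'   by (piece, onset)
#' @export
assemble_cca_inputs <- function(pieces, delta = 5) {
  xs <- ys <- list(); idx <- NULL
  xnames <- names(pieces[[1]]$x_gkf)
  ynames <- names(pieces[[1]]$y_gkf)
  for (pc in pieces) {
    ons <- sort(merge_onsets(pc$onsets, delta))
    if (!length(ons)) next
    for (srcs in list(pc$x_gkf, pc$y_gkf))
      for (nm in names(srcs)) {
        tt <- series_time(srcs[[nm]])
        bad <- ons < min(tt) - 1e-9 | ons > max(tt) + 1e-9
        if (any(bad))
          stop(sprintf("onset %.2f s outside support of channel '%s' (piece %s)",
                       ons[which(bad)[1]], nm, pc$piece))
      }
    xs[[length(xs) + 1]] <- vapply(pc$x_gkf, series_at, numeric(length(ons)),
                                   at = ons)
    ys[[length(ys) + 1]] <- vapply(pc$y_gkf, series_at, numeric(length(ons)),
                                   at = ons)
    idx <- rbind(idx, data.frame(piece = pc$piece, version = pc$version,
                                 onset_s = ons))
  }
  if (is.null(idx)) stop("no musical change points supplied")
  X <- do.call(rbind, lapply(xs, matrix, ncol = length(xnames)))
  Y <- do.call(rbind, lapply(ys, matrix, ncol = length(ynames)))
  colnames(X) <- xnames; colnames(Y) <- ynames
  if (anyNA(X) || anyNA(Y)) stop("missing values after assembly")
  list(X = X, Y = Y, index = idx)
}
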