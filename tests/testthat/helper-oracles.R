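# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (plain-R definitional computations).

# exhaustive O(n^2) dynamic program for the penalized Gaussian mean-shift
# segmentation; exact optimum, no pruning. Returns 0-based segment starts
# to match the C++ kernels.
dp_mean_oracle <- function(x, beta, minlen = 2) {
  n <- length(x)
  s1 <- cumsum(c(0, x)); s2 <- cumsum(c(0, x^2))
  cost <- function(a, b) {       # [a, b) in 0-based half-open indices
    len <- b - a
    (s2[b + 1] - s2[a + 1]) - (s1[b + 1] - s1[a + 1])^2 / len
  }
  F <- rep(Inf, n + 1); F[1] <- -beta
  prev <- integer(n + 1)
  for (t in minlen:n) {
    best <- Inf; arg <- 0L
    for (s in 0:(t - minlen)) {
      if (s > 0 && s < minlen) next
      v <- F[s + 1] + cost(s, t) + beta
      if (v < best) { best <- v; arg <- s }
    }
    F[t + 1] <- best; prev[t + 1] <- arg
  }
  cps <- integer(0); t <- n
  while (t > 0) { s <- prev[t + 1]; if (s > 0) cps <- c(s, cps); t <- s }
  list(cps = cps, cost = F[n + 1])
}

# definitional Poincare SD1: SD of the rotated (x_{i+1} - x_i)/sqrt(2) axis
sd1_oracle <- function(rr) stats::sd(diff(rr) / sqrt(2)) * 1000

# brute-force loading: plain correlation of each standardized column with
# the variate
loading_oracle <- function(M, variate) {
  apply(M, 2, function(col) stats::cor(col, variate))
}

# hand-computed BH step-up
bh_oracle <- function(p) {
  m <- length(p); o <- order(p, decreasing = TRUE)
  q <- numeric(m); prev <- 1
  for (i in seq_along(o)) {
    rank <- m - i + 1
    prev <- min(prev, p[o[i]] * m / rank)
    q[o[i]] <- prev
  }
  q
}

# small synthetic cohort config used by several files (fast to generate)
tiny_sim <- function(seed = 11, ...) {
  args <- utils::modifyList(list(n_pieces = 2, n_listeners = 4,
                                 playlist_length = 3, piece_duration_s = 300,
                                 seed = seed), list(...))
  do.call(sim_config, args)
}

# event function over planted truth: annotation events by category plus
# acoustic truth change points by channel x direction
truth_events_fn <- function(cohort) {
  function(li, si, category) {
    pl <- cohort$listeners[[li]]$playlist
    p <- pl$piece[si]
    ann <- cohort$annotations[[p]]
    if (category %in% annotation_categories())
      return(ann$events$onset_s[ann$events$category == category])
    tc <- cohort$music[[p]][[1]]$truth_changepoints
    m <- regmatches(category, regexec("^(.*)_(up|down)$", category))[[1]]
    if (length(m) == 3)
      return(tc$time_s[tc$channel == m[2] & tc$direction == m[3]])
    numeric(0)
  }
}
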