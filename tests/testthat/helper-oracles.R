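# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: enumeration, bitmaps, and direct formula
# evaluation at tiny problem sizes.

# Exhaustive Viterbi: maximize the joint log probability over all 2^T state
# paths of the two-state HMM.
enumerate_viterbi <- function(obs, params) {
  T_ <- length(obs)
  best <- -Inf
  best_path <- NULL
  for (code in 0:(2^T_ - 1)) {
    path <- as.integer(intToBits(code)[1:T_])
    lp <- log(params$prior[path[1] + 1]) + log(params$emit[path[1] + 1, obs[1] + 1])
    if (T_ > 1) for (t in 2:T_) {
      lp <- lp + log(params$trans[path[t - 1] + 1, path[t] + 1]) +
        log(params$emit[path[t] + 1, obs[t] + 1])
    }
    # mirror the decoder's hom-preferring tie break: strictly better wins,
    # equal keeps the earlier (lower-code, more-hom) path
    if (lp > best + 1e-12) {
      best <- lp
      best_path <- path
    }
  }
  best_path
}

# Bitmap union coverage: place intervals on a logical vector.
bitmap_covered <- function(starts, lens, L) {
  v <- logical(L)
  for (j in seq_along(starts)) {
    v[(starts[j] + 1):(starts[j] + lens[j])] <- TRUE
  }
  sum(v)
}

# Bitmap re-implementation of the coverage-threshold trial: number of draws
# until each target fraction is covered.
bitmap_threshold_trial <- function(L, length_sampler, targets) {
  v <- logical(L)
  counts <- rep(NA_integer_, length(targets))
  n <- 0L
  while (anyNA(counts)) {
    len <- length_sampler(1)
    while (len > L) len <- length_sampler(1)
    s <- floor(runif(1, 0, L - len + 1))
    v[(s + 1):(s + len)] <- TRUE
    n <- n + 1L
    tot <- sum(v)
    counts[is.na(counts) & targets * L <= tot] <- n
  }
  counts
}

# Direct hypergeometric projection by enumeration over subsets is
# unnecessary; dhyper is the closed form. This helper instead computes the
# projected class mass from first principles with explicit binomials.
project_mass_oracle <- function(counts, n, m, j) {
  i <- seq_len(n - 1)
  sum(counts * choose(i, j) * choose(n - i, m - j) / choose(n, m))
}

# chi-square statistic from the textbook formula, no continuity correction
chisq_stat_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# base-level recall/precision of detected segments against truth tracts
segment_base_metrics <- function(detected, truth, L) {
  mark <- function(df) {
    v <- logical(L)
    for (j in seq_len(nrow(df))) v[(df$start[j] + 1):df$end[j]] <- TRUE
    v
  }
  d <- if (nrow(detected)) mark(detected) else logical(L)
  t_ <- if (nrow(truth)) mark(truth) else logical(L)
  list(recall = if (sum(t_) == 0) NA else sum(d & t_) / sum(t_),
       precision = if (sum(d) == 0) NA else sum(d & t_) / sum(d))
}
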