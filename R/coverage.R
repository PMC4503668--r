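#' Build a duplication length sampler
#'
#' Either the empirical distribution of an observed call table (sampling
#' lengths with replacement) or a parametric law for synthetic runs.
#'
#' @param x Numeric vector of observed lengths, or a length law list (see
#'   [synth_config()]).
#' @return A function `f(n)` returning `n` lengths in bp.
#' @export
make_length_sampler <- function(x) {
  if (is.numeric(x)) {
    .assert(length(x) > 0 && all(x > 0), "lengths must be positive")
    lengths <- as.numeric(x)
    function(n) sample(lengths, n, replace = TRUE)
  } else {
    .validate_length_law(x)
    function(n) draw_lengths(x, n)
  }
}

#' @noRd
.chrom_subseed <- function(seed, chrom) {
  if (is.null(seed)) return(NULL)
  # Deterministic per-chromosome substream, derived from the name alone so a
  # chromosome simulated by itself reproduces its slice of a multi-chromosome
  # run. Kept far below 2^31.
  (as.integer(seed) + sum(utf8ToInt(chrom))) %% 2147480000L
}

#' @noRd
.covered_width <- function(ranges) sum(IRanges::width(IRanges::reduce(ranges)))

#' Duplications required to cover a fraction of a chromosome
#'
#' Monte-Carlo answer to: drawing duplication lengths from the observed
#' length distribution and placing start sites uniformly on the chromosome
#' (uniform on [0, L - len], no wraparound), how many duplications are
#' needed before their union covers 10/25/50/90% of the sequence? Union
#' coverage is tracked exactly by merged interval lists. Chromosomes are
#' simulated independently on per-chromosome RNG substreams.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param length_sampler A function from [make_length_sampler()]; drawn
#'   lengths longer than the chromosome are redrawn (they cannot be placed).
#' @param targets Coverage fractions to hit (each in (0, 1]).
#' @param trials Monte-Carlo trials per chromosome (default 1000).
#' @param seed Optional base seed.
#' @return List of class `coverage_sim_result`: `counts` (data.frame
#'   `chrom`, `trial`, `target`, `count`) and `summary` (mean and quartiles
#'   of the count per chromosome and target).
#' @export
coverage_threshold_sim <- function(chrom_lengths, length_sampler,
                                   targets = c(0.1, 0.25, 0.5, 0.9),
                                   trials = 1000L, seed = NULL) {
  .assert(all(targets > 0 & targets <= 1), "targets must lie in (0, 1]")
  .assert(trials >= 1, "trials must be >= 1")
  targets <- sort(targets)
  rows <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    .with_seed(.chrom_subseed(seed, ch), {
      out <- matrix(NA_integer_, nrow = trials, ncol = length(targets))
      for (tr in seq_len(trials)) {
        out[tr, ] <- .single_coverage_trial(L, length_sampler, targets)
      }
      data.frame(chrom = ch,
                 trial = rep(seq_len(trials), times = length(targets)),
                 target = rep(targets, each = trials),
                 count = as.vector(out))
    })
  })
  counts <- do.call(rbind, rows)
  agg <- aggregate(count ~ chrom + target, data = counts, FUN = function(x)
    c(mean = mean(x), q25 = quantile(x, 0.25, names = FALSE),
      median = quantile(x, 0.5, names = FALSE),
      q75 = quantile(x, 0.75, names = FALSE)))
  summary <- cbind(agg[c("chrom", "target")], as.data.frame(agg$count))
  structure(list(counts = counts, summary = summary, trials = trials),
            class = "coverage_sim_result")
}

#' @noRd
.single_coverage_trial <- function(L, length_sampler, targets,
                                   chunk_start = 64L, chunk_max = 4096L) {
  goal <- targets * L
  counts <- rep(NA_integer_, length(targets))
  covered <- IRanges::IRanges()
  tot_prev <- 0
  n_prev <- 0L
  chunk <- chunk_start
  while (anyNA(counts)) {
    len <- length_sampler(chunk)
    bad <- len > L
    while (any(bad)) {  # redraw lengths that cannot be placed
      len[bad] <- length_sampler(sum(bad))
      bad <- len > L
    }
    start <- floor(runif(chunk, 0, L - len + 1))
    new <- IRanges::IRanges(start = as.integer(start) + 1L, width = as.integer(len))
    merged <- IRanges::reduce(c(covered, new))
    tot <- sum(IRanges::width(merged))
    hit <- which(is.na(counts) & goal <= tot)
    for (h in hit) {
      # bisect for the minimal prefix of this chunk reaching the target
      lo <- 1L
      hi <- chunk
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        w <- sum(IRanges::width(IRanges::reduce(c(covered, new[seq_len(mid)]))))
        if (w >= goal[h]) hi <- mid else lo <- mid + 1L
      }
      counts[h] <- n_prev + lo
    }
    covered <- merged
    tot_prev <- tot
    n_prev <- n_prev + chunk
    chunk <- min(chunk * 2L, chunk_max)
  }
  counts
}

#' Genome fraction spanned by a fixed number of duplications
#'
#' Resamples `n_dups` duplication lengths from the observed distribution,
#' places each uniformly on a chromosome chosen proportionally to length,
#' and reports the mean (over replicates) of the fraction of the genome
#' covered by the union.
#'
#' @param n_dups Number of duplications to place (>= 0).
#' @inheritParams coverage_threshold_sim
#' @param reps Replicates (default 100).
#' @return List with `mean_fraction` and per-replicate `fractions`.
#' @export
span_fraction_sim <- function(n_dups, chrom_lengths, length_sampler,
                              reps = 100L, seed = NULL) {
  .assert(.is_count(n_dups), "n_dups must be a non-negative integer")
  genome <- sum(chrom_lengths)
  fractions <- .with_seed(seed, vapply(seq_len(reps), function(r) {
    if (n_dups == 0) return(0)
    len <- length_sampler(n_dups)
    bad <- len > max(chrom_lengths)
    while (any(bad)) {
      len[bad] <- length_sampler(sum(bad))
      bad <- len > max(chrom_lengths)
    }
    # chromosome assignment proportional to length among fitting chromosomes
    assign_chrom <- vapply(len, function(l) {
      fit <- names(chrom_lengths)[chrom_lengths >= l]
      if (length(fit) == 1) fit
      else sample(fit, 1, prob = chrom_lengths[fit] / sum(chrom_lengths[fit]))
    }, character(1))
    covered <- 0
    for (ch in unique(assign_chrom)) {
      l_ch <- len[assign_chrom == ch]
      L <- chrom_lengths[[ch]]
      start <- floor(runif(length(l_ch), 0, L - l_ch + 1))
      rng <- IRanges::IRanges(start = as.integer(start) + 1L,
                              width = as.integer(l_ch))
      covered <- covered + .covered_width(rng)
    }
    covered / genome
  }, numeric(1)))
  list(mean_fraction = mean(fractions), fractions = fractions)
}
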