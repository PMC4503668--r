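#' Sample site frequency spectrum
#'
#' Counts of variants by derived-allele frequency class i = 1..n-1 in a
#' sample of n sequences. Duplication panels use n = number of strains plus
#' the reference (frequencies are counted among the non-reference strains).
#'
#' @param counts Numeric vector of length n-1; element i is the number of
#'   variants observed at derived sample frequency i. Non-integer values are
#'   allowed (projected or corrected spectra are expectations).
#' @param n Sample size defining the frequency classes.
#' @param kind `"snp"` or `"duplication"`.
#' @param proportions Optional normalized spectrum (sums to 1).
#' @return An object of class `sample_sfs`.
#' @examples
#' sample_sfs(c(6, 3, 1), n = 4)
#' @export
sample_sfs <- function(counts, n, kind = c("snp", "duplication"),
                       proportions = NULL) {
  kind <- match.arg(kind)
  .assert(.is_count(n) && n >= 2, "n must be an integer >= 2")
  .assert(is.numeric(counts) && length(counts) == n - 1,
          "counts must have one entry per frequency class 1..n-1")
  .assert(all(counts >= 0), "counts must be non-negative")
  if (!is.null(proportions)) {
    .assert(length(proportions) == n - 1 && all(proportions >= -1e-12),
            "proportions must cover classes 1..n-1 and be non-negative")
    .assert(abs(sum(proportions) - 1) < 1e-8, "proportions must sum to 1")
  }
  structure(list(n = as.integer(n), counts = as.numeric(unname(counts)),
                 kind = kind, proportions = proportions),
            class = "sample_sfs")
}

#' @export
print.sample_sfs <- function(x, ...) {
  cat(sprintf("sample_sfs: n = %d, kind = %s, S = %.6g\n",
              x$n, x$kind, sum(x$counts)))
  print(setNames(x$counts, seq_len(x$n - 1L)))
  invisible(x)
}

#' Total number of segregating variants in a spectrum
#' @param sfs A [sample_sfs()].
#' @return Numeric scalar.
#' @export
sfs_total <- function(sfs) sum(sfs$counts)

#' Build a duplication SFS from a call table
#'
#' Bins duplication calls by sample frequency after two filters: strains
#' whose residually heterozygous segments (padded by `pad` bp on each side)
#' overlap a call are dropped from that call's denominator, and calls with
#' fewer than `min_strains` strains remaining, or flagged as present in the
#' reference assembly, are excluded altogether. Reference-present calls are
#' ascertainment artifacts (they cannot be discovered by divergent reads
#' against an accurate reference) and would otherwise distort the spectrum.
#'
#' @param calls Data.frame of duplication calls with columns `id`, `chrom`,
#'   `start`, `end`, `in_reference` (logical) and a list-column `strains`
#'   holding, per call, the character vector of carrier strains.
#' @param panel_n Sample size labelling the output spectrum classes
#'   (typically number of strains + 1 when the reference genome is part of
#'   the discovery panel).
#' @param strains Character vector of all sequenced strains; defaults to the
#'   union of carriers across calls.
#' @param het_mask Optional residual-heterozygosity segments: data.frame with
#'   columns `chrom`, `start`, `end`, `strain` (see [extract_segments()]).
#' @param min_strains Minimum strains remaining for a call to enter the SFS.
#' @param pad Padding (bp) applied to each heterozygous segment before
#'   overlap testing.
#' @return A [sample_sfs()] of kind `"duplication"` with attribute
#'   `"call_table"` giving per-call frequency and effective denominator.
#' @export
build_sfs <- function(calls, panel_n, strains = NULL, het_mask = NULL,
                      min_strains = 15L, pad = 1000L) {
  .assert(panel_n >= min_strains, "panel_n smaller than min_strains")
  if (is.null(strains)) strains <- sort(unique(unlist(calls$strains)))
  keep <- !isTRUE_vec(calls$in_reference)
  excl <- if (is.null(het_mask) || nrow(calls) == 0) {
    rep(list(character(0)), nrow(calls))
  } else {
    mask_features(calls, het_mask, pad = pad)
  }
  freq <- integer(nrow(calls))
  n_eff <- integer(nrow(calls))
  for (j in seq_len(nrow(calls))) {
    remaining <- setdiff(strains, excl[[j]])
    n_eff[j] <- length(remaining)
    freq[j] <- length(intersect(calls$strains[[j]], remaining))
  }
  keep <- keep & n_eff >= min_strains & freq >= 1 & freq <= panel_n - 1
  counts <- tabulate(freq[keep], nbins = panel_n - 1L)
  out <- sample_sfs(counts, n = panel_n, kind = "duplication")
  attr(out, "call_table") <- data.frame(
    id = if (!is.null(calls$id)) calls$id else seq_len(nrow(calls)),
    freq = freq, n_eff = n_eff, kept = keep
  )
  out
}

#' @noRd
isTRUE_vec <- function(x) if (is.null(x)) FALSE else as.logical(x) %in% TRUE

#' Correct a duplication SFS for reference-discovery ascertainment bias
#'
#' Duplications are discovered by divergently oriented reads relative to a
#' reference genome, so variants present in the reference individual are
#' invisible: a variant at sample frequency i out of n (reference included)
#' is detected only when the reference lacks it, which happens with
#' probability (n-i)/n. The corrected proportion of class i is therefore
#' \deqn{x_i = \frac{y_i\, n/(n-i)}{\sum_i y_i\, n/(n-i)}}
#' which shifts mass toward high-frequency classes.
#'
#' @param sfs A duplication [sample_sfs()] (counts or proportions over
#'   classes 1..n-1; class n is undefined under this sampling scheme).
#' @param sum_upper Upper bound of the normalization sum: `"n-1"` (default,
#'   covers every polymorphic class) or `"n-2"`.
#' @return A [sample_sfs()] whose `proportions` field holds the corrected
#'   spectrum; `counts` carries the input rescaled to the corrected shape.
#' @export
correct_ascertainment <- function(sfs, sum_upper = c("n-1", "n-2")) {
  sum_upper <- match.arg(sum_upper)
  .assert(inherits(sfs, "sample_sfs"), "sfs must be a sample_sfs")
  .assert(sfs$kind == "duplication",
          "ascertainment correction applies to duplication spectra")
  n <- sfs$n
  y <- sfs$counts
  .assert(sum(y) > 0, "all-zero spectrum cannot be corrected")
  i <- seq_len(n - 1L)
  w <- n / (n - i)
  upper <- if (sum_upper == "n-1") n - 1L else n - 2L
  denom <- sum((y * w)[seq_len(upper)])
  .assert(denom > 0, "normalization sum is zero")
  x <- y * w / denom
  sample_sfs(sum(y) * x / sum(x), n = n, kind = "duplication",
             proportions = x / sum(x))
}

#' Mispolarization probability from outgroup divergence
#'
#' When the ancestral state of a SNP is read off an outgroup genome, an
#' independent mutation at the same site in the outgroup lineage flips the
#' inferred polarity. With transition/transversion ratio kappa, the flip
#' probability is the chance of an identical independent transition at a
#' transition site plus half the chance of a transversion at a transversion
#' site, scaled by net divergence:
#' \deqn{k = \left[\left(\frac{\kappa}{2+\kappa}\right)^2 +
#'   \frac12\left(\frac{2}{2+\kappa}\right)^2\right] D_{net}}
#' with \eqn{D_{net} = Div_{x,y} - \pi_x}. At the empirical Drosophila
#' kappa = 2 this reduces to k = (3/8) D_net.
#'
#' @param divergence Per-site divergence to the outgroup.
#' @param pi_x Per-site heterozygosity of the focal species.
#' @param kappa Transition/transversion ratio (> 0), default 2.
#' @return Mispolarization probability k in [0, 0.5).
#' @export
mispolarization_rate <- function(divergence, pi_x, kappa = 2) {
  .assert(kappa > 0, "kappa must be positive")
  .assert(divergence >= pi_x, "divergence must be >= pi_x (D_net >= 0)")
  d_net <- divergence - pi_x
  k <- ((kappa / (2 + kappa))^2 + 0.5 * (2 / (2 + kappa))^2) * d_net
  .assert(k < 0.5, "resulting k >= 0.5: correction undefined")
  k
}

#' Apply mispolarization mixing to a spectrum
#'
#' The forward operator of ancestral-state error: each variant's recorded
#' class is i with probability 1-k and n-i with probability k, so in
#' expectation \eqn{S_{i,obs} = S_i (1-k) + S_{n-i} k}. This is the exact
#' inverse of [correct_polarization()].
#'
#' @param sfs A [sample_sfs()].
#' @param k Mispolarization probability in [0, 0.5).
#' @return A [sample_sfs()] with mixed expected counts.
#' @export
mix_polarization <- function(sfs, k) {
  .assert(k >= 0 && k < 0.5, "k must lie in [0, 0.5)")
  s <- sfs$counts
  sample_sfs(s * (1 - k) + rev(s) * k, n = sfs$n, kind = sfs$kind)
}

#' Correct an unfolded SFS for ancestral-state mispolarization
#'
#' Inverts the mixing of classes i and n-i caused by independent mutations
#' in the outgroup reference:
#' \deqn{E[S_i] = \frac{S_{i,obs}(1-k) - S_{n-i,obs}\,k}{1-2k}}
#' Total mass is conserved pairwise between classes i and n-i. On noisy
#' counts the estimate can go negative; negative entries are clipped to
#' zero with a warning.
#'
#' @inheritParams mix_polarization
#' @return A corrected [sample_sfs()].
#' @export
correct_polarization <- function(sfs, k) {
  .assert(k >= 0 && k < 0.5, "k must lie in [0, 0.5)")
  s <- sfs$counts
  est <- (s * (1 - k) - rev(s) * k) / (1 - 2 * k)
  if (any(est < 0)) {
    warning(sprintf("%d corrected classes were negative and clipped to 0",
                    sum(est < 0)))
    est <- pmax(est, 0)
  }
  sample_sfs(est, n = sfs$n, kind = sfs$kind)
}

#' Project an SFS onto a smaller sample size
#'
#' Hypergeometric downsampling: a variant at frequency i of n contributes to
#' class j of m with weight \eqn{\binom{i}{j}\binom{n-i}{m-j}/\binom{n}{m}}.
#' Classes j = 0 and j = m (projected to monomorphic) are dropped, so total
#' mass can shrink.
#'
#' @param sfs A [sample_sfs()].
#' @param m Target sample size, 2 <= m <= n.
#' @return A [sample_sfs()] on classes 1..m-1 (expected, non-integer counts).
#' @export
project_sfs <- function(sfs, m) {
  n <- sfs$n
  .assert(.is_count(m) && m >= 2 && m <= n, "need 2 <= m <= n")
  m <- as.integer(m)
  i <- seq_len(n - 1L)
  out <- vapply(seq_len(m - 1L), function(j) {
    sum(sfs$counts * dhyper(j, i, n - i, m))
  }, numeric(1))
  sample_sfs(out, n = m, kind = sfs$kind)
}

#' Expand a spectrum into one observation per variant
#' @noRd
.sfs_to_obs <- function(sfs) {
  counts <- round(sfs$counts)
  rep(seq_len(sfs$n - 1L), counts)
}

#' Contrast two site frequency spectra
#'
#' Non-parametric comparisons of per-variant sample-frequency lists (each
#' variant contributes its frequency class as one observation): Wilcoxon
#' rank-sum, Kolmogorov-Smirnov, or a chi-square test on a 2x2 table asking
#' whether high-frequency variants (class >= `highfreq_cutoff`) are
#' overrepresented in `a` relative to `b`.
#'
#' @param a,b [sample_sfs()] objects (counts are rounded to expand into
#'   observation lists).
#' @param method `"wilcoxon"`, `"ks"` or `"chi2_highfreq"`.
#' @param tails `"two"` (default) or `"one"`; one-tailed tests take
#'   `alternative` sense "a less than b" for rank tests.
#' @param highfreq_cutoff Frequency class defining "high"; defaults to n-1
#'   of spectrum `a`.
#' @param yates Apply Yates continuity correction to the chi-square test
#'   (default FALSE).
#' @return A list of class `sfs_test_result` with `statistic`, `p_value`,
#'   `method`, `tails`.
#' @export
compare_sfs <- function(a, b, method = c("wilcoxon", "ks", "chi2_highfreq"),
                        tails = c("two", "one"), highfreq_cutoff = NULL,
                        yates = FALSE) {
  method <- match.arg(method)
  tails <- match.arg(tails)
  xa <- .sfs_to_obs(a)
  xb <- .sfs_to_obs(b)
  .assert(length(xa) > 0 && length(xb) > 0, "empty spectrum")
  alt <- if (tails == "two") "two.sided" else "less"
  res <- switch(method,
    wilcoxon = {
      w <- suppressWarnings(wilcox.test(xa, xb, alternative = alt))
      list(statistic = unname(w$statistic), p_value = w$p.value)
    },
    ks = {
      w <- suppressWarnings(ks.test(xa, xb, alternative = alt))
      list(statistic = unname(w$statistic), p_value = w$p.value)
    },
    chi2_highfreq = {
      cutoff <- if (is.null(highfreq_cutoff)) a$n - 1L else highfreq_cutoff
      tab <- rbind(
        c(sum(xa >= cutoff), sum(xa < cutoff)),
        c(sum(xb >= cutoff), sum(xb < cutoff))
      )
      w <- suppressWarnings(chisq.test(tab, correct = yates))
      list(statistic = unname(w$statistic), p_value = w$p.value)
    }
  )
  structure(c(res, list(method = method, tails = tails)),
            class = "sfs_test_result")
}

#' @export
print.sfs_test_result <- function(x, ...) {
  cat(sprintf("%s (%s-tailed): statistic = %.6g, p = %.4g\n",
              x$method, x$tails, x$statistic, x$p_value))
  invisible(x)
}
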