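#' Simulate a neutral sample site frequency spectrum
#'
#' Under the standard neutral model the expected number of variants at
#' derived sample frequency i in n sequences over L sites is theta*L/i.
#' Class counts are drawn independently Poisson with those means, which
#' matches the marginal SFS law (linkage is not modelled).
#'
#' @param theta_site Per-site population mutation rate (>= 0).
#' @param n Sample size (integer >= 2).
#' @param L Number of sites (>= 1).
#' @param seed Optional integer seed; global RNG state is left untouched.
#' @return A [sample_sfs()] of kind `"snp"`.
#' @examples
#' gen_neutral_sfs(0.01, n = 10, L = 1e4, seed = 1)
#' @export
gen_neutral_sfs <- function(theta_site, n, L, seed = NULL) {
  .assert(.is_count(n) && n >= 2, "n must be an integer >= 2")
  .assert(L >= 1, "L must be >= 1")
  .assert(is.numeric(theta_site) && theta_site >= 0,
          "theta_site must be non-negative")
  counts <- .with_seed(seed, rpois(n - 1L, theta_site * L / seq_len(n - 1L)))
  sample_sfs(counts, n = n, kind = "snp")
}

#' Simulate a table of segregating duplication calls
#'
#' Draws `n_dups` duplication intervals with lengths from the configured
#' length law, start positions uniform within the chromosome (chromosomes
#' sampled proportionally to length), and per-strain presence vectors whose
#' sample frequencies follow `freq_weights` over classes 1..n_strains
#' (default neutral, proportional to 1/i). Lengths exceeding every
#' chromosome are skipped with a warning.
#'
#' @param config A [synth_config()].
#' @param n_dups Number of calls to draw.
#' @param freq_weights Optional positive weights over frequency classes
#'   1..n_strains-? (length `n_strains`); default 1/i. The last class
#'   (present in every strain) is permitted.
#' @param seed Optional seed (defaults to `config$seed`).
#' @return Data.frame with columns `id`, `chrom`, `start`, `end`, `freq`,
#'   `in_reference` and list-column `strains`.
#' @export
gen_dup_calls <- function(config, n_dups, freq_weights = NULL, seed = config$seed) {
  .assert(inherits(config, "synth_config"), "config must be a synth_config")
  .assert(.is_count(n_dups), "n_dups must be a non-negative integer")
  n <- config$n_strains
  strains <- sprintf("s%02d", seq_len(n))
  if (is.null(freq_weights)) freq_weights <- 1 / seq_len(n)
  .assert(length(freq_weights) == n && all(freq_weights >= 0),
          "freq_weights must be non-negative, one per class 1..n_strains")
  empty <- data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      freq = integer(0), in_reference = logical(0))
  empty$strains <- list()
  if (n_dups == 0) return(empty)
  .with_seed(seed, {
    len <- draw_lengths(config$dup_length_law, n_dups)
    fits <- len <= max(config$chrom_lengths)
    if (any(!fits)) {
      warning(sprintf("%d duplication(s) longer than every chromosome skipped",
                      sum(!fits)))
      len <- len[fits]
    }
    m <- length(len)
    if (m == 0) {
      empty
    } else {
      cl <- config$chrom_lengths
      chrom <- character(m)
      start <- integer(m)
      for (j in seq_len(m)) {
        ok <- names(cl)[cl >= len[j]]
        w <- cl[ok] / sum(cl[ok])
        chrom[j] <- if (length(ok) == 1) ok else sample(ok, 1, prob = w)
        start[j] <- as.integer(floor(runif(1, 0, cl[chrom[j]] - len[j] + 1)))
      }
      freq <- sample.int(n, m, replace = TRUE, prob = freq_weights)
      carriers <- lapply(freq, function(f) sort(sample(strains, f)))
      out <- data.frame(id = sprintf("dup%05d", seq_len(m)), chrom = chrom,
                        start = start, end = start + len, freq = freq,
                        in_reference = FALSE)
      out$strains <- carriers
      out
    }
  })
}

#' Simulate per-site heterozygosity observations for one strain
#'
#' Emits a binary het/hom call per base of a chromosome: inside the
#' configured truth tracts a site is called heterozygous with probability
#' `tract_theta` (residual heterozygosity at the scaled mutation rate),
#' outside with probability `error_eps` (genotyping error). The truth tracts
#' are returned so detection can be scored.
#'
#' @param config A [synth_config()] (uses `het_tracts`, `tract_theta`,
#'   `error_eps`).
#' @param strain Strain identifier selecting truth tracts.
#' @param chrom Chromosome name (must be in `config$chrom_lengths`).
#' @param seed Optional seed (defaults to `config$seed`).
#' @return List with `obs` (integer 0 = hom, 1 = het, length = chromosome
#'   length), `positions` (0-based bp of each observation) and `truth`
#'   (the strain's tracts on that chromosome).
#' @export
gen_het_observations <- function(config, strain, chrom = names(config$chrom_lengths)[1],
                                 seed = config$seed) {
  .assert(inherits(config, "synth_config"), "config must be a synth_config")
  .assert(chrom %in% names(config$chrom_lengths), "unknown chromosome")
  L <- as.integer(config$chrom_lengths[[chrom]])
  tr <- config$het_tracts
  tr <- if (is.null(tr)) tr else tr[tr$strain == strain & tr$chrom == chrom, , drop = FALSE]
  p <- rep(config$error_eps, L)
  if (!is.null(tr) && nrow(tr) > 0) {
    for (j in seq_len(nrow(tr))) p[(tr$start[j] + 1L):tr$end[j]] <- config$tract_theta
  }
  obs <- .with_seed(seed, rbinom(L, 1L, p))
  list(obs = obs, positions = seq_len(L) - 1L,
       truth = if (is.null(tr)) data.frame(chrom = character(0), start = integer(0),
                                           end = integer(0), strain = character(0)) else tr)
}

#' Simulate a window of polarized SNPs with ancestral-state error
#'
#' Derived-allele counts per site follow the neutral SFS law (class counts
#' Poisson with mean theta*L/i); each site's recorded ancestral state is
#' flipped independently with probability `mispolarization_k`, turning
#' observed class i into n-i.
#'
#' @param config A [synth_config()].
#' @param window_length Number of sites L (>= 1).
#' @param seed Optional seed (defaults to `config$seed`).
#' @return Data.frame with columns `pos` (0-based), `true_class`,
#'   `obs_class`, `flipped`; attributes `n` and `L`.
#' @export
gen_snp_window <- function(config, window_length, seed = config$seed) {
  .assert(inherits(config, "synth_config"), "config must be a synth_config")
  .assert(window_length >= 1, "window_length must be >= 1")
  k <- config$mispolarization_k
  .assert(k < 0.5, "mispolarization_k = 0.5 is singular")
  n <- config$n_strains
  .with_seed(seed, {
    counts <- rpois(n - 1L, config$theta_site * window_length / seq_len(n - 1L))
    true_class <- rep(seq_len(n - 1L), counts)
    s <- length(true_class)
    flipped <- if (s > 0) rbinom(s, 1L, k) == 1L else logical(0)
    obs_class <- ifelse(flipped, n - true_class, true_class)
    pos <- if (s > 0) sort(sample.int(window_length, min(s, window_length))) - 1L else integer(0)
    # more variants than sites is possible at extreme theta; recycle positions
    if (s > length(pos)) pos <- c(pos, sample.int(window_length, s - length(pos)) - 1L)
    out <- data.frame(pos = pos, true_class = true_class,
                      obs_class = as.integer(obs_class), flipped = flipped)
    attr(out, "n") <- n
    attr(out, "L") <- window_length
    out
  })
}

#' Tabulate a simulated SNP window into a spectrum
#'
#' @param snps Output of [gen_snp_window()].
#' @param which `"obs"` (recorded ancestral states) or `"true"`.
#' @return A [sample_sfs()].
#' @export
snp_window_sfs <- function(snps, which = c("obs", "true")) {
  which <- match.arg(which)
  n <- attr(snps, "n")
  cls <- if (which == "obs") snps$obs_class else snps$true_class
  sample_sfs(tabulate(cls, nbins = n - 1L), n = n, kind = "snp")
}

#' Simulate reference-discovery ascertainment of a duplication spectrum
#'
#' Draws variants from a true population spectrum over classes 1..n-1 and
#' retains each with probability (n-i)/n: the chance that the reference
#' individual, one of the n sampled chromosomes, lacks the variant and so
#' divergent-read discovery can see it. The retained counts are what a
#' reference-anchored caller reports; [correct_ascertainment()] inverts the
#' bias in expectation.
#'
#' @param true_props Numeric vector of true class proportions (length n-1).
#' @param n Panel size including the reference.
#' @param n_variants Number of variants to draw.
#' @param seed Optional seed.
#' @return A [sample_sfs()] of kind `"duplication"` with the observed counts.
#' @export
simulate_reference_discovery <- function(true_props, n, n_variants, seed = NULL) {
  .assert(length(true_props) == n - 1 && all(true_props >= 0),
          "true_props must cover classes 1..n-1")
  p <- true_props / sum(true_props)
  .with_seed(seed, {
    cls <- sample.int(n - 1L, n_variants, replace = TRUE, prob = p)
    detected <- rbinom(n_variants, 1L, (n - cls) / n) == 1L
    sample_sfs(tabulate(cls[detected], nbins = n - 1L), n = n,
               kind = "duplication")
  })
}

#' Simulate a non-overlapping gene annotation
#'
#' Lays genes left to right on one chromosome: gene g (0-based) starts where
#' the previous gene plus its following spacer ends, so with fixed length
#' 1500 and spacing 500 gene g starts at g*2000.
#'
#' @param n_genes Number of genes.
#' @param gene_length_law,spacing_law Length laws (see [synth_config()]);
#'   spacing may also be `list(law = "fixed", value = 0)`.
#' @param seed Optional seed.
#' @param chrom Chromosome name.
#' @param chrom_length Optional chromosome length; an error is raised when
#'   the layout does not fit.
#' @return Data.frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open CDS spans), `strand`.
#' @export
gen_annotation <- function(n_genes, gene_length_law, spacing_law, seed = NULL,
                           chrom = "chr1", chrom_length = NULL) {
  .assert(.is_count(n_genes), "n_genes must be a non-negative integer")
  if (n_genes == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), strand = character(0)))
  .with_seed(seed, {
    len <- draw_lengths(gene_length_law, n_genes)
    spc <- if (identical(spacing_law$value, 0)) rep(0L, n_genes)
           else draw_lengths(spacing_law, n_genes)
    start <- cumsum(c(0L, head(len + spc, -1L)))
    end <- start + len
    if (!is.null(chrom_length))
      .assert(max(end) <= chrom_length,
              "genome too small for the requested genes")
    data.frame(gene_id = sprintf("g%04d", seq_len(n_genes) - 1L),
               chrom = chrom, start = start, end = end, strand = "+")
  })
}
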