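#' Configuration for the synthetic-data generators
#'
#' Bundles the panel design and the statistical parameters the generators
#' assume: the neutral per-site mutation rate feeding the site frequency
#' spectrum, the duplication length law, the ancestral-state mispolarization
#' rate, and the residual-heterozygosity emission rates.
#'
#' @param seed Integer RNG seed used by generators that are not passed one
#'   explicitly.
#' @param n_strains Number of sequenced (non-reference) strains in the panel.
#' @param theta_site Per-site population mutation rate (4\emph{Ne mu},
#'   dimensionless).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param dup_length_law Duplication length distribution, a list with element
#'   `law` (`"loguniform"`, `"uniform"` or `"fixed"`) and its parameters
#'   (`min`/`max` in bp, or `value` for `"fixed"`). Lengths are capped at
#'   25 kb, the call-size ceiling of paired-end duplication detection.
#' @param mispolarization_k Probability that a site's recorded ancestral
#'   state is flipped by an independent mutation in the outgroup; must be
#'   < 0.5 (the correction is singular at 0.5).
#' @param het_tracts Truth tracts of residual heterozygosity: a data.frame
#'   with columns `chrom`, `start`, `end` (0-based half-open bp) and
#'   `strain`, or NULL.
#' @param tract_theta Per-site heterozygote probability inside tracts
#'   (default 0.01, the scaled mutation rate of the detection HMM).
#' @param error_eps Per-site heterozygote probability outside tracts
#'   (default 0.001, the genotyping error rate of the detection HMM).
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, chrom_lengths = c(chr1 = 1e6))
#' @export
synth_config <- function(seed = 1L,
                         n_strains = 20L,
                         theta_site = 0.01,
                         chrom_lengths = c(chr1 = 1e6),
                         dup_length_law = list(law = "loguniform",
                                               min = 100, max = 25000),
                         mispolarization_k = 0.03,
                         het_tracts = NULL,
                         tract_theta = 0.01,
                         error_eps = 0.001) {
  .assert(.is_count(n_strains) && n_strains >= 2, "n_strains must be >= 2")
  .assert(is.numeric(theta_site) && theta_site >= 0, "theta_site must be >= 0")
  .assert(length(chrom_lengths) >= 1 && all(chrom_lengths > 0) &&
            !is.null(names(chrom_lengths)),
          "chrom_lengths must be a named vector of positive lengths")
  .validate_length_law(dup_length_law)
  if (!is.null(dup_length_law$max))
    .assert(dup_length_law$max <= 25000,
            "dup_length_law max must be <= 25000 bp (call-size ceiling)")
  .assert(mispolarization_k >= 0 && mispolarization_k < 0.5,
          "mispolarization_k must lie in [0, 0.5)")
  for (p in c(tract_theta, error_eps))
    .assert(p >= 0 && p <= 1, "probabilities must lie in [0,1]")
  if (!is.null(het_tracts)) {
    .assert(is.data.frame(het_tracts) &&
              all(c("chrom", "start", "end", "strain") %in% names(het_tracts)),
            "het_tracts needs columns chrom, start, end, strain")
    .assert(all(het_tracts$end > het_tracts$start), "tracts must have end > start")
    .assert(all(het_tracts$chrom %in% names(chrom_lengths)),
            "tract on unknown chromosome")
    .assert(all(het_tracts$end <= chrom_lengths[het_tracts$chrom]) &&
              all(het_tracts$start >= 0), "tract outside chromosome")
    by_sc <- split(het_tracts, paste(het_tracts$strain, het_tracts$chrom))
    for (tr in by_sc) {
      tr <- tr[order(tr$start), ]
      .assert(all(tr$start[-1] >= tr$end[-nrow(tr)]),
              "tracts must be non-overlapping per strain")
    }
  }
  structure(list(seed = as.integer(seed), n_strains = as.integer(n_strains),
                 theta_site = theta_site, chrom_lengths = chrom_lengths,
                 dup_length_law = dup_length_law,
                 mispolarization_k = mispolarization_k,
                 het_tracts = het_tracts, tract_theta = tract_theta,
                 error_eps = error_eps),
            class = "synth_config")
}

#' @noRd
.validate_length_law <- function(law) {
  .assert(is.list(law) && !is.null(law$law), "length law must be a list with $law")
  switch(law$law,
    loguniform = ,
    uniform = .assert(!is.null(law$min) && !is.null(law$max) &&
                        law$min > 0 && law$max >= law$min,
                      "length law needs 0 < min <= max"),
    fixed = .assert(!is.null(law$value) && law$value > 0,
                    "fixed law needs positive value"),
    stop("unknown length law: ", law$law, call. = FALSE)
  )
  invisible(law)
}

#' Draw interval lengths from a named length law
#'
#' @param law A length law list (see [synth_config()]).
#' @param n Number of lengths to draw.
#' @return Integer vector of lengths (bp).
#' @export
draw_lengths <- function(law, n) {
  .validate_length_law(law)
  if (n == 0) return(integer(0))
  len <- switch(law$law,
    loguniform = exp(runif(n, log(law$min), log(law$max))),
    uniform = runif(n, law$min, law$max),
    fixed = rep(law$value, n)
  )
  pmax(1L, as.integer(round(len)))
}
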