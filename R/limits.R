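#' Effective population size from neutral diversity
#'
#' Ne = theta_pi / (4 mu) under the neutral expectation theta = 4 Ne mu.
#'
#' @param theta_pi_site Per-site pairwise heterozygosity at putatively
#'   neutral sites (> 0).
#' @param mu_site Per-site per-generation mutation rate (> 0).
#' @return Effective population size (individuals).
#' @export
effective_popsize <- function(theta_pi_site, mu_site) {
  .assert(theta_pi_site > 0, "theta_pi_site must be > 0")
  .assert(mu_site > 0, "mu_site must be > 0")
  theta_pi_site / (4 * mu_site)
}

#' Effective per-gene mutation rate from per-gene diversity
#'
#' mu = theta_pi / (4 Ne): inverts the neutral expectation using the
#' species' effective population size, giving the rate at which a given
#' structural class of duplication arises per gene per generation.
#'
#' @param theta_pi_gene Per-gene heterozygosity for the mutation class (>= 0).
#' @param Ne Effective population size (> 0).
#' @return Per-gene per-generation mutation rate.
#' @export
per_gene_mu <- function(theta_pi_gene, Ne) {
  .assert(theta_pi_gene >= 0, "theta_pi_gene must be >= 0")
  .assert(Ne > 0, "Ne must be > 0")
  theta_pi_gene / (4 * Ne)
}

#' Probability of adaptation from standing genetic variation
#'
#' Closed form of Hermisson & Pennings for an additive locus with
#' previously neutral standing variation:
#' \deqn{P_{sgv} = 1 - e^{-\theta_\pi \ln(1 + 2 N_e s)}}
#' equivalently \eqn{1 - (1 + 2 N_e s)^{-\theta_\pi}}; monotone in every
#' argument.
#'
#' @param theta_pi Population mutation parameter of the mutational target
#'   (per gene for duplications, per site for SNPs).
#' @param Ne Effective population size (> 0).
#' @param s Selection coefficient after the environmental shift
#'   (> -1/(2Ne)).
#' @return Probability in [0, 1].
#' @export
prob_sgv <- function(theta_pi, Ne, s) {
  .assert(theta_pi >= 0, "theta_pi must be >= 0")
  .assert(Ne > 0, "Ne must be > 0")
  .assert(all(s > -1 / (2 * Ne)), "s must exceed -1/(2Ne)")
  1 - exp(-theta_pi * log1p(2 * Ne * s))
}

#' Establishment time of a sweep from new mutations
#'
#' Expected generations until a new beneficial mutation arises and escapes
#' stochastic loss, for a deterministic sweep with beneficial mutation rate
#' equal to the population rate theta_pi: T_e = 1/(theta_pi * s). A lower
#' bound, since not all mutations at the locus are beneficial.
#'
#' @param theta_pi Population mutation parameter (> 0).
#' @param s Selection coefficient (> 0).
#' @param generations_per_year If non-NULL, also report years (default NULL).
#' @return Generations (numeric), or a list with `generations` and `years`
#'   when `generations_per_year` is given.
#' @export
establishment_time <- function(theta_pi, s, generations_per_year = NULL) {
  .assert(all(theta_pi > 0), "theta_pi must be > 0")
  .assert(all(s > 0), "s must be > 0")
  gens <- 1 / (theta_pi * s)
  if (is.null(generations_per_year)) return(gens)
  list(generations = gens, years = gens / generations_per_year)
}

#' Sojourn time of an allele destined for loss
#'
#' Expected persistence, in generations, of a neutral allele that will
#' ultimately be lost: 2 ln(Ne).
#'
#' @param Ne Effective population size (>= 1).
#' @return Generations.
#' @export
sojourn_time <- function(Ne) {
  .assert(Ne >= 1, "Ne must be >= 1")
  2 * log(Ne)
}

#' Nearly neutral selection threshold
#'
#' Selection coefficients below 1/(4Ne) behave effectively neutrally;
#' returns that threshold.
#'
#' @param Ne Effective population size (> 0).
#' @return Selection coefficient threshold.
#' @export
nearly_neutral_threshold <- function(Ne) {
  .assert(Ne > 0, "Ne must be > 0")
  1 / (4 * Ne)
}

#' Probability an allele is shared across species through ancestry
#'
#' The chance an allele fails to coalesce over t generations in a
#' population of size Ne, approximately exp(-t / (2 Ne)); vanishingly small
#' for species separated by millions of years.
#'
#' @param t_generations Time back to the species split, in generations (>= 0).
#' @param Ne Effective population size (> 0).
#' @return Probability.
#' @export
shared_ancestry_prob <- function(t_generations, Ne) {
  .assert(t_generations >= 0, "t_generations must be >= 0")
  .assert(Ne > 0, "Ne must be > 0")
  exp(-t_generations / (2 * Ne))
}

#' Binomial test for convergently duplicated genes across species
#'
#' Is the number of genes duplicated in both species larger than expected
#' if the focal species' duplicated genes were drawn uniformly from the
#' other species' annotated genes? Exact binomial with n = number of genes
#' duplicated in the focal species and success probability p = proportion
#' of the other species' genes that are duplicated.
#'
#' @param k_shared Number of genes duplicated in both species.
#' @param n_dup_focal Genes duplicated in the focal species.
#' @param n_dup_other,n_genes_other Duplicated and total gene counts in the
#'   other species (ignored when `proportion` is given).
#' @param proportion Optional success probability overriding
#'   `n_dup_other / n_genes_other` (e.g. a pre-rounded proportion).
#' @param alternative `"greater"` (upper tail, default) or `"two.sided"`.
#' @return P-value of the exact binomial test.
#' @export
shared_gene_test <- function(k_shared, n_dup_focal, n_dup_other = NULL,
                             n_genes_other = NULL, proportion = NULL,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(.is_count(k_shared) && .is_count(n_dup_focal) &&
            k_shared <= n_dup_focal, "need integer 0 <= k_shared <= n_dup_focal")
  p <- if (!is.null(proportion)) proportion else {
    .assert(!is.null(n_dup_other) && !is.null(n_genes_other),
            "give n_dup_other and n_genes_other, or proportion")
    n_dup_other / n_genes_other
  }
  .assert(p > 0 && p < 1, "success proportion must lie in (0, 1)")
  binom.test(k_shared, n_dup_focal, p = p, alternative = alternative)$p.value
}

#' Mutation-limits report by structural class
#'
#' Assembles, for one species, the quantities that bound adaptation through
#' tandem duplication: effective population size from neutral diversity,
#' per-gene effective mutation rates by structural class (whole-gene
#' duplication, recruited non-coding, chimeric gene), the probability that a
#' sweep starts from standing variation (P_sgv) and the establishment time
#' for a sweep from new mutations (T_e) at each selection coefficient, the
#' sojourn time of doomed alleles, and the nearly neutral threshold. The
#' `snp` class uses the neutral per-site theta-pi; duplication classes use
#' their per-gene theta-pi with the species Ne.
#'
#' @param species Species label.
#' @param theta_pi_neutral Per-site neutral heterozygosity (e.g. short
#'   intron sites 8-30).
#' @param mu_site Per-site per-generation mutation rate.
#' @param theta_pi_class Named numeric vector of per-gene heterozygosities,
#'   e.g. `c(whole_gene = ..., recruit = ..., chimera = ...)`.
#' @param s Selection coefficients to tabulate (default 0.01 and 0.20).
#' @param Ne Optional override of the effective population size (otherwise
#'   computed from unrounded theta/(4 mu)).
#' @param generations_per_year For year conversions (default 12).
#' @return A list of class `limits_report`; `as.data.frame()` yields a
#'   class-by-quantity table.
#' @export
limits_report <- function(species, theta_pi_neutral, mu_site, theta_pi_class,
                          s = c(0.01, 0.20), Ne = NULL,
                          generations_per_year = 12) {
  .assert(!is.null(names(theta_pi_class)) && all(nzchar(names(theta_pi_class))),
          "theta_pi_class must be a named vector")
  if (is.null(Ne)) Ne <- effective_popsize(theta_pi_neutral, mu_site)
  theta <- c(snp = unname(theta_pi_neutral), theta_pi_class)
  mu <- c(snp = unname(mu_site),
          vapply(theta_pi_class, per_gene_mu, numeric(1), Ne = Ne))
  psgv <- sapply(s, function(si) vapply(theta, prob_sgv, numeric(1),
                                        Ne = Ne, s = si))
  te <- sapply(s, function(si) vapply(theta, establishment_time, numeric(1),
                                      s = si))
  colnames(psgv) <- colnames(te) <- paste0("s=", s)
  structure(list(species = species, Ne = Ne,
                 theta_pi_site = theta_pi_neutral, mu_site = mu_site,
                 theta_pi = theta, mu = mu, s = s,
                 P_sgv = psgv, T_e = te,
                 T_e_years = te / generations_per_year,
                 sojourn = sojourn_time(Ne),
                 s_nearly_neutral = nearly_neutral_threshold(Ne),
                 generations_per_year = generations_per_year),
            class = "limits_report")
}

#' @export
as.data.frame.limits_report <- function(x, ...) {
  classes <- names(x$theta_pi)
  out <- data.frame(species = x$species, class = classes,
                    theta_pi = unname(x$theta_pi), mu = unname(x$mu))
  for (j in seq_along(x$s)) {
    out[[sprintf("P_sgv_s%g", x$s[j])]] <- unname(x$P_sgv[, j])
    out[[sprintf("T_e_s%g", x$s[j])]] <- unname(x$T_e[, j])
  }
  out
}

#' @export
print.limits_report <- function(x, ...) {
  cat(sprintf("Mutation limits for %s: Ne = %.4g, sojourn = %.1f gens, nearly-neutral s = %.3g\n",
              x$species, x$Ne, x$sojourn, x$s_nearly_neutral))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
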