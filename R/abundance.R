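#' Generalized harmonic numbers
#'
#' Exact summation for m <= 1e6; beyond that the asymptotic expansion
#' ln(m) + gamma + 1/(2m) - 1/(12m^2) (power = 1) or pi^2/6 - 1/m + 1/(2m^2)
#' (power = 2). The switchover is continuous to better than 1e-9 relative.
#'
#' @param m Upper summation bound (>= 1).
#' @param power 1 for sum 1/i, 2 for sum 1/i^2.
#' @return Numeric scalar.
#' @export
harmonic_number <- function(m, power = 1) {
  .assert(m >= 1, "m must be >= 1")
  .assert(power %in% c(1, 2), "power must be 1 or 2")
  euler_gamma <- 0.57721566490153286
  if (m <= 1e6) {
    i <- seq_len(floor(m))
    if (power == 1) sum(1 / i) else sum(1 / i^2)
  } else if (power == 1) {
    log(m) + euler_gamma + 1 / (2 * m) - 1 / (12 * m^2)
  } else {
    pi^2 / 6 - 1 / m + 1 / (2 * m^2)
  }
}

#' Correct a segregating-site count for false positives
#'
#' @param S_raw Raw number of calls (>= 0).
#' @param fpr False positive rate of the caller in [0, 1); the default
#'   0.039 is the validated rate of divergent-read duplication calling.
#' @return `S_raw * (1 - fpr)`.
#' @export
correct_false_positives <- function(S_raw, fpr = 0.039) {
  .assert(is.numeric(S_raw) && all(S_raw >= 0), "S_raw must be non-negative")
  .assert(fpr >= 0 && fpr < 1, "fpr must lie in [0, 1)")
  S_raw * (1 - fpr)
}

#' @noRd
.abundance_estimate <- function(point, variance, method, inputs) {
  structure(list(point = point, variance = variance, method = method,
                 inputs_echo = inputs),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("abundance (%s): point = %.6g, variance = %.6g (sd = %.4g)\n",
              x$method, x$point, x$variance,
              if (is.na(x$variance)) NA else sqrt(x$variance)))
  invisible(x)
}

#' Extrapolate sample segregating sites to the whole population
#'
#' Under the standard coalescent the expected number of segregating sites
#' scales with the harmonic number of the sample size, so the population
#' total (a "sample" of 2Ne chromosomes) is
#' \deqn{E[S_{pop}] = S_{sample}\, a_{pop} / a_{sample}}
#' with \eqn{a_{sample} = \sum_{i=1}^{n-1} 1/i} and \eqn{a_{pop} =
#' \sum_{i=1}^{2Ne} 1/i \approx \ln(2Ne) + 0.57722}. The variance is
#' \eqn{\theta a_{pop} + \theta^2 \sum 1/i^2} with
#' \eqn{\theta = S_{sample}/a_{sample}}.
#'
#' @param S_sample Segregating sites observed in the sample (after any
#'   false-positive correction).
#' @param n Sample size (number of strains, >= 2).
#' @param Ne Effective population size (>= 1).
#' @return An `abundance_estimate` (`point`, `variance`, `inputs_echo`).
#' @export
extrapolate_segregating <- function(S_sample, n, Ne) {
  .assert(S_sample >= 0, "S_sample must be non-negative")
  .assert(.is_count(n) && n >= 2, "n must be an integer >= 2")
  .assert(Ne >= 1, "Ne must be >= 1")
  if (Ne < n) warning("Ne < n: extrapolating to a population smaller than the sample")
  a_sample <- harmonic_number(n - 1, 1)
  a_pop <- harmonic_number(2 * Ne, 1)
  theta <- S_sample / a_sample
  point <- S_sample * a_pop / a_sample
  variance <- theta * a_pop + theta^2 * harmonic_number(2 * Ne, 2)
  .abundance_estimate(point, variance, "coalescent",
                      list(S_sample = S_sample, n = n, Ne = Ne, theta = theta))
}

#' Chao1 richness estimator for segregating duplications
#'
#' Rarefaction-based lower bound on the number of segregating variants in
#' the population, free of neutral-model assumptions:
#' \deqn{S_{total} = S_{obs} + S_1^2 / (2 S_2)}
#' where S1 and S2 are singleton and doubleton counts. When S2 = 0 the
#' bias-corrected form `S_obs + S1(S1-1)/(2(S2+1))` is used (variance
#' reported NA). The variance for S2 > 0 is the standard
#' \eqn{S_2 (r^2/2 + r^3 + r^4/4)}, r = S1/S2.
#'
#' @param S_obs Observed number of variants.
#' @param S1,S2 Counts of variants seen in exactly one / exactly two strains.
#' @return An `abundance_estimate`.
#' @export
chao1 <- function(S_obs, S1, S2) {
  .assert(S_obs >= 0 && S1 >= 0 && S2 >= 0, "counts must be non-negative")
  if (S2 > 0) {
    point <- S_obs + S1^2 / (2 * S2)
    r <- S1 / S2
    variance <- S2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    point <- S_obs + S1 * (S1 - 1) / 2
    variance <- NA_real_
  }
  .abundance_estimate(point, variance, "chao1",
                      list(S_obs = S_obs, S1 = S1, S2 = S2))
}
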