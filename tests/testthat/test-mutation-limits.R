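test_that("effective population size and per-gene rates invert 4 Ne mu", {
  expect_equal(effective_popsize(0.0138, 5.8e-9), 5.93e5, tolerance = 0.01)
  expect_equal(effective_popsize(0.0280, 5.8e-9), 1.21e6, tolerance = 0.01)
  expect_equal(effective_popsize(4 * 1e-9, 1e-9), 1)

  expect_equal(per_gene_mu(0.00277, 5.93e5), 1.17e-9, tolerance = 0.01)
  expect_equal(per_gene_mu(0.00291, 1.207e6), 6.03e-10, tolerance = 0.01)
  expect_equal(per_gene_mu(0, 1e6), 0)

  # round-trip self-consistency: mu * 4 * Ne returns theta exactly
  ne <- effective_popsize(0.0138, 5.8e-9)
  expect_equal(per_gene_mu(0.00277, ne) * 4 * ne, 0.00277)
  expect_error(effective_popsize(0.01, 0), "> 0")
})

test_that("probability of adaptation from standing variation matches the closed form", {
  expect_equal(prob_sgv(0, 1e6, 0.01), 0)
  expect_equal(prob_sgv(0.0138, 5.93e5, 0.01), 0.121, tolerance = 0.005)
  expect_equal(prob_sgv(0.0280, 1.21e6, 0.01), 0.246, tolerance = 0.005)
  expect_equal(prob_sgv(0.0138, 5.93e5, 0.20), 0.157, tolerance = 0.005)
  # the closed form itself, pinned at a high-diversity strong-selection corner
  expect_equal(prob_sgv(0.0280, 1.21e6, 0.20),
               1 - exp(-0.0280 * log(1 + 2 * 1.21e6 * 0.20)), tolerance = 1e-12)

  # algebraic alternative form 1 - (1 + 2 Ne s)^(-theta)
  set.seed(5)
  for (r in 1:50) {
    th <- runif(1, 0, 0.05); ne <- 10^runif(1, 3, 7); s <- runif(1, 0, 0.3)
    expect_equal(prob_sgv(th, ne, s), 1 - (1 + 2 * ne * s)^(-th),
                 tolerance = 1e-12)
  }

  # monotone in each argument
  expect_gt(prob_sgv(0.02, 1e6, 0.01), prob_sgv(0.01, 1e6, 0.01))
  expect_gt(prob_sgv(0.01, 1e7, 0.01), prob_sgv(0.01, 1e6, 0.01))
  expect_gt(prob_sgv(0.01, 1e6, 0.1), prob_sgv(0.01, 1e6, 0.01))
  expect_error(prob_sgv(0.01, 1e6, -1), "-1/\\(2Ne\\)")
})

test_that("establishment, sojourn and nearly-neutral quantities follow their reciprocals", {
  expect_equal(establishment_time(0.00277, 0.01), 36101.08, tolerance = 1e-6)
  expect_equal(establishment_time(0.00041, 0.01), 243902.4, tolerance = 1e-6)
  expect_equal(establishment_time(0.01, 0.1), 1000)
  yr <- establishment_time(0.00277, 0.01, generations_per_year = 12)
  expect_equal(yr$years, 36101.08 / 12, tolerance = 1e-6)

  expect_equal(sojourn_time(1), 0)
  expect_equal(sojourn_time(exp(1)), 2)
  expect_equal(sojourn_time(1e6), 2 * log(1e6))

  expect_equal(nearly_neutral_threshold(0.25), 1)
  expect_equal(nearly_neutral_threshold(1.21e6), 1 / (4 * 1.21e6))
  expect_gt(nearly_neutral_threshold(1e4), nearly_neutral_threshold(1e6))
})

test_that("shared-ancestry probability decays exponentially in generations", {
  expect_equal(shared_ancestry_prob(0, 1e6), 1)
  expect_equal(shared_ancestry_prob(2 * 1.3e6 * log(2), 1.3e6), 0.5)
  p <- shared_ancestry_prob(12e6 * 12, 1.2e6)
  expect_equal(p, exp(-60))
  expect_equal(signif(p, 1), 9e-27)
})

test_that("shared-gene binomial test sums the exact upper tail", {
  expect_equal(shared_gene_test(0, 10, proportion = 0.3), 1)
  expect_equal(shared_gene_test(2, 2, proportion = 0.5), 0.25)

  # exact tail summation oracle
  p <- 845 / 16082
  expect_equal(shared_gene_test(56, 478, 845, 16082),
               sum(dbinom(56:478, 478, p)), tolerance = 1e-12)
  expect_error(shared_gene_test(5, 3, proportion = 0.2), "k_shared")
  expect_error(shared_gene_test(1, 3, proportion = 0), "\\(0, 1\\)")
})

test_that("the limits report assembles per-class rates and waiting times", {
  rep_y <- limits_report("yakuba", 0.0138, 5.8e-9,
                         c(whole_gene = 0.00277, recruit = 0.00082,
                           chimera = 0.00088))
  df <- as.data.frame(rep_y)
  expect_equal(df$class, c("snp", "whole_gene", "recruit", "chimera"))
  expect_equal(df$mu[1], 5.8e-9)
  expect_equal(df$theta_pi[2], 0.00277)
  expect_equal(df$T_e_s0.01[2], 1 / (0.00277 * 0.01))
  expect_equal(df$P_sgv_s0.01[1], prob_sgv(0.0138, rep_y$Ne, 0.01))
  # printed-Ne override reproduces cells computed with the rounded value
  rep_o <- limits_report("yakuba", 0.0138, 5.8e-9,
                         c(whole_gene = 0.00277), Ne = 5.93e5)
  expect_equal(as.data.frame(rep_o)$mu[2], 0.00277 / (4 * 5.93e5))
  expect_equal(rep_y$sojourn, 2 * log(rep_y$Ne))
})
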