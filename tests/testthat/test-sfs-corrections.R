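make_call <- function(id, chrom, start, end, strains, in_ref = FALSE) {
  out <- data.frame(id = id, chrom = chrom, start = start, end = end,
                    in_reference = in_ref)
  out$strains <- list(strains)
  out
}

test_that("build_sfs bins calls and applies the het-mask and reference filters", {
  strains <- sprintf("s%02d", 1:20)
  calls <- rbind(make_call("d1", "chr1", 100, 600, strains[1]),
                 make_call("d2", "chr1", 5000, 5400, strains[2]),
                 make_call("d3", "chr1", 9000, 9900, strains[3:4]))
  sfs <- build_sfs(calls, panel_n = 20, strains = strains)
  expect_equal(sfs$counts[1:2], c(2, 1))
  expect_equal(sum(sfs$counts), 3)

  # het segments in 6 of 20 strains leave 14 < 15 -> call excluded
  mask <- data.frame(chrom = "chr1", start = 0, end = 1000,
                     strain = strains[5:10])
  sfs2 <- build_sfs(calls, panel_n = 20, strains = strains, het_mask = mask,
                    min_strains = 15)
  expect_equal(sum(sfs2$counts), 2)

  # reference-present calls are excluded regardless of frequency
  calls$in_reference[3] <- TRUE
  sfs3 <- build_sfs(calls, panel_n = 20, strains = strains)
  expect_equal(sum(sfs3$counts), 2)

  expect_error(build_sfs(calls, panel_n = 10, strains = strains,
                         min_strains = 15), "min_strains")
})

test_that("ascertainment correction reweights by detectability", {
  one <- sample_sfs(c(1, rep(0, 19)), n = 21, kind = "duplication")
  expect_equal(correct_ascertainment(one)$proportions[1], 1)

  # hand evaluation: weights 21/20 on class 1 and 21/1 on class 20
  y <- c(0.5, rep(0, 18), 0.5)
  x <- correct_ascertainment(sample_sfs(y, 21, kind = "duplication"))$proportions
  expect_equal(x[1], 0.525 / 11.025, tolerance = 1e-12)
  expect_equal(x[20], 10.5 / 11.025, tolerance = 1e-12)

  # correction shifts mass toward high-frequency classes (stochastic dominance)
  set.seed(41)
  for (r in 1:20) {
    n <- sample(5:25, 1)
    y <- rpois(n - 1, 50 / seq_len(n - 1)) + 1
    s <- sample_sfs(y, n, kind = "duplication")
    x <- correct_ascertainment(s)$proportions
    cdf_in <- cumsum(y / sum(y))
    cdf_out <- cumsum(x)
    expect_true(all(cdf_out <= cdf_in + 1e-12))
  }

  expect_error(correct_ascertainment(sample_sfs(rep(0, 20), 21, kind = "duplication")),
               "all-zero")
  expect_error(correct_ascertainment(sample_sfs(c(5, 4, 3), 4, kind = "snp")),
               "duplication")
})

test_that("mispolarization rate follows the transition/transversion mixture", {
  expect_equal(mispolarization_rate(0.05, 0.05), 0)
  expect_equal(mispolarization_rate(0.08 + 0.01, 0.01, kappa = 2), 0.03)
  expect_equal(mispolarization_rate(0.09, 0, kappa = 1),
               (1 / 9 + 2 / 9) * 0.09)
  expect_error(mispolarization_rate(0.01, 0.02), "D_net")
  expect_error(mispolarization_rate(2, 0), "0.5")
})

test_that("polarization correction inverts class mixing exactly", {
  s <- sample_sfs(c(90, 30, 10, 30, 10), 6)
  expect_equal(correct_polarization(s, 0)$counts, s$counts)

  sym <- sample_sfs(c(4, 7, 9, 7, 4), 6)
  expect_equal(correct_polarization(sym, 0.3)$counts, sym$counts)

  # hand evaluation: S1obs = 90, S(n-1)obs = 10, k = 0.1
  hand <- sample_sfs(c(90, 10), 3)
  out <- correct_polarization(hand, 0.1)
  expect_equal(out$counts, c(100, 0))
  expect_equal(sum(out$counts), sum(hand$counts))

  # mixing then correcting is the exact algebraic inverse on random spectra
  set.seed(7)
  for (r in 1:100) {
    n <- sample(3:30, 1)
    x <- sample_sfs(runif(n - 1, 0, 100), n)
    k <- runif(1, 0, 0.49)
    back <- correct_polarization(mix_polarization(x, k), k)
    expect_equal(back$counts, x$counts, tolerance = 1e-10)
  }

  expect_warning(correct_polarization(sample_sfs(c(0, 100), 3), 0.2), "clipped")
  expect_error(mix_polarization(s, 0.5), "0.5")
})

test_that("projection matches the hypergeometric closed form and conserves frequency", {
  s <- sample_sfs(c(3, 5, 2), 4)
  expect_equal(project_sfs(s, 4)$counts, s$counts)

  six <- sample_sfs(c(0, 6, 0), 4)
  p <- project_sfs(six, 2)
  expect_equal(p$counts, 4)  # 6 * C(2,1)C(2,1)/C(4,2); 2/6 lost to monomorphic
  expect_equal(p$counts, project_mass_oracle(six$counts, 4, 2, 1))

  # projecting twice to the same m is idempotent on expectations
  s2 <- sample_sfs(rpois(19, 100 / 1:19), 20)
  p1 <- project_sfs(s2, 12)
  expect_equal(project_sfs(p1, 12)$counts, p1$counts, tolerance = 1e-12)

  # expected per-variant derived frequency i/n is conserved (monomorphic
  # classes included in the expectation)
  n <- 15; m <- 8
  s3 <- sample_sfs(rpois(n - 1, 200 / seq_len(n - 1)), n)
  mean_in <- sum(s3$counts * seq_len(n - 1) / n) / sum(s3$counts)
  mass_j <- vapply(0:m, function(j)
    sum(s3$counts * dhyper(j, seq_len(n - 1), n - seq_len(n - 1), m)), numeric(1))
  mean_out <- sum(mass_j * (0:m) / m) / sum(mass_j)
  expect_equal(mean_out, mean_in, tolerance = 1e-12)

  expect_error(project_sfs(s, 6), "m <= n")
})

test_that("spectrum contrasts use rank, distribution and high-frequency tests", {
  a <- sample_sfs(c(10, 10, 10), 4)
  self <- compare_sfs(a, a, method = "wilcoxon")
  expect_gt(self$p_value, 0.99)

  lo <- sample_sfs(c(50, rep(0, 18)), 20)
  hi <- sample_sfs(c(rep(0, 18), 50), 20)
  expect_lt(compare_sfs(lo, hi, method = "wilcoxon")$p_value, 1e-15)

  # chi-square on a 2x2 high-frequency table, against the textbook formula
  n <- 18
  a2 <- sample_sfs(c(90, rep(0, 15), 10), n)   # 10 of 100 high (class 17)
  b2 <- sample_sfs(c(60, rep(0, 15), 40), n)   # 40 of 100 high
  res <- compare_sfs(a2, b2, method = "chi2_highfreq", highfreq_cutoff = 17)
  tab <- rbind(c(10, 90), c(40, 60))
  expect_equal(unname(res$statistic), chisq_stat_oracle(tab), tolerance = 1e-10)
  expect_equal(unname(res$statistic), 24, tolerance = 1e-10)
  yates <- compare_sfs(a2, b2, method = "chi2_highfreq", highfreq_cutoff = 17,
                       yates = TRUE)
  expect_equal(unname(yates$statistic), 225 * (14.5 / 15)^2 * (2 / 25 + 2 / 75),
               tolerance = 1e-10)

  ks <- compare_sfs(lo, hi, method = "ks")
  expect_lt(ks$p_value, 1e-10)

  expect_error(compare_sfs(sample_sfs(c(0, 0, 0), 4), a), "empty")
})
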