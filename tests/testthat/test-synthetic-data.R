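test_that("neutral SFS generator matches the theta/i expectation", {
  expect_equal(gen_neutral_sfs(0, n = 12, L = 1e4, seed = 1)$counts, rep(0, 11))

  two <- gen_neutral_sfs(1, n = 2, L = 10, seed = 1)
  expect_length(two$counts, 1)

  # Monte-Carlo mean per class within 3 SE of theta*L/i
  n <- 10; thetaL <- 100; reps <- 1000
  acc <- matrix(0, reps, n - 1)
  for (r in seq_len(reps)) {
    acc[r, ] <- gen_neutral_sfs(0.01, n = n, L = 1e4, seed = 1000 + r)$counts
  }
  expected <- thetaL / seq_len(n - 1)
  se <- sqrt(expected / reps)
  expect_true(all(abs(colMeans(acc) - expected) <= 3 * se))

  # total segregating sites have mean theta*L*a_n
  a_n <- sum(1 / seq_len(n - 1))
  tot <- rowSums(acc)
  expect_equal(mean(tot), thetaL * a_n, tolerance = 3 * sd(tot) / sqrt(reps) / (thetaL * a_n))

  # bit-reproducible under a fixed seed
  expect_identical(gen_neutral_sfs(0.01, 10, 1e4, seed = 7)$counts,
                   gen_neutral_sfs(0.01, 10, 1e4, seed = 7)$counts)
  expect_error(gen_neutral_sfs(-0.1, 10, 100), "non-negative")
  expect_error(gen_neutral_sfs(0.01, 2.5, 100), "integer")
})

test_that("duplication call generator respects bounds and the frequency law", {
  cfg <- synth_config(seed = 3, chrom_lengths = c(chrA = 1e6),
                      dup_length_law = list(law = "fixed", value = 1000))
  expect_equal(nrow(gen_dup_calls(cfg, 0)), 0)

  calls <- gen_dup_calls(cfg, 500)
  expect_true(all(calls$end - calls$start == 1000))
  expect_true(all(calls$start >= 0 & calls$end <= 1e6))
  expect_true(all(lengths(calls$strains) == calls$freq))

  # neutral frequency law: singleton fraction ~ 1 / H_19 for n = 20
  big <- gen_dup_calls(cfg, 1e4, seed = 11)
  h19 <- sum(1 / 1:19)
  # weights span classes 1..20 by default; use explicit 1..19 weighting here
  big <- gen_dup_calls(cfg, 1e4, freq_weights = c(1 / 1:19, 0), seed = 11)
  p1 <- (1 / 1) / h19
  se <- sqrt(p1 * (1 - p1) / 1e4)
  expect_equal(mean(big$freq == 1), p1, tolerance = 3 * se / p1)
  expect_equal(p1, 0.2819, tolerance = 1e-3)

  # reproducibility
  expect_identical(gen_dup_calls(cfg, 50, seed = 5),
                   gen_dup_calls(cfg, 50, seed = 5))
})

test_that("het observation generator plants tracts at the configured rates", {
  tract <- data.frame(chrom = "chr1", start = 4e5, end = 4.5e5, strain = "s01")
  cfg <- synth_config(seed = 2, chrom_lengths = c(chr1 = 1e6),
                      het_tracts = tract)

  none <- synth_config(seed = 2, chrom_lengths = c(chr1 = 1e4), error_eps = 0)
  expect_true(all(gen_het_observations(none, "s01")$obs == 0))

  all_het <- synth_config(seed = 2, chrom_lengths = c(chr1 = 1e3),
                          het_tracts = data.frame(chrom = "chr1", start = 0,
                                                  end = 1e3, strain = "s01"),
                          tract_theta = 1, error_eps = 0)
  expect_true(all(gen_het_observations(all_het, "s01")$obs == 1))

  sim <- gen_het_observations(cfg, "s01")
  inside <- sim$obs[(4e5 + 1):(4.5e5)]
  outside <- sim$obs[-((4e5 + 1):(4.5e5))]
  se_in <- sqrt(0.01 * 0.99 / length(inside))
  se_out <- sqrt(0.001 * 0.999 / length(outside))
  expect_lt(abs(mean(inside) - 0.01), 3 * se_in)
  expect_lt(abs(mean(outside) - 0.001), 3 * se_out)

  bad <- data.frame(chrom = "chr1", start = 0, end = 2e6, strain = "s01")
  expect_error(synth_config(chrom_lengths = c(chr1 = 1e6), het_tracts = bad),
               "outside chromosome")
})

test_that("SNP window generator applies mispolarization as a class swap", {
  cfg0 <- synth_config(seed = 4, n_strains = 10, theta_site = 0.01,
                       mispolarization_k = 0)
  w0 <- gen_snp_window(cfg0, 1e4)
  expect_identical(w0$obs_class, w0$true_class)

  expect_error(synth_config(mispolarization_k = 0.5), "0.5")

  cfg <- synth_config(seed = 4, n_strains = 10, theta_site = 0.1,
                      mispolarization_k = 0.1)
  w <- gen_snp_window(cfg, 1e5, seed = 9)
  s_true <- tabulate(w$true_class, nbins = 9)
  s_obs <- tabulate(w$obs_class, nbins = 9)
  expected9 <- 0.9 * s_true[9] + 0.1 * s_true[1]
  se <- sqrt(0.9 * 0.1 * (s_true[9] + s_true[1]))
  expect_lt(abs(s_obs[9] - expected9), 3 * se)
})

test_that("annotation generator lays out genes deterministically and round-trips GFF3", {
  expect_equal(nrow(gen_annotation(0, list(law = "fixed", value = 100),
                                   list(law = "fixed", value = 10))), 0)

  genes <- gen_annotation(5, list(law = "fixed", value = 1500),
                          list(law = "fixed", value = 500))
  expect_equal(genes$start, (0:4) * 2000)
  expect_equal(genes$end - genes$start, rep(1500, 5))

  expect_error(gen_annotation(5, list(law = "fixed", value = 1500),
                              list(law = "fixed", value = 500),
                              chrom_length = 5000),
               "too small")

  path <- withr::local_tempfile(fileext = ".gff3")
  write_genes_gff3(genes, path)
  back <- read_genes_gff3(path)
  expect_equal(back[c("gene_id", "chrom", "start", "end")],
               genes[c("gene_id", "chrom", "start", "end")])
})

test_that("simulated mispolarization is undone by the spectrum correction in expectation", {
  cfg <- synth_config(seed = 6, n_strains = 12, theta_site = 0.05,
                      mispolarization_k = 0.2)
  reps <- 60
  err <- matrix(0, reps, 11)
  for (r in seq_len(reps)) {
    w <- gen_snp_window(cfg, 2e4, seed = 100 + r)
    corr <- correct_polarization(snp_window_sfs(w, "obs"), 0.2)
    err[r, ] <- corr$counts - tabulate(w$true_class, nbins = 11)
  }
  se <- apply(err, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(err)) <= 4 * se + 1e-9))
})
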