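# Simulate polarized SNPs along one chromosome with per-site theta that may
# vary by position (theta_fun maps 0-based position -> theta). Sites are laid
# down per neutral class with Poisson counts per non-overlapping 500 bp tile
# so windowed estimates inherit the local theta.
sim_snps <- function(L, n, theta_fun, tile = 500L) {
  starts <- seq(0L, L - tile, by = tile)
  rows <- lapply(starts, function(s0) {
    th <- theta_fun(s0 + tile / 2)
    cnt <- rpois(n - 1, th * tile / seq_len(n - 1))
    tot <- sum(cnt)
    if (tot == 0) return(NULL)
    data.frame(chrom = "chr1",
               pos = s0 + sample.int(tile, tot, replace = TRUE) - 1L,
               count = rep(seq_len(n - 1), cnt))
  })
  do.call(rbind, rows)
}

test_that("window statistics implement per-site theta-pi, theta-W and Tajima's D", {
  # no SNPs: zero estimates, D missing
  w0 <- window_stats(data.frame(chrom = character(0), pos = integer(0),
                                count = integer(0)),
                     n = 15, chrom_lengths = c(chr1 = 5000))
  expect_equal(w0$theta_pi, 0)
  expect_equal(w0$theta_w, 0)
  expect_true(is.na(w0$tajimas_d))

  # single SNP at i = 5 of n = 15 over 5000 callable sites
  w1 <- window_stats(data.frame(chrom = "chr1", pos = 2500L, count = 5L),
                     n = 15, chrom_lengths = c(chr1 = 5000))
  expect_equal(w1$theta_pi, (2 * 5 * 10 / 210) / 5000, tolerance = 1e-9)

  # Watterson: S = 10, n = 20, 5000 callable -> 10 / (H19 * 5000)
  snps <- data.frame(chrom = "chr1", pos = seq(100L, 1000L, 100L), count = 1L)
  w2 <- window_stats(snps, n = 20, chrom_lengths = c(chr1 = 5000))
  expect_equal(w2$theta_w, 10 / (sum(1 / 1:19) * 5000), tolerance = 1e-9)
  expect_equal(w2$theta_w, 5.637e-4, tolerance = 1e-3)

  # halving callable sites with fixed SNPs doubles per-site estimates exactly
  half <- data.frame(chrom = "chr1", start = 0L, end = 2500L)
  w3 <- window_stats(snps, n = 20, chrom_lengths = c(chr1 = 5000),
                     callable = half, min_callable = 1000)
  expect_equal(w3$theta_pi, 2 * w2$theta_pi)
  expect_equal(w3$theta_w, 2 * w2$theta_w)

  # windows below the callable threshold are flagged invalid, not errors
  w4 <- window_stats(snps, n = 20, chrom_lengths = c(chr1 = 5000),
                     callable = data.frame(chrom = "chr1", start = 0L, end = 100L))
  expect_false(w4$valid)
  expect_error(window_stats(snps, n = 1, chrom_lengths = c(chr1 = 5000)), ">= 2")
})

test_that("z-scaling centers valid windows per chromosome", {
  w <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(5000, 10000),
                  callable = 5000, S = 1, theta_pi = c(1, 3), theta_w = 1,
                  tajimas_d = 0, valid = TRUE)
  z <- zscale(w)
  expect_equal(z$z_pi, c(-1, 1) / sqrt(2), tolerance = 1e-12)

  w2 <- w
  w2$theta_pi <- w$theta_pi + 10  # location shift leaves z unchanged
  expect_equal(zscale(w2)$z_pi, z$z_pi)

  w3 <- w
  w3$theta_pi <- c(2, 2)
  expect_error(zscale(w3), "variance")
})

test_that("feature-centered diversity picks focal windows and dedupes", {
  set.seed(11)
  snps <- sim_snps(1e5, 20, function(p) 0.01)
  w <- zscale(window_stats(snps, n = 20, chrom_lengths = c(chr1 = 1e5)))
  centers <- (w$start + w$end) / 2

  f <- data.frame(chrom = "chr1", pos = centers[20])
  fd <- feature_diversity(w, f)
  expect_equal(fd$features$focal_z, w$z_pi[20])

  # two features in one window: second dropped
  f2 <- data.frame(chrom = "chr1", pos = c(centers[20], centers[20] + 10))
  fd2 <- feature_diversity(w, f2)
  expect_equal(nrow(fd2$features), 1)

  # interval features anchor at the midpoint
  f3 <- data.frame(chrom = "chr1", start = w$start[30], end = w$end[30])
  fd3 <- feature_diversity(w, f3)
  expect_equal(fd3$features$focal_z, w$z_pi[30])

  expect_error(feature_diversity(w, data.frame(chrom = "chrX", pos = 1)),
               "unknown chromosome")

  # exclusion intervals drop features
  fd4 <- feature_diversity(w, f, exclude = data.frame(chrom = "chr1",
                                                      start = 0, end = 1e5))
  expect_equal(nrow(fd4$features), 0)
})

test_that("the sweep test is a one-tailed rank test with the stated orientation", {
  x <- c(1.2, -0.5, 0.3, 0.9, -1.1)
  same <- sweep_test(x, x)
  expect_equal(same$p_value, 0.5, tolerance = 0.12)

  lo <- seq(-3, -2, length.out = 20)
  hi <- seq(1, 2, length.out = 20)
  expect_lt(sweep_test(lo, hi)$p_value, 1e-7)
  expect_gt(sweep_test(hi, lo)$p_value, 0.5)
  expect_error(sweep_test(numeric(0), hi), "empty")
})

test_that("low-diversity tail selection uses the type-7 quantile", {
  w <- data.frame(chrom = "chr1", start = (0:99) * 5000, end = (1:100) * 5000,
                  callable = 5000, S = 1, theta_pi = 1:100, theta_w = 1,
                  tajimas_d = 0, valid = TRUE)
  w <- zscale(w)
  f <- data.frame(chrom = "chr1", pos = (w$start[1:10] + w$end[1:10]) / 2)
  tail5 <- low_diversity_features(w, f, q = 0.05)
  expect_equal(nrow(tail5), 5)   # type-7 quantile of 1..100 at 0.05 is 5.95
  expect_equal(nrow(low_diversity_features(w, f, q = 1)), 10)
  none <- data.frame(chrom = "chr1", pos = (w$start[90] + w$end[90]) / 2)
  expect_equal(nrow(low_diversity_features(w, none, q = 0.05)), 0)
  expect_error(low_diversity_features(w, f, q = 0), "0, 1")
})

test_that("neutral windows recover theta and slide phase does not bias estimates", {
  set.seed(21)
  snps <- sim_snps(3e5, 20, function(p) 0.01)
  w <- window_stats(snps, n = 20, chrom_lengths = c(chr1 = 3e5),
                    window = 5000, slide = 5000)
  expect_equal(mean(w$theta_pi), 0.01, tolerance = 0.05)
  w_shift <- window_stats(snps, n = 20, chrom_lengths = c(chr1 = 3e5),
                          window = 5000, slide = 500)
  expect_equal(mean(w_shift$theta_pi), mean(w$theta_pi), tolerance = 0.05)
})
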