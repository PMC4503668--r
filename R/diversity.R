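#' Tajima's D from segregating sites and pairwise diversity
#'
#' Standard variance-normalized difference between the pairwise estimator
#' and Watterson's estimator, using the usual a1, a2, b1, b2, e1, e2
#' constants for n sampled sequences. Returns NA when S = 0.
#'
#' @param S Number of segregating sites (vectorized).
#' @param pi_sum Sum over sites of 2i(n-i)/(n(n-1)) (theta-pi, not per site).
#' @param n Number of sampled sequences (>= 2).
#' @return Numeric vector of D values.
#' @export
tajimas_d <- function(S, pi_sum, n) {
  .assert(n >= 2, "n must be >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  out <- (pi_sum - S / a1) / denom
  out[S == 0] <- NA_real_
  out
}

#' Windowed diversity statistics with callable-site correction
#'
#' Computes theta-pi, Watterson's theta and Tajima's D in sliding windows,
#' dividing by the number of callable sites per window (sites passing the
#' coverage/quality mask) rather than the window length. Windows with fewer
#' than `min_callable` callable sites are flagged invalid and excluded from
#' downstream scaling.
#'
#' @param snps Data.frame of polarized SNPs with columns `chrom`, `pos`
#'   (0-based bp) and `count` (derived-allele sample count i, 0 < i < n).
#' @param n Number of sampled sequences.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param callable Optional callable-site mask, data.frame with `chrom`,
#'   `start`, `end` (0-based half-open); NULL means every site callable.
#' @param window Window size in bp (default 5000).
#' @param slide Slide in bp (default 500).
#' @param min_callable Minimum callable sites for a window to be valid
#'   (default 4000).
#' @return Data.frame with one row per window: `chrom`, `start`, `end`,
#'   `callable`, `S`, `theta_pi`, `theta_w` (both per site), `tajimas_d`,
#'   `valid`.
#' @export
window_stats <- function(snps, n, chrom_lengths, callable = NULL,
                         window = 5000L, slide = 500L, min_callable = 4000L) {
  .assert(n >= 2, "n must be >= 2")
  .assert(all(snps$count > 0 & snps$count < n), "derived counts must satisfy 0 < i < n")
  a1 <- sum(1 / seq_len(n - 1L))
  res <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, L - window), by = slide)
    win <- IRanges::IRanges(start = starts + 1L, width = window)
    s <- snps[snps$chrom == ch, , drop = FALSE]
    sites <- IRanges::IRanges(start = s$pos + 1L, width = 1L)
    hit <- IRanges::findOverlaps(sites, win)
    gi <- 2 * s$count * (n - s$count) / (n * (n - 1))
    S <- tabulate(S4Vectors::subjectHits(hit), nbins = length(win))
    pi_sum <- rep(0, length(win))
    if (length(hit) > 0) {
      agg <- rowsum(gi[S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit))
      pi_sum[as.integer(rownames(agg))] <- agg[, 1]
    }
    if (is.null(callable)) {
      call_n <- rep(as.integer(window), length(win))
    } else {
      cm <- callable[callable$chrom == ch, , drop = FALSE]
      cov <- IRanges::coverage(IRanges::reduce(.as_iranges0(cm$start, cm$end)),
                               width = L)
      call_n <- as.integer(IRanges::viewSums(IRanges::Views(cov, win)))
    }
    data.frame(chrom = ch, start = starts, end = starts + window,
               callable = call_n, S = S,
               theta_pi = ifelse(call_n > 0, pi_sum / call_n, NA_real_),
               theta_w = ifelse(call_n > 0, S / a1 / call_n, NA_real_),
               tajimas_d = tajimas_d(S, pi_sum, n),
               valid = call_n >= min_callable)
  })
  do.call(rbind, res)
}

#' Scale window diversity to unit-normal z-values per chromosome
#'
#' Subtracts the chromosome mean and divides by the chromosome standard
#' deviation (sample, n-1 denominator) of theta-pi over valid windows, so
#' windows can be pooled across chromosomes on a common scale.
#'
#' @param windows Output of [window_stats()].
#' @param by_chrom Scale per chromosome (default TRUE) or globally.
#' @return `windows` with a `z_pi` column (NA for invalid windows).
#' @export
zscale <- function(windows, by_chrom = TRUE) {
  grp <- if (by_chrom) windows$chrom else rep("all", nrow(windows))
  windows$z_pi <- NA_real_
  for (g in unique(grp)) {
    idx <- grp == g & windows$valid
    .assert(sum(idx) >= 2, sprintf("fewer than 2 valid windows in %s", g))
    x <- windows$theta_pi[idx]
    s <- sd(x)
    .assert(is.finite(s) && s > 0, sprintf("zero diversity variance in %s", g))
    windows$z_pi[idx] <- (x - mean(x)) / s
  }
  windows
}

#' @noRd
.feature_midpoints <- function(features) {
  if (!is.null(features$pos)) return(features$pos)
  .assert(all(c("start", "end") %in% names(features)),
          "features need pos or start/end columns")
  floor((features$start + features$end) / 2)
}

#' @noRd
.in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (j in seq_len(nrow(intervals))) {
    out <- out | (chrom == intervals$chrom[j] &
                    pos >= intervals$start[j] & pos < intervals$end[j])
  }
  out
}

#' Diversity at and around genomic features
#'
#' For each feature (a SNP position or a duplication interval, anchored at
#' its midpoint) reports the z-scaled diversity of the focal window - the
#' valid window whose center is nearest the feature - and a profile of mean
#' z by signed distance out to `flank` bp. Features falling in exclusion
#' intervals (centromeres, known artifact clusters) are dropped, and when
#' `dedupe` is TRUE only the first feature per focal window is kept so a
#' single unusual window cannot be counted twice.
#'
#' @param windows Output of [zscale()].
#' @param features Data.frame with `chrom` and either `pos` or
#'   `start`/`end`.
#' @param flank Profile half-width in bp (default 50000).
#' @param exclude Optional exclusion intervals (`chrom`, `start`, `end`).
#' @param dedupe Keep at most one feature per focal window (default TRUE).
#' @return List with `features` (input rows retained, plus `mid`,
#'   `focal_z`, `focal_theta_pi`, `focal_window`) and `profile`
#'   (data.frame `offset`, `mean_z`, `n`).
#' @export
feature_diversity <- function(windows, features, flank = 50000L,
                              exclude = NULL, dedupe = TRUE) {
  .assert("z_pi" %in% names(windows), "windows must be z-scaled first")
  .assert(all(features$chrom %in% windows$chrom), "feature on unknown chromosome")
  mid <- .feature_midpoints(features)
  keep <- !.in_intervals(features$chrom, mid, exclude)
  features <- features[keep, , drop = FALSE]
  mid <- mid[keep]
  centers <- (windows$start + windows$end) / 2
  focal <- integer(nrow(features))
  for (j in seq_len(nrow(features))) {
    idx <- which(windows$chrom == features$chrom[j] & windows$valid)
    focal[j] <- if (length(idx) == 0) NA_integer_
                else idx[which.min(abs(centers[idx] - mid[j]))]
  }
  if (dedupe) {
    dup <- duplicated(focal) & !is.na(focal)
    features <- features[!dup, , drop = FALSE]
    mid <- mid[!dup]
    focal <- focal[!dup]
  }
  features$mid <- mid
  features$focal_window <- focal
  features$focal_z <- windows$z_pi[focal]
  features$focal_theta_pi <- windows$theta_pi[focal]
  prof <- NULL
  for (j in seq_len(nrow(features))) {
    idx <- which(windows$chrom == features$chrom[j] & windows$valid &
                   abs(centers - mid[j]) <= flank)
    if (length(idx) == 0) next
    slide <- if (nrow(windows) > 1) min(diff(sort(unique(windows$start)))) else 1
    off <- round((centers[idx] - mid[j]) / slide) * slide
    prof <- rbind(prof, data.frame(offset = off, z = windows$z_pi[idx]))
  }
  profile <- if (is.null(prof)) {
    data.frame(offset = numeric(0), mean_z = numeric(0), n = integer(0))
  } else {
    agg <- aggregate(z ~ offset, data = prof, FUN = mean)
    cnt <- aggregate(z ~ offset, data = prof, FUN = length)
    data.frame(offset = agg$offset, mean_z = agg$z, n = cnt$z)
  }
  list(features = features, profile = profile)
}

#' Test for reduced diversity around duplications
#'
#' One-tailed Wilcoxon rank-sum test of the hypothesis that z-scaled focal
#' diversity around duplications is lower than around matched neutral SNPs,
#' the footprint expected of recent sweeps at or near the duplications.
#'
#' @param dup_focal_values,snp_focal_values Numeric vectors of z-scaled
#'   focal diversity (NAs dropped).
#' @return An `sfs_test_result` list (`statistic`, `p_value`).
#' @export
sweep_test <- function(dup_focal_values, snp_focal_values) {
  d <- dup_focal_values[!is.na(dup_focal_values)]
  s <- snp_focal_values[!is.na(snp_focal_values)]
  .assert(length(d) > 0 && length(s) > 0, "empty input")
  w <- suppressWarnings(wilcox.test(d, s, alternative = "less"))
  structure(list(statistic = unname(w$statistic), p_value = w$p.value,
                 method = "wilcoxon", tails = "one"),
            class = "sfs_test_result")
}

#' Features lying in the low-diversity tail of the genome
#'
#' Returns the features whose focal window theta-pi is at or below the
#' q-quantile (type-7) of valid windows - candidates for linked selection.
#'
#' @inheritParams feature_diversity
#' @param q Tail quantile in (0, 1] (default 0.05).
#' @return The subset of `features` (with focal columns) in the tail.
#' @export
low_diversity_features <- function(windows, features, q = 0.05, exclude = NULL) {
  .assert(is.numeric(q) && q > 0 && q <= 1, "q must lie in (0, 1]")
  fd <- feature_diversity(windows, features, exclude = exclude, dedupe = FALSE)
  thr <- quantile(windows$theta_pi[windows$valid], q, type = 7, names = FALSE)
  fd$features[!is.na(fd$features$focal_theta_pi) &
                fd$features$focal_theta_pi <= thr, , drop = FALSE]
}
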