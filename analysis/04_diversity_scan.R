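#!/usr/bin/env Rscript
# Sliding-window diversity scan (5 kb windows, 500 bp slide, per-site
# correction, >= 4000 callable bp) around duplications vs neutral SNPs:
# z-scale theta-pi per chromosome, compare focal diversity with a
# one-tailed rank test, and list duplications in the 5% low-diversity tail.
source("analysis/00_config.R")

cfg <- panel_config()
out <- results_dir()
syn <- "results/synthetic"

snps <- read_snp_vcf(file.path(syn, "intronic_snps.vcf"))
calls <- read_calls_bed(file.path(syn, "dup_calls.bed"))

snp_df <- data.frame(chrom = "chr2L", pos = snps$pos, count = snps$true_class)
w <- window_stats(snp_df, n = cfg$n_strains,
                  chrom_lengths = c(chr2L = 5e5),
                  window = 5000, slide = 500)
w <- zscale(w)
write.table(w, file.path(out, "diversity_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dups <- calls[calls$chrom == "chr2L" & calls$end <= 5e5, , drop = FALSE]
set.seed(cfg$seed)
ctrl_idx <- sample(nrow(snp_df), min(200, nrow(snp_df)))
ctrl <- snp_df[ctrl_idx, , drop = FALSE]

fd_dup <- feature_diversity(w, dups)
fd_snp <- feature_diversity(w, ctrl)
res <- sweep_test(fd_dup$features$focal_z, fd_snp$features$focal_z)

tail5 <- low_diversity_features(w, dups, q = 0.05)
write.table(tail5[c("chrom", "start", "end", "id", "focal_theta_pi")],
            file.path(out, "low_diversity_duplications.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

cat(sprintf("scan: %d valid windows, mean theta-pi %.4g (generating 0.0138)\n",
            sum(w$valid), mean(w$theta_pi[w$valid])))
cat(sprintf("sweep test (dups lower): W = %.1f, one-tailed p = %.3g on %d dups vs %d SNPs\n",
            res$statistic, res$p_value, nrow(fd_dup$features), nrow(fd_snp$features)))
cat(sprintf("%d duplications in the 5%% low-diversity tail\n", nrow(tail5)))
# On this neutral panel the duplications were not planted in troughs, so the
# sweep test should NOT reject: p is expected to be unremarkable.
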