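#!/usr/bin/env Rscript
# From the synthetic call table and SNP window: build the duplication SFS
# (dropping strains masked by residual heterozygosity, calls present in the
# reference, and calls with < 15 strains remaining), correct it for
# reference-discovery ascertainment bias, project spectra to a common
# sample size, correct the SNP spectrum for mispolarization, and contrast
# duplication vs SNP spectra with rank and distribution tests.
source("analysis/00_config.R")

cfg <- panel_config()
out <- results_dir()
syn <- "results/synthetic"

calls <- read_calls_bed(file.path(syn, "dup_calls.bed"))
segs <- read_segments_bed(file.path(out, "het_segments.bed"))
snps <- read_snp_vcf(file.path(syn, "intronic_snps.vcf"))

strains <- sprintf("s%02d", seq_len(cfg$n_strains))
panel_n <- cfg$n_strains + 1L  # reference genome joins the discovery panel

dup_sfs <- build_sfs(calls, panel_n = panel_n, strains = strains,
                     het_mask = segs, min_strains = 15)
write_sfs_tsv(dup_sfs, file.path(out, "dup_sfs_raw.tsv"))

dup_corr <- correct_ascertainment(dup_sfs)
write_sfs_tsv(dup_corr, file.path(out, "dup_sfs_ascertainment_corrected.tsv"))

dup_proj <- project_sfs(dup_corr, 15)
write_sfs_tsv(dup_proj, file.path(out, "dup_sfs_projected_n15.tsv"))

snp_obs <- sample_sfs(tabulate(snps$obs_class, nbins = cfg$n_strains - 1L),
                      n = cfg$n_strains)
snp_corr <- correct_polarization(snp_obs, cfg$mispolarization_k)
snp_proj <- project_sfs(snp_corr, 15)
write_sfs_tsv(snp_corr, file.path(out, "snp_sfs_polarization_corrected.tsv"))

wil <- compare_sfs(dup_proj, snp_proj, method = "wilcoxon")
ks <- compare_sfs(dup_proj, snp_proj, method = "ks")
chi <- compare_sfs(dup_proj, snp_proj, method = "chi2_highfreq",
                   highfreq_cutoff = 14)
tests <- data.frame(test = c("wilcoxon", "ks", "chi2_highfreq"),
                    statistic = c(wil$statistic, ks$statistic, chi$statistic),
                    p_value = c(wil$p_value, ks$p_value, chi$p_value))
write.table(tests, file.path(out, "sfs_contrast_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("dup SFS: %d calls in spectrum (of %d); singleton share %.3f raw -> %.3f corrected\n",
            round(sum(dup_sfs$counts)), nrow(calls),
            dup_sfs$counts[1] / sum(dup_sfs$counts), dup_corr$proportions[1]))
cat(sprintf("dup vs SNP (projected to n = 15): Wilcoxon W = %.1f, p = %.3g\n",
            wil$statistic, wil$p_value))
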