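#!/usr/bin/env Rscript
# Build the synthetic study panel every later step consumes: 20 inbred
# strains on two 3 Mb chromosome arms, segregating tandem duplications with
# a singleton-enriched frequency law, a polarized intronic SNP window with
# ancestral-state error, residual-heterozygosity truth tracts for two
# strains, and a gene annotation for the classifier.
source("analysis/00_config.R")

cfg <- panel_config()
out <- results_dir("synthetic")

# duplication calls: neutral 1/i law tilted toward singletons, as observed
# for copy-number variants under purifying selection
w <- 1 / seq_len(cfg$n_strains)
w[1] <- w[1] * 2
calls <- gen_dup_calls(cfg, n_dups = 1400, freq_weights = w)
write_calls_bed(calls, file.path(out, "dup_calls.bed"))

snps <- gen_snp_window(cfg, window_length = 5e5)
write_snp_vcf(snps, file.path(out, "intronic_snps.vcf"), chrom = "chr2L")

genes <- gen_annotation(600, list(law = "loguniform", min = 500, max = 4000),
                        list(law = "loguniform", min = 500, max = 3000),
                        seed = cfg$seed, chrom = "chr2L", chrom_length = 3e6)
write_genes_gff3(genes, file.path(out, "genes.gff3"))

# per-base het/hom observations are regenerated from the config in step 02;
# only the truth tracts are materialized for scoring
write_segments_bed(cbind(panel_tracts, n_het_sites = 0L),
                   file.path(out, "truth_tracts.bed"))

cat(sprintf("panel: %d dup calls, %d SNPs, %d genes, %d truth tracts -> %s\n",
            nrow(calls), nrow(snps), nrow(genes), nrow(panel_tracts), out))
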