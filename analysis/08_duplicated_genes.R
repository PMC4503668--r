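#!/usr/bin/env Rscript
# Classify duplications against the gene annotation (whole-gene vs chimeric
# vs intergenic by CDS coverage and breakpoint position), drop mutational
# hotspots (genes hit by 4+ independent calls), and count duplicated genes
# per structural class - the inputs of the per-class mutation-rate estimates.
source("analysis/00_config.R")

out <- results_dir()
calls <- read_calls_bed("results/synthetic/dup_calls.bed")
genes <- read_genes_gff3("results/synthetic/genes.gff3")

cls <- classify_duplications(calls, genes)
mf <- multiplicity_filter(cls)

tab <- table(cls$calls$structural_class)
write.table(cls$calls[c("chrom", "start", "end", "id", "freq",
                        "structural_class", "max_coverage")],
            file.path(out, "classified_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(mf$hotspot_genes, file.path(out, "hotspot_genes.txt"))

cat("structural classes:\n")
print(tab)
cat(sprintf("%d hotspot genes (4+ independent calls); %d calls excluded from rate estimation\n",
            length(mf$hotspot_genes), nrow(mf$excluded)))
cat(sprintf("%d distinct genes carry duplicated coding sequence\n",
            length(unique(cls$coverage$gene_id))))
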