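#!/usr/bin/env Rscript
# How many tandem duplications segregate in the whole population? Coalescent
# extrapolation of the sample count (after the 3.9% false-positive
# correction) and the assumption-free Chao1 rarefaction estimate, for the
# synthetic panel and for the two published panel counts.
source("analysis/00_config.R")

out <- results_dir()
sfs <- read_sfs_tsv(file.path(out, "dup_sfs_raw.tsv"), n = 21,
                    kind = "duplication")

add <- function(label, S_raw, n, Ne, S1 = NULL, S2 = NULL) {
  S <- correct_false_positives(S_raw)
  co <- extrapolate_segregating(S, n, Ne)
  out <- data.frame(panel = label, method = "coalescent", S_sample = S,
                    point = co$point, sd = sqrt(co$variance))
  if (!is.null(S1)) {
    ch <- chao1(S, S1, S2)
    out <- rbind(out, data.frame(panel = label, method = "chao1",
                                 S_sample = S, point = ch$point,
                                 sd = sqrt(ch$variance)))
  }
  out
}

res <- rbind(
  add("synthetic", sum(sfs$counts), 20, 5.93e5,
      S1 = sfs$counts[1], S2 = sfs$counts[2]),
  # published call counts with the D. yakuba / D. simulans neutral Ne
  add("yakuba_panel", 1415, 20, 5.93e5),
  add("simulans_panel", 975, 20, 1.21e6)
)
write.table(res, file.path(out, "population_abundance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(res, digits = 5, row.names = FALSE)
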