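# Shared study-panel configuration for the analysis scripts. Sourced, not
# run. The generator parameters are the study conditions: 20 inbred strains,
# neutral short-intron theta of 0.0138 per site, duplications up to 25 kb,
# mispolarization of 3% ((3/8) * D_net at kappa = 2, D_net = 0.08), and
# residual-heterozygosity emission rates theta = 0.01 / eps = 0.001.
library(duplimits)

panel_tracts <- data.frame(
  chrom = c("chr2L", "chr2L", "chr2R"),
  start = c(4e5, 2.1e6, 1.2e6),
  end = c(4.6e5, 2.16e6, 1.23e6),
  strain = c("s03", "s08", "s03")
)

panel_config <- function(seed = 20260919) {
  synth_config(
    seed = seed,
    n_strains = 20,
    theta_site = 0.0138,
    chrom_lengths = c(chr2L = 3e6, chr2R = 3e6),
    dup_length_law = list(law = "loguniform", min = 100, max = 25000),
    mispolarization_k = 0.03,
    het_tracts = panel_tracts
  )
}

results_dir <- function(sub = NULL) {
  d <- if (is.null(sub)) "results" else file.path("results", sub)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
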