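Package: duplimits
Title: Population Genetics of Segregating Tandem Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of segregating tandem
    duplications in resequenced panels: site-frequency spectra with
    ascertainment-bias and mispolarization corrections and hypergeometric
    projection, sliding-window diversity scans (theta-pi, Watterson's theta,
    Tajima's D) around duplications, coalescent and Chao1 estimators of
    population-wide duplication abundance, the mutation-limits calculus
    (effective population size, per-gene duplication rates, probability of
    adaptation from standing variation, sweep establishment times), a
    two-state Viterbi HMM for residual heterozygosity in inbred lines,
    Monte-Carlo genome-coverage simulations, duplication classification
    against gene models, and a synthetic-data module that generates every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
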