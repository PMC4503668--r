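#' Classify duplications against gene models
#'
#' For every call x overlapped gene, CDS coverage is the covered fraction of
#' the gene's genomic start-to-stop span. A call is `chimeric` when a call
#' boundary falls strictly inside any overlapped gene span (the breakpoint
#' creates a novel gene structure; this rule dominates), `whole_gene` when
#' some overlapped gene is covered to at least `min_cov` and no breakpoint
#' lies inside a gene, and `intergenic` when it overlaps no gene.
#' Classification is invariant to strand and record order.
#'
#' @param calls Data.frame with `id`, `chrom`, `start`, `end` (0-based
#'   half-open, maximum span across strains).
#' @param genes Data.frame of CDS spans with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param min_cov Whole-gene coverage threshold (default 0.9).
#' @return List with `calls` (input plus `structural_class` and
#'   `max_coverage`) and `coverage` (data.frame `id`, `gene_id`,
#'   `coverage`, `breakpoint_inside`).
#' @export
classify_duplications <- function(calls, genes, min_cov = 0.9) {
  .assert(all(calls$end > calls$start), "malformed call intervals")
  .assert(all(calls$end - calls$start <= 25000),
          "calls must span 25 kb or less")
  .assert(all(genes$end > genes$start), "malformed gene intervals")
  cov_tab <- data.frame(id = character(0), gene_id = character(0),
                        coverage = numeric(0), breakpoint_inside = logical(0))
  cls <- rep("intergenic", nrow(calls))
  maxcov <- rep(0, nrow(calls))
  if (nrow(calls) > 0 && nrow(genes) > 0) {
    cg <- .df_to_granges0(calls)
    gg <- .df_to_granges0(genes)
    hits <- GenomicRanges::findOverlaps(cg, gg, ignore.strand = TRUE)
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov_start <- pmax(calls$start[qi], genes$start[si])
      ov_end <- pmin(calls$end[qi], genes$end[si])
      coverage <- (ov_end - ov_start) / (genes$end[si] - genes$start[si])
      bp_in <- (calls$start[qi] > genes$start[si] & calls$start[qi] < genes$end[si]) |
               (calls$end[qi] > genes$start[si] & calls$end[qi] < genes$end[si])
      cov_tab <- data.frame(id = calls$id[qi], gene_id = genes$gene_id[si],
                            coverage = coverage, breakpoint_inside = bp_in)
      for (j in unique(qi)) {
        rows <- qi == j
        maxcov[j] <- max(coverage[rows])
        cls[j] <- if (any(bp_in[rows])) "chimeric"
                  else if (maxcov[j] >= min_cov) "whole_gene"
                  else "intergenic"
      }
    }
  }
  calls$structural_class <- cls
  calls$max_coverage <- maxcov
  list(calls = calls, coverage = cov_tab)
}

#' Exclude genes hit by too many independent duplications
#'
#' Genes captured by more than `max_hits` independent calls are mutational
#' hotspots (or somatic-duplication artifacts) whose rates would distort
#' per-gene mutation estimates; their calls are excluded from rate
#' estimation.
#'
#' @param classified Output of [classify_duplications()].
#' @param max_hits Maximum independent calls per gene before it is flagged
#'   (default 3: four or more hits flag a hotspot).
#' @return List with `retained` (calls data.frame), `excluded`, and
#'   `hotspot_genes` (character).
#' @export
multiplicity_filter <- function(classified, max_hits = 3L) {
  cov <- classified$coverage
  calls <- classified$calls
  hits_per_gene <- table(unique(cov[c("id", "gene_id")])$gene_id)
  hotspots <- names(hits_per_gene)[hits_per_gene > max_hits]
  bad_ids <- unique(cov$id[cov$gene_id %in% hotspots])
  list(retained = calls[!calls$id %in% bad_ids, , drop = FALSE],
       excluded = calls[calls$id %in% bad_ids, , drop = FALSE],
       hotspot_genes = hotspots)
}

#' Genes duplicated in both of two species
#'
#' Intersects duplicated-gene sets through a one-to-one ortholog map and
#' emits the counts the cross-species convergence test consumes
#' ([shared_gene_test()]).
#'
#' @param genes_a,genes_b Character vectors of duplicated gene identifiers
#'   in species A and B.
#' @param ortholog_map Data.frame with columns `a` and `b` mapping species-A
#'   gene ids to species-B gene ids; must be one-to-one on the tested genes.
#' @return List with `pairs` (data.frame `a`, `b`), `k` (number shared),
#'   and `test_inputs` (k and n for the binomial test).
#' @export
shared_duplicated_genes <- function(genes_a, genes_b, ortholog_map) {
  .assert(is.data.frame(ortholog_map) && all(c("a", "b") %in% names(ortholog_map)),
          "ortholog_map needs columns a and b")
  m <- ortholog_map[ortholog_map$a %in% genes_a | ortholog_map$b %in% genes_b, ,
                    drop = FALSE]
  .assert(!anyDuplicated(m$a) && !anyDuplicated(m$b),
          "ortholog map is not one-to-one on the tested genes")
  shared <- m[m$a %in% genes_a & m$b %in% genes_b, , drop = FALSE]
  list(pairs = data.frame(a = shared$a, b = shared$b, row.names = NULL),
       k = nrow(shared),
       test_inputs = list(k_shared = nrow(shared),
                          n_dup_focal = length(unique(genes_a))))
}
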