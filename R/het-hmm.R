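#' Parameters of the residual-heterozygosity HMM
#'
#' Two hidden states - homozygous background and residually heterozygous
#' tract - with near-absorbing transitions (switch probability 1e-10) so
#' single stray calls cannot flip the state. The heterozygous state emits a
#' het call at the scaled mutation rate theta = 0.01 per site; the
#' homozygous state emits a het call at the genotyping error rate
#' epsilon = 0.001.
#'
#' @param prior State prior, default c(0.5, 0.5) over (hom, het).
#' @param switch_prob Per-site probability of switching state (default
#'   1e-10).
#' @param theta P(het call | het state), default 0.01.
#' @param eps P(het call | hom state), default 0.001.
#' @return A list of class `het_hmm_params` with the log-space matrices the
#'   decoder consumes.
#' @export
het_hmm_params <- function(prior = c(0.5, 0.5), switch_prob = 1e-10,
                           theta = 0.01, eps = 0.001) {
  .assert(length(prior) == 2 && all(prior > 0) && abs(sum(prior) - 1) < 1e-9,
          "prior must be a 2-vector summing to 1")
  .assert(switch_prob > 0 && switch_prob < 0.5, "switch_prob must lie in (0, 0.5)")
  .assert(theta > 0 && theta < 1 && eps > 0 && eps < 1,
          "emission probabilities must lie in (0, 1)")
  trans <- matrix(c(1 - switch_prob, switch_prob,
                    switch_prob, 1 - switch_prob), 2, 2, byrow = TRUE)
  # emit[state, obs + 1]: rows (hom, het) x observation (hom call, het call)
  emit <- matrix(c(1 - eps, eps,
                   1 - theta, theta), 2, 2, byrow = TRUE)
  structure(list(prior = prior, trans = trans, emit = emit,
                 switch_prob = switch_prob, theta = theta, eps = eps),
            class = "het_hmm_params")
}

#' Viterbi decoding of residual heterozygosity
#'
#' Computes the most probable hidden-state path for a per-site sequence of
#' het/hom calls under the two-state HMM, in log space (the 1e-10 switch
#' probability underflows linear space over chromosome-length sequences).
#' Deterministic; ties are broken toward the homozygous state.
#'
#' @param observations Integer or logical vector: 1/TRUE = het call,
#'   0/FALSE = hom call. Non-callable sites should be encoded as hom
#'   (uninformative) so distances along the path stay physical, or dropped
#'   beforehand with their positions carried alongside.
#' @param params A [het_hmm_params()].
#' @return Integer vector of states (0 = hom, 1 = het) aligned to the
#'   observations.
#' @export
viterbi_het <- function(observations, params = het_hmm_params()) {
  .assert(length(observations) > 0, "observations must be non-empty")
  if (is.logical(observations)) observations <- as.integer(observations)
  .assert(is.numeric(observations) && all(observations %in% c(0L, 1L)),
          "observations must be 0 (hom) or 1 (het)")
  viterbi2_cpp(as.integer(observations), log(params$prior),
               log(params$trans), log(params$emit))
}

#' Extract heterozygous segments from a decoded path
#'
#' Turns maximal runs of the het state into genomic intervals, clusters
#' runs lying within `merge_gap` of one another into single segments, and
#' retains segments of at least `min_len` bp. With `order = "merge_first"`
#' (default) clustering precedes the length filter, so nearby sub-threshold
#' runs can jointly survive; `"filter_first"` applies the length filter to
#' raw runs before clustering.
#'
#' @param path Integer state vector from [viterbi_het()].
#' @param positions 0-based bp position of each observation (same length as
#'   `path`); defaults to 0..length-1.
#' @param min_len Minimum retained segment length in bp (default 10000).
#' @param merge_gap Cluster runs separated by at most this many bp
#'   (default 100000).
#' @param order `"merge_first"` or `"filter_first"`.
#' @param chrom,strain Labels copied onto the output.
#' @return Data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strain`, `n_het_sites` (decoded het sites within the segment).
#' @export
extract_segments <- function(path, positions = seq_along(path) - 1L,
                             min_len = 10000L, merge_gap = 100000L,
                             order = c("merge_first", "filter_first"),
                             chrom = "chr1", strain = NA_character_) {
  order <- match.arg(order)
  .assert(length(path) == length(positions), "path and positions differ in length")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strain = character(0),
                      n_het_sites = integer(0))
  r <- rle(as.integer(path))
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  het <- which(r$values == 1L)
  if (length(het) == 0) return(empty)
  runs <- data.frame(start = positions[starts_idx[het]],
                     end = positions[ends_idx[het]] + 1L)
  merge_runs <- function(d, gap) {
    d <- d[base::order(d$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(d$start[-1] - d$end[-nrow(d)] > gap)))
    u <- unique(grp)
    data.frame(
      start = vapply(u, function(g) min(d$start[grp == g]), numeric(1)),
      end = vapply(u, function(g) max(d$end[grp == g]), numeric(1))
    )
  }
  segs <- if (order == "merge_first") {
    m <- merge_runs(runs, merge_gap)
    m[m$end - m$start >= min_len, , drop = FALSE]
  } else {
    f <- runs[runs$end - runs$start >= min_len, , drop = FALSE]
    if (nrow(f) == 0) f else merge_runs(f, merge_gap)
  }
  if (nrow(segs) == 0) return(empty)
  het_pos <- positions[path == 1L]
  n_het <- vapply(seq_len(nrow(segs)), function(j)
    sum(het_pos >= segs$start[j] & het_pos < segs$end[j]), integer(1))
  data.frame(chrom = chrom, start = segs$start, end = segs$end,
             strain = strain, n_het_sites = n_het, row.names = NULL)
}

#' Strains to exclude per feature due to residual heterozygosity
#'
#' For each feature, finds the strains whose heterozygous segments - padded
#' by `pad` bp on each side - overlap the feature interval. Consumed by
#' [build_sfs()] to drop unreliable strains from a call's denominator.
#'
#' @param features Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param segments Data.frame of heterozygous segments with `chrom`,
#'   `start`, `end`, `strain` (see [extract_segments()]).
#' @param pad Padding in bp (default 1000).
#' @return List, one character vector of excluded strains per feature row.
#' @export
mask_features <- function(features, segments, pad = 1000L) {
  nf <- nrow(features)
  if (is.null(segments) || nrow(segments) == 0) {
    return(rep(list(character(0)), nf))
  }
  fg <- .df_to_granges0(features)
  sg <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, segments$start + 1L - pad),
                              end = segments$end + pad)
  )
  hits <- GenomicRanges::findOverlaps(fg, sg, ignore.strand = TRUE)
  out <- rep(list(character(0)), nf)
  if (length(hits) > 0) {
    sp <- split(segments$strain[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) out[[as.integer(q)]] <- sort(unique(sp[[q]]))
  }
  out
}
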