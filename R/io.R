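# On-disk formats: BED-like TSV for calls and segments (0-based half-open,
# matching the internal convention), GFF3 for gene models (1-based closed,
# converted on I/O by rtracklayer), 2-column TSV for spectra, and a minimal
# VCF 4.2 for polarized SNP windows (ancestral allele in INFO/AA).

#' Write / read a site frequency spectrum as 2-column TSV
#'
#' @param sfs A [sample_sfs()].
#' @param path File path.
#' @return `read_sfs_tsv` returns a [sample_sfs()].
#' @export
write_sfs_tsv <- function(sfs, path) {
  df <- data.frame(class = seq_len(sfs$n - 1L), count = sfs$counts)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs_tsv
#' @param n Sample size (defaults to max class + 1).
#' @param kind Spectrum kind.
#' @export
read_sfs_tsv <- function(path, n = NULL, kind = "snp") {
  df <- read.delim(path)
  if (is.null(n)) n <- max(df$class) + 1L
  counts <- numeric(n - 1L)
  counts[df$class] <- df$count
  sample_sfs(counts, n = n, kind = kind)
}

#' Write / read duplication calls as BED-like TSV
#'
#' Columns: chrom, start, end, id, freq, strains (comma-separated carriers),
#' in_reference.
#'
#' @param calls Call table (see [gen_dup_calls()]).
#' @param path File path.
#' @export
write_calls_bed <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$start, end = calls$end,
                   id = calls$id, freq = calls$freq,
                   strains = vapply(calls$strains, paste, character(1),
                                    collapse = ","),
                   in_reference = as.integer(calls$in_reference))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  df <- read.delim(path, header = FALSE,
                   col.names = c("chrom", "start", "end", "id", "freq",
                                 "strains", "in_reference"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character",
                                  "integer"))
  out <- data.frame(id = df$id, chrom = df$chrom, start = df$start,
                    end = df$end, freq = df$freq,
                    in_reference = df$in_reference == 1L)
  out$strains <- strsplit(df$strains, ",", fixed = TRUE)
  out
}

#' Write / read heterozygous segments (or any strain-labelled intervals) as BED
#'
#' BED6-style: chrom, start, end, name = strain, score = n_het_sites, strand.
#'
#' @param segments Data.frame with `chrom`, `start`, `end`, `strain`,
#'   optionally `n_het_sites`.
#' @param path File path.
#' @export
write_segments_bed <- function(segments, path) {
  score <- if (!is.null(segments$n_het_sites)) segments$n_het_sites else 0L
  df <- data.frame(segments$chrom, segments$start, segments$end,
                   segments$strain, score, ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path) {
  df <- read.delim(path, header = FALSE)
  data.frame(chrom = as.character(df[[1]]), start = df[[2]], end = df[[3]],
             strain = as.character(df[[4]]), n_het_sites = df[[5]])
}

#' Write / read gene models as GFF3
#'
#' Internal 0-based half-open spans are converted to GFF3 1-based closed
#' coordinates by rtracklayer on export and back on import.
#'
#' @param genes Data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param path File path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = .as_iranges0(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "duplimits"
  S4Vectors::mcols(gr)$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(gene_id = S4Vectors::mcols(gr)$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             row.names = NULL)
}

#' Write a polarized SNP window as a minimal VCF
#'
#' Encodes each site with REF = A (true ancestral) and ALT = T (derived).
#' INFO carries AA (the *recorded* ancestral allele, which differs from REF
#' at mispolarized sites), AC (derived count) and AN (sample size), so the
#' observed frequency class is AC when AA equals REF and AN - AC otherwise.
#'
#' @param snps Output of [gen_snp_window()].
#' @param path File path (plain-text .vcf).
#' @param chrom Chromosome name.
#' @export
write_snp_vcf <- function(snps, path, chrom = "chr1") {
  n <- attr(snps, "n")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Recorded ancestral allele\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Derived allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Sample size\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps) > 0) {
    aa <- ifelse(snps$flipped, "T", "A")
    info <- sprintf("AA=%s;AC=%d;AN=%d", aa, snps$true_class, n)
    writeLines(sprintf("%s\t%d\t.\tA\tT\t.\tPASS\t%s",
                       chrom, snps$pos + 1L, info), con)
  }
  invisible(path)
}

#' Read a polarized SNP window from VCF
#'
#' Parses with vcfR and reconstructs the true and observed frequency
#' classes from the AA/AC/AN INFO keys.
#'
#' @param path VCF path.
#' @return Data.frame as produced by [gen_snp_window()].
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  fix <- if (is.matrix(fix)) as.data.frame(fix, stringsAsFactors = FALSE)
         else as.data.frame(as.list(fix), stringsAsFactors = FALSE)
  info <- fix$INFO
  get_key <- function(key) sub(sprintf(".*%s=([^;]+).*", key), "\\1", info)
  aa <- get_key("AA")
  ac <- as.integer(get_key("AC"))
  an <- as.integer(get_key("AN"))
  flipped <- aa != fix$REF
  out <- data.frame(pos = as.integer(fix$POS) - 1L, true_class = ac,
                    obs_class = ifelse(flipped, an - ac, ac),
                    flipped = flipped)
  attr(out, "n") <- if (length(an) > 0) an[1] else NA_integer_
  out
}
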