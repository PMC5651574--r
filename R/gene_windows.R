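#' Build cis-windows around selected SNPs
#'
#' Each window spans [max(1, pos - half_width), pos + half_width] on the
#' SNP's chromosome (1-based closed interval), i.e. a total width of
#' ~2 x half_width; the default half-width of 250 kb gives a 500 kb
#' cis-window. SNPs without a position are skipped with a warning.
#'
#' @param snps data.frame with locus_id, chromosome, position_bp (the
#'   selected SNPs).
#' @param half_width_bp half-width in bp (default 250000).
#' @return data.frame: locus_id, chromosome, start_bp, end_bp.
#' @export
build_windows <- function(snps, half_width_bp = 250000) {
  stopifnot(half_width_bp >= 0)
  drop <- is.na(snps$position_bp) | is.na(snps$chromosome)
  if (any(drop)) {
    warning(sum(drop), " SNP(s) without position skipped")
    snps <- snps[!drop, , drop = FALSE]
  }
  if (any(snps$position_bp < 1)) stop("positions must be >= 1")
  data.frame(locus_id = snps$locus_id,
             chromosome = as.character(snps$chromosome),
             start_bp = pmax(1, snps$position_bp - half_width_bp),
             end_bp = snps$position_bp + half_width_bp,
             stringsAsFactors = FALSE)
}

# strip a leading "chr"/"Chr" so "1" and "chr1" style labels agree
.norm_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Extract genes overlapping SNP cis-windows
#'
#' A gene overlaps a window iff gene.start <= window.end and gene.end >=
#' window.start (any shared base, 1-based closed intervals); overlap is
#' computed with GenomicRanges. The report lists genes per window plus a
#' global list deduplicated by gene id, ordered by (chromosome, start).
#' Chromosome labels are normalized ("chr1" vs "1") before matching.
#'
#' @param windows output of \code{\link{build_windows}}.
#' @param annotation data.frame of gene records (gene_id, chromosome,
#'   start_bp, end_bp).
#' @return list: \code{per_window} (data.frame locus_id, gene_id, chrom,
#'   gene coords), \code{genes} (deduplicated gene data.frame),
#'   \code{n_genes}.
#' @export
extract_genes <- function(windows, annotation) {
  stopifnot(all(annotation$start_bp <= annotation$end_bp))
  wchr <- .norm_chrom(windows$chromosome)
  gchr <- .norm_chrom(annotation$chromosome)
  if (!any(wchr %in% gchr) && nrow(windows) > 0 && nrow(annotation) > 0)
    stop("no shared chromosome labels between windows and annotation")
  wr <- GenomicRanges::GRanges(wchr,
          IRanges::IRanges(windows$start_bp, windows$end_bp))
  gr <- GenomicRanges::GRanges(gchr,
          IRanges::IRanges(annotation$start_bp, annotation$end_bp))
  hits <- GenomicRanges::findOverlaps(wr, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  per_window <- data.frame(
    locus_id = windows$locus_id[qi],
    gene_id = annotation$gene_id[si],
    chromosome = annotation$chromosome[si],
    gene_start = annotation$start_bp[si],
    gene_end = annotation$end_bp[si],
    stringsAsFactors = FALSE)
  genes <- annotation[sort(unique(si)), , drop = FALSE]
  genes <- genes[order(.norm_chrom(genes$chromosome), genes$start_bp,
                       genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(per_window = per_window, genes = genes, n_genes = nrow(genes))
}
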