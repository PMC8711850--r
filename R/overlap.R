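#' Intersect CNVs with gene models
#'
#' A CNV overlaps a gene iff their intervals share at least
#' `min_overlap_bp` bases on the same scaffold; strand is ignored (CNVs
#' are unstranded dosage events) and half-open abutment is not an overlap.
#' Aggregates are computed over ALL CNVs, so zero-overlap CNVs pull the
#' per-type means towards zero.
#'
#' @param table A [cnv_table()].
#' @param genes data.frame of gene models as returned by [read_gff3()].
#' @param min_overlap_bp Minimum shared bases (default 1).
#' @param genome Optional [genome_index()]; genes on scaffolds absent from
#'   it are skipped with a warning.
#' @return An object of class `overlap_table`: list with `pairs` (one row
#'   per overlapping CNV/gene pair), `per_cnv` (gene count per CNV) and
#'   the aggregate block (`n_cnvs_overlapping`, `fraction_overlapping`,
#'   `n_distinct_genes`, `n_pairs`, `mean_genes_per_cnv_by_type`,
#'   `max_genes_per_cnv_by_type`).
#' @export
overlap_cnv_genes <- function(table, genes, min_overlap_bp = 1, genome = NULL) {
  if (min_overlap_bp < 1) stopf("min_overlap_bp must be >= 1")
  if (!is.null(genome)) {
    check_scaffolds(table, genome)
    unknown <- !(genes$scaffold %in% genome$name)
    if (any(unknown)) {
      warnf("overlap_cnv_genes: %d gene(s) on unknown scaffold(s) skipped",
            sum(unknown))
      genes <- genes[!unknown, , drop = FALSE]
    }
  }
  loci <- table$loci
  pairs <- data.frame(locus_id = character(), svtype = character(),
                      gene_id = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(loci) > 0L && nrow(genes) > 0L) {
    seqlv <- unique(c(loci$scaffold, genes$scaffold))
    gr_cnv <- GenomicRanges::GRanges(
      loci$scaffold, IRanges::IRanges(loci$start + 1, loci$end),
      seqinfo = GenomeInfoDb::Seqinfo(seqlv))
    gr_gene <- GenomicRanges::GRanges(
      genes$scaffold, IRanges::IRanges(genes$start + 1, genes$end),
      seqinfo = GenomeInfoDb::Seqinfo(seqlv))
    hits <- GenomicRanges::findOverlaps(gr_cnv, gr_gene,
                                        minoverlap = min_overlap_bp,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_cnv)[qi], IRanges::ranges(gr_gene)[si]))
    pairs <- data.frame(locus_id = loci$locus_id[qi],
                        svtype = loci$svtype[qi],
                        gene_id = genes$gene_id[si],
                        overlap_bp = ov,
                        stringsAsFactors = FALSE)
  }
  per_cnv <- data.frame(locus_id = loci$locus_id, svtype = loci$svtype,
                        n_genes = as.integer(
                          table(factor(pairs$locus_id,
                                       levels = loci$locus_id))),
                        stringsAsFactors = FALSE)
  out <- list(pairs = pairs, per_cnv = per_cnv)
  out <- c(out, overlap_summary(out, nrow(loci)))
  class(out) <- "overlap_table"
  out
}

#' Aggregate block of a CNV/gene overlap table
#'
#' @param ov List with elements `pairs` and `per_cnv` as produced by
#'   [overlap_cnv_genes()].
#' @param n_total Total number of CNVs (denominator of the overlapping
#'   fraction).
#' @return List with the aggregate fields.
#' @export
overlap_summary <- function(ov, n_total) {
  per_cnv <- ov$per_cnv
  n_overlapping <- sum(per_cnv$n_genes > 0L)
  by_type <- function(fun, default) {
    vapply(c(DEL = "DEL", DUP = "DUP"), function(tp) {
      v <- per_cnv$n_genes[per_cnv$svtype == tp]
      if (length(v) == 0L) default else fun(v)
    }, numeric(1L))
  }
  list(
    n_cnvs_overlapping = n_overlapping,
    fraction_overlapping = if (n_total > 0L) n_overlapping / n_total else 0,
    n_distinct_genes = length(unique(ov$pairs$gene_id)),
    n_pairs = nrow(ov$pairs),
    mean_genes_per_cnv_by_type = by_type(mean, 0),
    max_genes_per_cnv_by_type = by_type(max, 0))
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf(paste0(
    "CNV x gene overlap: %d of %d CNVs (%.1f%%) overlap %d distinct gene(s)",
    " [%d pairs]\n"),
    x$n_cnvs_overlapping, nrow(x$per_cnv), 100 * x$fraction_overlapping,
    x$n_distinct_genes, x$n_pairs))
  invisible(x)
}
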