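#' Read a structural-variant VCF into a CNV table
#'
#' Consumes the LUMPY/svtyper dialect: `SVTYPE` and `END` in INFO, a `GT`
#' genotype per sample, symbolic `<DEL>`/`<DUP>` ALT alleles. Only DEL and
#' DUP rows are kept; other SV types (INV, BND, INS, ...) are counted and
#' skipped with a message. The 1-based inclusive VCF `POS`/`END` pair is
#' converted to the internal 0-based half-open `[POS - 1, END)` interval.
#' Multi-allelic rows are split into one record per ALT allele with
#' `_1`, `_2`, ... suffixed locus ids; the per-sample dosage of record
#' `j` is the number of `j` alleles in the GT call.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param genome A [genome_index()]; every record scaffold must be listed.
#' @param groups Optional named character vector of sample -> group labels
#'   attached to the returned table.
#' @return A [cnv_table()].
#' @export
read_sv_vcf <- function(path, genome, groups = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  if (!all(c("SVTYPE", "END") %in% names(info))) {
    stopf("VCF INFO lacks SVTYPE and/or END: %s", path)
  }
  svtype <- as.character(info$SVTYPE)
  endpos <- as.numeric(unlist(info$END))
  pos <- as.numeric(GenomicRanges::start(rr))
  scaffold <- as.character(GenomicRanges::seqnames(rr))
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0("sv_", seq_along(rr))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF has no GT genotype field: %s", path)
  samples <- colnames(gt)

  keep <- svtype %in% c("DEL", "DUP")
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    message(sprintf("read_sv_vcf: skipped %d record(s) with SVTYPE not in {DEL, DUP}",
                    n_skip))
  }
  if (sum(keep) == 0L) stopf("no DEL/DUP records in %s", path)

  scaffold <- scaffold[keep]; pos <- pos[keep]; endpos <- endpos[keep]
  svtype <- svtype[keep]; ids <- ids[keep]
  gt <- gt[keep, , drop = FALSE]
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))[keep]

  unknown <- setdiff(unique(scaffold), genome$name)
  if (length(unknown) > 0L) {
    stopf("VCF record(s) on scaffold(s) absent from the genome index: %s",
          paste(unknown, collapse = ", "))
  }
  bad <- endpos <= pos
  if (any(bad)) {
    stopf("END <= POS for record(s): %s", paste(ids[bad], collapse = ", "))
  }

  # expand multi-allelic rows: one output record per ALT allele index
  row_idx <- rep.int(seq_along(ids), n_alt)
  allele <- sequence(n_alt)
  locus_id <- ifelse(n_alt[row_idx] > 1L,
                     paste0(ids[row_idx], "_", allele), ids[row_idx])

  geno <- matrix(NA_integer_, nrow = length(row_idx), ncol = length(samples),
                 dimnames = list(locus_id, samples))
  tokens <- strsplit(gt, "[/|]")
  for (k in seq_along(row_idx)) {
    i <- row_idx[k]
    a <- as.character(allele[k])
    # gt (and thus tokens) is laid out column-major: index accordingly
    geno[k, ] <- vapply(seq_along(samples), function(s) {
      tok <- tokens[[(s - 1L) * nrow(gt) + i]]
      if (any(tok == ".") || length(tok) == 0L) return(NA_integer_)
      sum(tok == a)
    }, integer(1L))
  }

  loci <- data.frame(locus_id = locus_id,
                     scaffold = scaffold[row_idx],
                     start = pos[row_idx] - 1,
                     end = endpos[row_idx],
                     svtype = svtype[row_idx],
                     stringsAsFactors = FALSE)
  cnv_table(loci, geno, samples, groups = groups)
}

#' Write a CNV table as a svtyper-dialect VCF
#'
#' Emits VCF 4.2 with symbolic ALT alleles, `SVTYPE`/`END`/`SVLEN` INFO
#' keys and per-sample GT calls, the exact dialect [read_sv_vcf()]
#' consumes (round-trip safe). Records are sorted by genome scaffold
#' order, then start.
#'
#' @param table A [cnv_table()].
#' @param genome A [genome_index()] supplying the contig header lines.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sv_vcf <- function(table, genome, path) {
  check_scaffolds(table, genome)
  ord <- order(match(table$loci$scaffold, genome$name), table$loci$start)
  loci <- table$loci[ord, , drop = FALSE]
  geno <- table$genotypes[ord, , drop = FALSE]

  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno))
  gt_str[is.na(geno)] <- "./."

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvscape",
    sprintf("##contig=<ID=%s,length=%.0f>", genome$name, genome$length),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t"))
  svlen <- loci$end - loci$start
  svlen <- ifelse(loci$svtype == "DEL", -svlen, svlen)
  body <- paste(loci$scaffold,
                sprintf("%.0f", loci$start + 1),
                loci$locus_id,
                "N",
                paste0("<", loci$svtype, ">"),
                ".", ".",
                sprintf("SVTYPE=%s;END=%.0f;SVLEN=%.0f",
                        loci$svtype, loci$end, svlen),
                "GT",
                apply(gt_str, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Keeps rows of the requested feature type (default `"gene"`), converting
#' the 1-based inclusive GFF coordinates to internal 0-based half-open.
#' The `ID` attribute becomes `gene_id`; features without one get a
#' synthesized `gene_<n>` id with a warning. A `Note` (or `product`)
#' attribute, when present, is carried through as the annotation string.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type GFF3 `type` value to keep.
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `annotation`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  n <- length(gr)
  if (n == 0L) {
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, n)
  miss <- is.na(ids) | ids == ""
  if (any(miss)) {
    warnf("read_gff3: %d feature(s) without an ID attribute; ids synthesized",
          sum(miss))
    ids[miss] <- paste0("gene_", which(miss))
  }
  ann <- rep("", n)
  for (key in c("Note", "product")) {
    if (key %in% names(S4Vectors::mcols(gr))) {
      v <- S4Vectors::mcols(gr)[[key]]
      v <- vapply(as.list(v), function(z) paste(unlist(z), collapse = "; "),
                  character(1L))
      ann[ann == "" & !is.na(v)] <- v[ann == "" & !is.na(v)]
      break
    }
  }
  data.frame(gene_id = ids,
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             annotation = ann,
             stringsAsFactors = FALSE)
}

# write gene models (as returned by read_gff3/simulate_gene_models) as GFF3
write_gff3 <- function(genes, path, source = "cnvscape") {
  header <- "##gff-version 3"
  if (nrow(genes) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(nchar(genes$annotation) > 0L,
                         paste0(";Note=", gsub("[;=\t]", " ", genes$annotation)),
                         ""))
  body <- paste(genes$scaffold, source, "gene",
                sprintf("%.0f", genes$start + 1), sprintf("%.0f", genes$end),
                ".", strand, ".", attrs, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write intervals to a BED file
#'
#' Internal coordinates are already 0-based half-open, i.e. BED
#' convention: no conversion is applied. Output is sorted by the scaffold
#' order of `genome` (or lexicographically when `genome` is `NULL`), then
#' by start.
#'
#' @param intervals data.frame with columns `scaffold`, `start`, `end` and
#'   optionally `name` and `score`.
#' @param path Output path.
#' @param genome Optional [genome_index()] fixing the scaffold sort order.
#' @return Invisibly, the path.
#' @export
write_bed <- function(intervals, path, genome = NULL) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  key <- if (is.null(genome)) rank(intervals$scaffold, ties.method = "min")
         else match(intervals$scaffold, genome$name)
  ord <- order(key, intervals$start)
  df <- intervals[ord, , drop = FALSE]
  cols <- list(df$scaffold, sprintf("%.0f", df$start), sprintf("%.0f", df$end))
  if (!is.null(df$name)) cols <- c(cols, list(as.character(df$name)))
  if (!is.null(df$score)) cols <- c(cols, list(as.character(df$score)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

# write a .fai-style index (5 columns; only name/length are meaningful)
write_fai <- function(genome, path) {
  offset <- cumsum(c(0, head(genome$length + 1, -1)))
  writeLines(sprintf("%s\t%.0f\t%.0f\t%.0f\t%.0f",
                     genome$name, genome$length, offset,
                     80, 81), path)
  invisible(path)
}
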