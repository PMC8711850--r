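#' Multi-sample CNV catalog
#'
#' The central container of the package: one row per CNV locus (interval
#' plus SV type) and a locus x sample matrix of diploid alternate-allele
#' dosages. All coordinates are 0-based half-open; conversion to and from
#' 1-based formats (VCF, GFF3) happens only at I/O boundaries.
#'
#' @param loci data.frame with columns `locus_id`, `scaffold`, `start`,
#'   `end`, `svtype` (values "DEL"/"DUP"); `start`/`end` in 0-based
#'   half-open bp.
#' @param genotypes Integer matrix (loci x samples) of alternate-allele
#'   dosages in `0:2`; `NA` encodes a missing ("./.") genotype.
#' @param samples Character vector of sample identifiers (column order of
#'   `genotypes`).
#' @param groups Optional named character vector mapping sample ->
#'   group label (e.g. ecotype); samples absent from `groups` carry no
#'   label and are excluded from discriminant analyses.
#' @return An object of class `cnv_table`.
#' @export
cnv_table <- function(loci, genotypes, samples, groups = NULL) {
  required <- c("locus_id", "scaffold", "start", "end", "svtype")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0L) {
    stopf("loci is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)[required]
  loci$locus_id <- as.character(loci$locus_id)
  loci$scaffold <- as.character(loci$scaffold)
  loci$start <- as.numeric(loci$start)
  loci$end <- as.numeric(loci$end)
  loci$svtype <- as.character(loci$svtype)
  rownames(loci) <- NULL

  if (anyDuplicated(loci$locus_id)) {
    stopf("duplicate locus_id(s): %s",
          paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  }
  bad <- loci$end <= loci$start
  if (any(bad)) {
    stopf("end <= start for locus/loci: %s",
          paste(loci$locus_id[bad], collapse = ", "))
  }
  if (!all(loci$svtype %in% c("DEL", "DUP"))) {
    stopf("svtype must be DEL or DUP")
  }

  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.character(samples)
  if (nrow(loci) != nrow(genotypes)) {
    stopf("genotype matrix has %d rows but there are %d loci",
          nrow(genotypes), nrow(loci))
  }
  if (ncol(genotypes) != length(samples)) {
    stopf("genotype matrix has %d columns but there are %d samples",
          ncol(genotypes), length(samples))
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) > 0L && (min(vals) < 0L || max(vals) > 2L)) {
    stopf("genotype dosages must lie in 0..2 (or NA for missing)")
  }
  dimnames(genotypes) <- list(loci$locus_id, samples)

  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    unknown <- setdiff(names(groups), samples)
    if (length(unknown) > 0L) {
      stopf("group labels refer to unknown sample(s): %s",
            paste(unknown, collapse = ", "))
    }
  }

  structure(list(loci = loci, genotypes = genotypes,
                 samples = samples, groups = groups),
            class = "cnv_table")
}

#' @export
print.cnv_table <- function(x, ...) {
  cat(sprintf("<cnv_table> %d loci (%d DEL, %d DUP) x %d samples\n",
              nrow(x$loci), sum(x$loci$svtype == "DEL"),
              sum(x$loci$svtype == "DUP"), length(x$samples)))
  invisible(x)
}

#' Number of loci in a CNV table
#' @param table A [cnv_table()].
#' @return Integer count.
#' @export
n_loci <- function(table) nrow(table$loci)

#' CNV interval lengths
#' @param table A [cnv_table()].
#' @return Numeric vector of `end - start`, named by locus.
#' @export
cnv_lengths <- function(table) {
  stats::setNames(table$loci$end - table$loci$start, table$loci$locus_id)
}

# carriers per locus: samples with dosage >= 1; NA never counts
carrier_counts <- function(table) {
  rowSums(table$genotypes >= 1L, na.rm = TRUE)
}

# subset a cnv_table by a logical/integer locus index, keeping structure
subset_loci <- function(table, idx) {
  cnv_table(table$loci[idx, , drop = FALSE],
            table$genotypes[idx, , drop = FALSE],
            table$samples, table$groups)
}

# validate that every record scaffold exists in the genome index
check_scaffolds <- function(table, genome, what = "CNV") {
  unknown <- setdiff(unique(table$loci$scaffold), genome$name)
  if (length(unknown) > 0L) {
    stopf("%s record(s) on scaffold(s) absent from the genome index: %s",
          what, paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}
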