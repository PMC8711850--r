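#' Filter a CNV catalog on length and carrier count
#'
#' Keeps loci whose interval length is at least `min_length` bp and that
#' are carried (dosage >= 1) by at least `min_carriers` samples. Loci with
#' zero carriers (reference-only calls) are always removed. Singleton
#' removal (`min_carriers = 2`) discards variants seen in only one genome,
#' which are more likely de novo or artefactual than segregating variation.
#' The filter is idempotent and does not depend on record order.
#'
#' @param table A [cnv_table()].
#' @param min_length Minimum CNV length in bp (default 1000: CNVs are
#'   conventionally segments longer than 1 kb).
#' @param min_carriers Minimum number of carrier samples (default 2).
#' @return The filtered [cnv_table()].
#' @export
filter_cnvs <- function(table, min_length = 1000, min_carriers = 2) {
  if (!is.numeric(min_length) || min_length < 1) {
    stopf("min_length must be >= 1")
  }
  if (!is.numeric(min_carriers) || min_carriers < 0) {
    stopf("min_carriers must be >= 0")
  }
  len <- table$loci$end - table$loci$start
  carriers <- carrier_counts(table)
  keep <- len >= min_length & carriers >= max(min_carriers, 1)
  subset_loci(table, keep)
}

#' Per-sample CNV counts
#'
#' A sample's count is the number of loci at which it carries at least one
#' alternate allele; missing genotypes never count.
#'
#' @param table A [cnv_table()].
#' @return List with `counts` (named integer vector), `mean`, `min`, `max`.
#' @export
per_sample_counts <- function(table) {
  counts <- colSums(table$genotypes >= 1L, na.rm = TRUE)
  list(counts = counts,
       mean = if (length(counts)) mean(counts) else NaN,
       min = if (length(counts)) min(counts) else NA_integer_,
       max = if (length(counts)) max(counts) else NA_integer_)
}

#' Per-locus carrier frequencies
#'
#' Frequency = carriers / non-missing samples at each locus. Loci where
#' every genotype is missing are excluded from the mean with a warning.
#'
#' @param table A [cnv_table()].
#' @return List with `frequencies` (named numeric, NaN where all-missing)
#'   and `mean` over defined loci.
#' @export
locus_frequencies <- function(table) {
  n_obs <- rowSums(!is.na(table$genotypes))
  carriers <- carrier_counts(table)
  freq <- carriers / n_obs # 0/0 -> NaN
  if (any(n_obs == 0L)) {
    warnf("locus_frequencies: %d locus/loci with no non-missing genotypes excluded",
          sum(n_obs == 0L))
  }
  list(frequencies = stats::setNames(freq, table$loci$locus_id),
       mean = if (any(n_obs > 0L)) mean(freq[n_obs > 0L]) else NaN)
}

#' Genome coverage of the CNV union
#'
#' Length of the union of all CNV intervals (overlapping calls counted
#' once), and that length as a fraction of the assembly size.
#'
#' @param table A [cnv_table()].
#' @param genome A [genome_index()].
#' @return List with `covered_bp` and `coverage_fraction`.
#' @export
genome_coverage <- function(table, genome) {
  if (nrow(table$loci) == 0L) {
    return(list(covered_bp = 0, coverage_fraction = 0))
  }
  check_scaffolds(table, genome)
  covered <- 0
  for (sc in unique(table$loci$scaffold)) {
    i <- table$loci$scaffold == sc
    ir <- IRanges::IRanges(start = table$loci$start[i] + 1,
                           end = table$loci$end[i])
    covered <- covered + sum(IRanges::width(IRanges::reduce(ir)))
  }
  list(covered_bp = covered,
       coverage_fraction = covered / genome$total_length)
}

#' Welch two-sample t test on CNV lengths
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p value. The sign convention is `t > 0` when
#' `mean(a) > mean(b)`; call with `a` = duplication lengths and `b` =
#' deletion lengths to test whether deletions are the smaller class.
#'
#' @param lengths_a,lengths_b Numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p_two_sided`, `mean_a`, `mean_b`.
#' @export
length_comparison <- function(lengths_a, lengths_b) {
  a <- as.numeric(lengths_a); b <- as.numeric(lengths_b)
  if (length(a) < 2L || length(b) < 2L) {
    stopf("length_comparison needs >= 2 values per group")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) stopf("length_comparison: zero variance in both groups")
  sa <- va / length(a); sb <- vb / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1) + sb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p_two_sided = p, mean_a = mean(a), mean_b = mean(b))
}

#' Catalog-level summary statistics
#'
#' Assembles the genome-architecture summary of a (filtered) CNV catalog:
#' DEL/DUP counts, mean length, per-sample burden, mean carrier frequency,
#' genome coverage of the CNV union, and the number of scaffolds holding
#' at least one CNV.
#'
#' @param table A [cnv_table()] (typically after [filter_cnvs()]).
#' @param genome A [genome_index()].
#' @return An object of class `catalog_summary` (a named list).
#' @export
summarize_catalog <- function(table, genome) {
  n_total <- nrow(table$loci)
  if (n_total == 0L) {
    out <- list(n_total = 0L, n_del = 0L, n_dup = 0L, mean_length = NaN,
                per_sample_counts = stats::setNames(integer(length(table$samples)),
                                                    table$samples),
                mean_per_sample = 0, min_per_sample = 0L, max_per_sample = 0L,
                mean_locus_frequency = NaN,
                covered_bp = 0, coverage_fraction = 0,
                n_scaffolds_with_cnv = 0L)
    class(out) <- "catalog_summary"
    return(out)
  }
  psc <- per_sample_counts(table)
  freq <- suppressWarnings(locus_frequencies(table))
  cov <- genome_coverage(table, genome)
  out <- list(
    n_total = n_total,
    n_del = sum(table$loci$svtype == "DEL"),
    n_dup = sum(table$loci$svtype == "DUP"),
    mean_length = mean(table$loci$end - table$loci$start),
    per_sample_counts = psc$counts,
    mean_per_sample = psc$mean,
    min_per_sample = psc$min,
    max_per_sample = psc$max,
    mean_locus_frequency = freq$mean,
    covered_bp = cov$covered_bp,
    coverage_fraction = cov$coverage_fraction,
    n_scaffolds_with_cnv = length(unique(table$loci$scaffold)))
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "CNV catalog summary\n",
    "  loci:               %d (%d DEL, %d DUP)\n",
    "  mean length:        %.1f bp\n",
    "  per-sample count:   mean %.2f, range %s-%s\n",
    "  mean carrier freq:  %.3f\n",
    "  genome coverage:    %.0f bp (%.1f%%)\n",
    "  scaffolds with CNV: %d\n"),
    x$n_total, x$n_del, x$n_dup, x$mean_length,
    x$mean_per_sample, x$min_per_sample, x$max_per_sample,
    x$mean_locus_frequency, x$covered_bp, 100 * x$coverage_fraction,
    x$n_scaffolds_with_cnv))
  invisible(x)
}
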