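#' Genome index: ordered scaffolds and lengths
#'
#' A `genome_index` records scaffold names, lengths and the cumulative
#' offset of each scaffold in the concatenated (scaffolds laid end-to-end)
#' coordinate system used by the genome-wide spatial statistics.
#'
#' @param names Character vector of unique scaffold names.
#' @param lengths Numeric vector of positive scaffold lengths (bp).
#' @return An object of class `genome_index` with elements `name`,
#'   `length`, `offset` (bp start of each scaffold in concatenated
#'   coordinates, first offset 0) and `total_length`.
#' @examples
#' gi <- genome_index(c("s1", "s2"), c(1000, 500))
#' gi$total_length # 1500
#' @export
genome_index <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) stopf("genome index needs at least one scaffold")
  if (length(names) != length(lengths)) {
    stopf("names and lengths differ in length")
  }
  dup <- names[duplicated(names)]
  if (length(dup) > 0L) {
    stopf("duplicate scaffold name(s): %s", paste(unique(dup), collapse = ", "))
  }
  bad <- !is.finite(lengths) | lengths <= 0
  if (any(bad)) {
    stopf("non-positive length for scaffold(s): %s",
          paste(names[bad], collapse = ", "))
  }
  offsets <- cumsum(c(0, lengths[-length(lengths)]))
  structure(
    list(name = names, length = lengths,
         offset = stats::setNames(offsets, names),
         total_length = sum(lengths)),
    class = "genome_index")
}

#' Read a genome index from a FASTA .fai or two-column TSV
#'
#' The dialect is auto-detected from the column count: a `.fai` (5+
#' columns) uses columns 1-2, a plain TSV must have exactly name and
#' length columns. Scaffolds are kept in file order.
#'
#' @param path Path to the file.
#' @return A [genome_index()].
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) stopf("genome index file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (ncol(tab) < 2L) stopf("expected at least 2 tab-separated columns in %s", path)
  genome_index(tab[[1L]], tab[[2L]])
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d scaffold(s), %.0f bp total\n",
              length(x$name), x$total_length))
  invisible(x)
}

#' @export
as.data.frame.genome_index <- function(x, ...) {
  data.frame(name = x$name, length = x$length,
             offset = unname(x$offset), stringsAsFactors = FALSE)
}
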