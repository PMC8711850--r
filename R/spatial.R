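#' CNV midpoints in concatenated genome coordinates
#'
#' Each CNV contributes one position: its interval midpoint shifted by the
#' offset of its scaffold in the concatenated coordinate system (scaffolds
#' laid end-to-end in [genome_index()] order). Midpoint assignment (rather
#' than any-overlap) keeps Mb-scale CNVs from being multi-counted across
#' thousands of windows.
#'
#' @param table A [cnv_table()].
#' @param genome A [genome_index()].
#' @return Numeric vector of genome-wide positions, named by locus.
#' @export
concatenated_positions <- function(table, genome) {
  if (nrow(table$loci) == 0L) return(numeric(0))
  check_scaffolds(table, genome)
  off <- genome$offset[table$loci$scaffold]
  stats::setNames(off + (table$loci$start + table$loci$end) / 2,
                  table$loci$locus_id)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over all sample points of the absolute difference
#' between the two empirical CDFs; the p value comes from the asymptotic
#' Kolmogorov distribution evaluated at `sqrt(n_eff) * D` with effective
#' sample size `n_eff = n_x * n_y / (n_x + n_y)`.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `D`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- sort(as.numeric(x)); y <- sort(as.numeric(y))
  if (length(x) == 0L || length(y) == 0L) {
    stopf("ks_two_sample: both samples must be non-empty")
  }
  pooled <- sort(c(x, y))
  # findInterval on a sorted vector counts values <= each pooled point
  d_all <- abs(findInterval(pooled, x) / length(x) -
               findInterval(pooled, y) / length(y))
  D <- max(d_all)
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  list(D = D, p = p, n_x = length(x), n_y = length(y))
}

# survival function of the Kolmogorov distribution:
# Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2), clamped into (0, 1]
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(q, .Machine$double.xmin))
}

#' Genome-wide spatial randomness test for CNV positions
#'
#' Compares the distribution of CNV midpoints (in concatenated genome
#' coordinates) against positions drawn uniformly, without replacement,
#' from the non-CNV portion of the genome (the complement of the CNV
#' union), using the two-sample KS test. A small D with large p is
#' consistent with uniform CNV placement; clustering inflates D.
#'
#' @param table A non-empty [cnv_table()].
#' @param genome A [genome_index()].
#' @param n_draws Number of non-CNV positions to sample (default: one per
#'   CNV).
#' @param seed Integer seed controlling the complement sample.
#' @return List with `D`, `p`, `n_x`, `n_y` (see [ks_two_sample()]).
#' @export
spatial_randomness_test <- function(table, genome, n_draws = NULL, seed = 1L) {
  if (nrow(table$loci) == 0L) stopf("spatial_randomness_test: empty table")
  x <- concatenated_positions(table, genome)
  n_draws <- n_draws %||% length(x)

  # complement of the CNV union, in concatenated coordinates
  comp <- complement_intervals(table, genome)
  comp_len <- comp$end - comp$start
  total_free <- sum(comp_len)
  if (total_free <= 0) {
    stopf("spatial_randomness_test: CNV union covers the whole genome")
  }
  if (n_draws > total_free) {
    stopf("spatial_randomness_test: n_draws exceeds the number of non-CNV bases")
  }
  y <- with_seed(seed, {
    ranks <- sample(total_free, n_draws) # 1-based rank among free bases
    cum <- cumsum(comp_len)
    iv <- findInterval(ranks - 1, cum) + 1L # interval holding each rank
    before <- c(0, cum)[iv] # free bases preceding that interval
    comp$start[iv] + (ranks - before) - 1
  })
  ks_two_sample(x, y)
}

# concatenated-coordinate complement of the CNV union: data.frame(start, end)
complement_intervals <- function(table, genome) {
  check_scaffolds(table, genome)
  off <- genome$offset[table$loci$scaffold]
  ir <- IRanges::IRanges(start = off + table$loci$start + 1,
                         end = off + table$loci$end)
  ir <- IRanges::reduce(ir)
  gaps <- IRanges::gaps(ir, start = 1, end = genome$total_length)
  data.frame(start = IRanges::start(gaps) - 1,
             end = as.numeric(IRanges::end(gaps)))
}

#' Sliding-window CNV counts
#'
#' Tiles each scaffold from position 0 with windows of `window` bp placed
#' every `step` bp (the final windows are truncated at the scaffold end;
#' scaffolds shorter than `window` yield truncated windows). A CNV is
#' assigned to a window iff its midpoint lies in `[start, end)`.
#'
#' @param table A [cnv_table()].
#' @param genome A [genome_index()].
#' @param window Window size in bp (default 2 Mb).
#' @param step Window pace in bp (default 1 kb).
#' @return An object of class `window_track`: list with `windows`
#'   (data.frame scaffold/start/end/count), `window`, `step`.
#' @export
window_counts <- function(table, genome, window = 2e6, step = 1000) {
  if (window < 1 || step < 1) stopf("window and step must be >= 1")
  if (nrow(table$loci) > 0L) check_scaffolds(table, genome)
  mids2 <- split(table$loci$start + table$loci$end, table$loci$scaffold)

  pieces <- vector("list", length(genome$name))
  for (i in seq_along(genome$name)) {
    sc <- genome$name[i]
    len <- genome$length[i]
    starts <- seq(0, max(len - 1, 0), by = step)
    ends <- pmin(starts + window, len)
    m2 <- sort(mids2[[sc]] %||% numeric(0)) # doubled midpoints (integers)
    # count of midpoints with 2*mid in [2*start, 2*end)
    cnt <- findInterval(2 * ends - 0.5, m2) - findInterval(2 * starts - 0.5, m2)
    pieces[[i]] <- data.frame(scaffold = sc, start = starts, end = ends,
                              count = cnt, stringsAsFactors = FALSE)
  }
  structure(list(windows = do.call(rbind, pieces), window = window, step = step),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("<window_track> %d windows (%g bp / pace %g bp), max count %d\n",
              nrow(x$windows), x$window, x$step,
              if (nrow(x$windows)) max(x$windows$count) else 0L))
  invisible(x)
}

#' Detect CNV hotspots from a window track
#'
#' The threshold is the genome-wide empirical `quantile` of all window
#' counts (linear-interpolation quantile, R type 7). Windows with counts
#' strictly above the threshold are supra-threshold; overlapping or
#' abutting supra-threshold windows on the same scaffold merge into one
#' hotspot whose interval is their union. With `step < window` consecutive
#' supra-threshold windows always overlap, so a hotspot is a contiguous
#' run of extreme windows. In the degenerate all-equal case no window is
#' strictly above the quantile and no hotspot is reported.
#'
#' @param track A `window_track` from [window_counts()].
#' @param quantile Upper-tail probability defining the threshold
#'   (default 0.975).
#' @param table Optional [cnv_table()]; when supplied, each hotspot's
#'   `n_cnvs` counts the distinct CNVs whose midpoints fall inside the
#'   merged interval (otherwise `n_cnvs` is `NA`).
#' @return data.frame with columns `scaffold`, `start`, `end`,
#'   `n_windows`, `n_cnvs`, sorted and pairwise disjoint.
#' @export
detect_hotspots <- function(track, quantile = 0.975, table = NULL) {
  if (quantile <= 0 || quantile >= 1) stopf("quantile must be in (0, 1)")
  w <- track$windows
  empty <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      n_cnvs = integer(), stringsAsFactors = FALSE)
  if (is.null(w) || nrow(w) == 0L) return(empty)
  thr <- stats::quantile(w$count, probs = quantile, names = FALSE, type = 7)
  supra <- w[w$count > thr, , drop = FALSE]
  if (nrow(supra) == 0L) return(empty)

  out <- list()
  for (sc in unique(supra$scaffold)) {
    s <- supra[supra$scaffold == sc, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(s$start[-1L] > cummax(s$end[-nrow(s)]))))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = min(sg$start), end = max(sg$end),
        n_windows = nrow(sg), n_cnvs = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  hs <- do.call(rbind, out)
  hs <- hs[order(match(hs$scaffold, unique(w$scaffold)), hs$start), , drop = FALSE]
  rownames(hs) <- NULL

  if (!is.null(table)) {
    mid_sc <- table$loci$scaffold
    mid <- (table$loci$start + table$loci$end) / 2
    hs$n_cnvs <- vapply(seq_len(nrow(hs)), function(i) {
      sum(mid_sc == hs$scaffold[i] & mid >= hs$start[i] & mid < hs$end[i])
    }, integer(1L))
  }
  hs
}
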