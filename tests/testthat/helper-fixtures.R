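# in-code fixtures shared across test files

toy_genome <- function(lens = c(s1 = 5e6, s2 = 3e6, s3 = 2e6)) {
  genome_index(names(lens), unname(lens))
}

# build a cnv_table from minimal arguments; genotypes default to making
# every sample a het carrier at every locus
toy_table <- function(scaffold, start, end,
                      svtype = rep("DEL", length(start)),
                      geno = NULL, n_samples = 4L, groups = NULL,
                      locus_id = sprintf("cnv%03d", seq_along(start))) {
  if (is.null(geno)) {
    geno <- matrix(1L, length(start), n_samples)
  }
  samples <- sprintf("smp%02d", seq_len(ncol(geno)))
  cnv_table(data.frame(locus_id = locus_id, scaffold = scaffold,
                       start = start, end = end, svtype = svtype,
                       stringsAsFactors = FALSE),
            geno, samples, groups = groups)
}

# uniform random catalog on a genome, for oracle comparisons
random_table <- function(genome, n, n_samples = 6L, seed = 1L,
                         len_range = c(1000, 50000)) {
  with_seed(seed, {
    sc_i <- sample.int(length(genome$name), n, replace = TRUE,
                       prob = genome$length)
    len <- round(runif(n, len_range[1L], len_range[2L]))
    start <- floor(runif(n) * (genome$length[sc_i] - len))
    geno <- matrix(sample(c(0L, 1L, 2L, NA_integer_), n * n_samples,
                          replace = TRUE, prob = c(0.45, 0.3, 0.2, 0.05)),
                   n, n_samples)
    toy_table(genome$name[sc_i], start, start + len,
              svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
              geno = geno)
  })
}

# interval Jaccard index on a shared scaffold
jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  if (inter <= 0) return(0)
  inter / ((a2 - a1) + (b2 - b1) - inter)
}

# fraction of planted hotspot intervals recovered at a Jaccard threshold
hotspot_recovery <- function(planted, detected, threshold = 0.5) {
  if (nrow(planted) == 0L) return(NA_real_)
  rec <- vapply(seq_len(nrow(planted)), function(i) {
    same <- which(detected$scaffold == planted$scaffold[i])
    if (length(same) == 0L) return(0)
    max(vapply(same, function(j) {
      jaccard(planted$start[i], planted$end[i],
              detected$start[j], detected$end[j])
    }, numeric(1L)))
  }, numeric(1L))
  mean(rec >= threshold)
}
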