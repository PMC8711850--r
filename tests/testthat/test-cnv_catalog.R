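test_that("filter_cnvs applies length and carrier rules", {
  # 6 records: lengths 500, 1000, 2000 x4; carriers 0, 1, 2, 3, 4, 2
  geno <- rbind(c(1L, 1L, 0L, 0L),  # length 500  -> out (length)
                c(0L, 0L, 0L, 0L),  # 0 carriers  -> out
                c(1L, 0L, 0L, 0L),  # 1 carrier   -> out (singleton)
                c(1L, 1L, 0L, 0L),
                c(1L, 1L, 1L, 1L),
                c(2L, NA, 1L, 0L))
  tab <- toy_table(rep("s1", 6), c(0, 1000, 3000, 6000, 9000, 12000),
                   c(500, 2000, 5000, 8000, 11000, 13000), geno = geno)
  out <- filter_cnvs(tab, min_length = 1000, min_carriers = 2)
  expect_equal(out$loci$locus_id, c("cnv004", "cnv005", "cnv006"))

  # brute-force re-scan agrees
  keep <- vapply(seq_len(n_loci(tab)), function(i) {
    len <- tab$loci$end[i] - tab$loci$start[i]
    carriers <- sum(tab$genotypes[i, ] >= 1, na.rm = TRUE)
    len >= 1000 && carriers >= 2
  }, logical(1L))
  expect_equal(out$loci$locus_id, tab$loci$locus_id[keep])

  # idempotent and order-insensitive
  expect_identical(filter_cnvs(out), out)
  perm <- with_seed(1, sample(n_loci(tab)))
  out_perm <- filter_cnvs(subset_perm <- cnv_table(
    tab$loci[perm, ], tab$genotypes[perm, ], tab$samples))
  expect_setequal(out_perm$loci$locus_id, out$loci$locus_id)

  expect_error(filter_cnvs(tab, min_length = 0), "min_length")
  expect_error(filter_cnvs(tab, min_carriers = -1), "min_carriers")
})

test_that("per_sample_counts and locus_frequencies match loop oracles", {
  genome <- toy_genome()
  tab <- random_table(genome, 50, n_samples = 8L, seed = 11L)

  psc <- per_sample_counts(tab)
  oracle_counts <- vapply(seq_along(tab$samples), function(s) {
    n <- 0L
    for (i in seq_len(n_loci(tab))) {
      g <- tab$genotypes[i, s]
      if (!is.na(g) && g >= 1L) n <- n + 1L
    }
    n
  }, integer(1L))
  expect_equal(unname(psc$counts), oracle_counts)
  expect_equal(psc$mean, mean(oracle_counts))

  lf <- locus_frequencies(tab)
  oracle_freq <- vapply(seq_len(n_loci(tab)), function(i) {
    g <- tab$genotypes[i, ]
    sum(g >= 1, na.rm = TRUE) / sum(!is.na(g))
  }, numeric(1L))
  expect_equal(unname(lf$frequencies), oracle_freq)
  expect_equal(lf$mean, mean(oracle_freq[is.finite(oracle_freq)]))
})

test_that("per-sample and frequency edge cases behave", {
  # one locus, every sample a carrier
  tab <- toy_table("s1", 0, 2000, n_samples = 20L)
  expect_true(all(per_sample_counts(tab)$counts == 1L))
  expect_equal(unname(locus_frequencies(tab)$frequencies), 1)

  # a sample with all-missing genotypes counts zero
  geno <- matrix(c(1L, 1L, NA, NA), 2, 2)
  tab2 <- toy_table("s1", c(0, 5000), c(2000, 7000), geno = geno)
  expect_equal(unname(per_sample_counts(tab2)$counts), c(2L, 0L))

  # 7 carriers of 20 -> 0.35
  geno3 <- matrix(c(rep(1L, 7), rep(0L, 13)), 1, 20)
  tab3 <- toy_table("s1", 0, 2000, geno = geno3)
  expect_equal(unname(locus_frequencies(tab3)$frequencies), 0.35)

  # all-missing locus excluded with warning
  geno4 <- rbind(rep(NA_integer_, 3), c(1L, 0L, 0L))
  tab4 <- toy_table("s1", c(0, 5000), c(2000, 7000), geno = geno4)
  expect_warning(lf <- locus_frequencies(tab4), "no non-missing")
  expect_equal(lf$mean, 1 / 3)
})

test_that("genome_coverage equals a per-base mask oracle", {
  genome <- genome_index(c("s1", "s2", "s3"), c(10000, 8000, 5000))

  one <- toy_table("s3", 0, 5000)
  expect_equal(genome_coverage(one, genome_index("s3", 5000))$coverage_fraction, 1)

  two <- toy_table(c("s1", "s1"), c(0, 50), c(100, 150))
  expect_equal(genome_coverage(two, genome)$covered_bp, 150)

  tab <- random_table(genome, 200, seed = 3L, len_range = c(10, 900))
  cov <- genome_coverage(tab, genome)
  mask_total <- 0
  for (sc in genome$name) {
    mask <- logical(genome$length[genome$name == sc])
    idx <- which(tab$loci$scaffold == sc)
    for (i in idx) {
      mask[(tab$loci$start[i] + 1):tab$loci$end[i]] <- TRUE
    }
    mask_total <- mask_total + sum(mask)
  }
  expect_equal(cov$covered_bp, mask_total)
  expect_equal(cov$coverage_fraction, mask_total / genome$total_length)

  # monotonicity and union bound
  more <- cnv_table(rbind(tab$loci,
                          data.frame(locus_id = "extra", scaffold = "s2",
                                     start = 0, end = 4000, svtype = "DUP")),
                    rbind(tab$genotypes, rep(1L, length(tab$samples))),
                    tab$samples)
  expect_gte(genome_coverage(more, genome)$covered_bp, cov$covered_bp)
  expect_lte(cov$covered_bp, sum(cnv_lengths(tab)))
})

test_that("length_comparison reproduces the closed-form Welch statistic", {
  # a = {10,12,14}, b = {1,2,3}: t = 10/sqrt(5/3), df = 50/17 (by hand)
  res <- length_comparison(c(10, 12, 14), c(1, 2, 3))
  expect_equal(res$t, 7.7459666924, tolerance = 1e-9)
  expect_equal(res$df, 50 / 17, tolerance = 1e-12)
  expect_equal(res$p_two_sided, 4.7979996991e-03, tolerance = 1e-8)
  # independent oracle
  tt <- stats::t.test(c(10, 12, 14), c(1, 2, 3))
  expect_equal(res$p_two_sided, unname(tt$p.value))

  # symmetry, scale invariance, sign convention
  same <- length_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  scaled <- length_comparison(1000 * c(10, 12, 14), 1000 * c(1, 2, 3))
  expect_equal(scaled$t, res$t)
  expect_equal(scaled$df, res$df)
  expect_equal(scaled$p_two_sided, res$p_two_sided)
  expect_lt(length_comparison(c(1, 2, 3), c(10, 12, 14))$t, 0)

  expect_error(length_comparison(5, c(1, 2)), ">= 2 values")
  expect_error(length_comparison(c(2, 2), c(3, 3)), "zero variance")
})

test_that("summarize_catalog assembles every field from its oracle", {
  genome <- toy_genome()
  tab <- random_table(genome, 100, n_samples = 8L, seed = 23L)
  s <- summarize_catalog(tab, genome)

  expect_equal(s$n_total, 100L)
  expect_equal(s$n_total, s$n_del + s$n_dup)            # conservation
  expect_equal(s$n_del, sum(tab$loci$svtype == "DEL"))
  expect_equal(s$mean_length, mean(tab$loci$end - tab$loci$start))
  expect_equal(s$per_sample_counts, per_sample_counts(tab)$counts)
  expect_equal(s$mean_locus_frequency, locus_frequencies(tab)$mean)
  expect_equal(s$covered_bp, genome_coverage(tab, genome)$covered_bp)
  expect_equal(s$n_scaffolds_with_cnv, length(unique(tab$loci$scaffold)))
  expect_true(s$min_per_sample <= s$mean_per_sample &&
              s$mean_per_sample <= s$max_per_sample)

  dels <- subset_del <- filter_cnvs(tab, min_length = 1, min_carriers = 0)
  only_del <- cnv_table(tab$loci[tab$loci$svtype == "DEL", ],
                        tab$genotypes[tab$loci$svtype == "DEL", ],
                        tab$samples)
  sd_ <- summarize_catalog(only_del, genome)
  expect_equal(sd_$n_dup, 0L)
  expect_equal(sd_$n_total, sd_$n_del)

  empty <- cnvscape:::subset_loci(tab, rep(FALSE, 100))
  se <- summarize_catalog(empty, genome)
  expect_equal(se$n_total, 0L)
  expect_equal(se$coverage_fraction, 0)
  expect_true(is.nan(se$mean_locus_frequency))
})

test_that("loci surviving min_carriers=2 with 20 samples have frequency >= 0.1", {
  p <- sim_params(scaffold_lengths = c(2e7, 1e7), n_loci = 120,
                  hotspot_count = 1L, hotspot_width = 2e6, seed = 5)
  sim <- simulate_cnv_catalog(simulate_genome(p), p)
  filt <- filter_cnvs(sim$table)
  freq <- locus_frequencies(filt)$frequencies
  expect_true(all(freq >= 2 / 20))
})
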