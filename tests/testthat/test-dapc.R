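# a small labelled table: 4 + 4 samples, controllable genotypes
labelled_table <- function(geno, groups = rep(c("A", "B"), each = 4L)) {
  n <- nrow(geno)
  samples <- sprintf("smp%02d", seq_len(ncol(geno)))
  cnv_table(data.frame(locus_id = sprintf("L%03d", seq_len(n)),
                       scaffold = "s1", start = seq_len(n) * 1e4,
                       end = seq_len(n) * 1e4 + 2000,
                       svtype = "DEL", stringsAsFactors = FALSE),
            geno, samples, groups = stats::setNames(groups, samples))
}

test_that("encode_dosage imputes, drops monomorphic loci, excludes unlabeled", {
  geno <- rbind(c(0L, 1L, 2L, NA, 0L, 1L, 2L, 0L),  # mean-imputed
                c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),  # monomorphic -> dropped
                c(0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L))
  tab <- labelled_table(geno)
  expect_warning(m <- encode_dosage(tab), "zero-variance")
  expect_equal(m$locus_ids, c("L001", "L003"))
  expect_equal(unname(m$values[4L, "L001"]), mean(c(0, 1, 2, 0, 1, 2, 0)))

  # unlabeled sample excluded from discrimination
  g2 <- stats::setNames(rep(c("A", "B"), each = 4L)[-8L],
                        sprintf("smp%02d", 1:7))
  expect_message(m2 <- suppressWarnings(encode_dosage(tab, groups = g2)),
                 "excluded.*smp08")
  expect_equal(nrow(m2$values), 7L)

  # binarize collapses dosage to carrier status
  m3 <- suppressWarnings(encode_dosage(tab, binarize = TRUE))
  expect_true(all(m3$values >= 0 & m3$values <= 1))
})

test_that("fit_pca is a faithful SVD decomposition", {
  with_seed(17, {
    geno <- matrix(sample(0:2, 8 * 30, replace = TRUE), 30, 8)
  })
  geno[1, 1] <- 1L # ensure some variance
  m <- suppressWarnings(encode_dosage(labelled_table(geno)))
  pca <- fit_pca(m)

  expect_true(all(diff(pca$variance_fraction) <= 1e-12)) # non-increasing
  expect_equal(sum(pca$variance_fraction), 1)
  # rotation orthonormal
  k <- ncol(pca$rotation)
  expect_equal(crossprod(pca$rotation), diag(k), ignore_attr = TRUE,
               tolerance = 1e-8)
  # full-rank reconstruction returns the centered matrix
  centered <- scale(m$values, center = TRUE, scale = FALSE)
  expect_equal(pca$scores %*% t(pca$rotation), centered,
               ignore_attr = TRUE, tolerance = 1e-8)

  # rank-1 toy: two samples, one nonzero PC
  m2 <- list(values = rbind(c(0, 0, 0), c(2, 2, 2)),
             sample_ids = c("a", "b"), locus_ids = c("x", "y", "z"),
             groups = c(a = "A", b = "B"))
  class(m2) <- "dosage_matrix"
  pca2 <- fit_pca(m2)
  expect_equal(length(pca2$variance_fraction), 1L)
  expect_equal(pca2$variance_fraction, 1)
})

test_that("choose_n_pcs follows the cumulative-variance rule", {
  expect_equal(choose_n_pcs(c(0.5, 0.3, 0.2), 0.875), 3L)
  expect_equal(choose_n_pcs(c(0.5, 0.3, 0.2), 0.4), 1L)
  expect_equal(choose_n_pcs(c(0.9, 0.1), 0.95, cap = 1L), 1L)
  expect_equal(choose_n_pcs(c(0.5, 0.4, 0.1), 0.9), 2L)
})

test_that("fit_dapc isolates a single informative locus", {
  # locus 1 separates groups; the rest vary orthogonally to the labels
  noise <- rbind(rep(c(0L, 1L), 4L), rep(c(1L, 0L), 4L),
                 rep(c(0L, 0L, 1L, 1L), 2L), rep(c(1L, 1L, 0L, 0L), 2L))
  geno <- rbind(c(rep(0L, 4L), rep(2L, 4L)), noise)
  tab <- labelled_table(geno)
  m <- encode_dosage(tab)
  model <- fit_dapc(m, n_pcs = 3L)

  expect_gt(model$contributions[["L001"]], 0.98)
  expect_equal(sum(model$contributions), 1, tolerance = 1e-9)
  expect_true(all(model$contributions >= 0))

  # group A scores do not overlap group B scores
  sA <- model$individual_scores[model$groups == "A"]
  sB <- model$individual_scores[model$groups == "B"]
  expect_true(max(sA) < min(sB) || max(sB) < min(sA))

  # swapping labels flips score signs, contributions unchanged
  swapped <- stats::setNames(rep(c("B", "A"), each = 4L), names(tab$groups))
  m2 <- encode_dosage(tab, groups = swapped)
  model2 <- fit_dapc(m2, n_pcs = 3L)
  expect_equal(model2$individual_scores, -model$individual_scores,
               tolerance = 1e-8)
  expect_equal(model2$contributions, model$contributions, tolerance = 1e-8)
})

test_that("fit_dapc rejects degenerate group structures", {
  geno <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L),
                c(2L, 1L, 0L, 2L, 1L, 0L, 2L, 1L))
  tab3 <- labelled_table(geno, groups = c("A", "A", "A", "B", "B", "C", "C", "C"))
  expect_error(fit_dapc(encode_dosage(tab3)), "exactly 2")
  tab1 <- labelled_table(geno, groups = c("A", rep("B", 7L)))
  expect_error(fit_dapc(encode_dosage(tab1)), ">= 2 samples")
})

test_that("discriminant scores beat every single retained PC at separation", {
  p <- sim_params(scaffold_lengths = c(2e7, 1e7), n_loci = 200,
                  hotspot_count = 1L, hotspot_width = 2e6,
                  n_divergent = 8L, seed = 77)
  sim <- simulate_cnv_catalog(simulate_genome(p), p)
  m <- suppressWarnings(encode_dosage(sim$table))
  model <- fit_dapc(m)
  pca <- fit_pca(m)

  ratio <- function(v, g) {
    mu <- tapply(v, g, mean)
    b <- sum(table(g) * (mu - mean(v))^2)
    w <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
    b / w
  }
  g <- m$groups
  dapc_ratio <- ratio(model$individual_scores, g)
  pc_ratios <- apply(pca$scores[, seq_len(model$n_pcs), drop = FALSE], 2L,
                     ratio, g = g)
  expect_true(all(dapc_ratio >= pc_ratios - 1e-9))
})

test_that("select_divergent applies the ceiling rule and handles ties", {
  expect_equal(select_divergent(rev(seq_len(1698)) / sum(1:1698), 0.025)$k, 43L)
  expect_equal(select_divergent(runif(100), 0.025)$k, 3L)

  contrib <- stats::setNames(rep(0.01, 100), sprintf("L%03d", 1:100))
  expect_warning(hits <- select_divergent(contrib, 0.025), "tie")
  expect_equal(hits$locus_ids, c("L001", "L002", "L003"))

  contrib2 <- stats::setNames(c(0.5, 0.3, 0.2, rep(0, 97)), sprintf("x%d", 1:100))
  hits2 <- select_divergent(contrib2, 0.025)
  expect_equal(hits2$locus_ids, c("x1", "x2", "x3"))
  expect_equal(hits2$threshold_value, 0.2)
  expect_error(select_divergent(contrib2, 0), "q must be")
})

test_that("permutation_null is seeded and sized correctly", {
  p <- sim_params(scaffold_lengths = c(2e7, 1e7), n_loci = 100,
                  hotspot_count = 1L, hotspot_width = 2e6,
                  n_divergent = 0L, seed = 13)
  sim <- simulate_cnv_catalog(simulate_genome(p), p)
  m <- suppressWarnings(encode_dosage(sim$table))

  expect_identical(permutation_null(m, n_perm = 0L), numeric(0))
  n1 <- permutation_null(m, n_perm = 7L, seed = 5L)
  n2 <- permutation_null(m, n_perm = 7L, seed = 5L)
  expect_identical(n1, n2)
  expect_length(n1, 7L)
  expect_true(all(n1 > 0 & n1 <= 1))
})

test_that("label permutation destroys planted signal", {
  # recovery under permuted labels is indistinguishable from random picks
  hits_per_seed <- vapply(1:20, function(s) {
    p <- sim_params(scaffold_lengths = c(4e7, 2e7), n_loci = 200,
                    hotspot_count = 1L, hotspot_width = 4e6,
                    n_divergent = 10L, seed = 500 + s)
    sim <- simulate_cnv_catalog(simulate_genome(p), p)
    m <- suppressWarnings(encode_dosage(sim$table))
    perm_groups <- with_seed(600 + s,
      stats::setNames(sample(unname(m$groups)), names(m$groups)))
    mp <- m
    mp$groups <- perm_groups
    model <- fit_dapc(mp)
    sel <- select_divergent(model, q = 12 / length(model$contributions))
    sum(sim$truth$divergent_locus_ids %in% sel$locus_ids)
  }, numeric(1L))
  # random selection expectation: 12/200 * 10 = 0.6 per seed
  n_sel <- sum(hits_per_seed)
  pb <- stats::binom.test(n_sel, 20L * 10L, p = 12 / 200)
  expect_gt(pb$p.value, 0.01)
})
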