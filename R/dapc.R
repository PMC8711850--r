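#' Encode a CNV table as a sample x locus dosage matrix
#'
#' Builds the numeric matrix fed to PCA/DAPC: rows are samples that carry
#' a group label, columns are loci, entries are alternate-allele dosages
#' in 0..2. Missing genotypes are imputed by the locus mean over
#' non-missing samples; loci with zero variance after imputation carry no
#' information for any linear analysis and are dropped with a warning.
#' Unlabeled samples (e.g. an ecotype represented by a single individual)
#' are excluded from discrimination.
#'
#' @param table A [cnv_table()].
#' @param groups Named character vector sample -> group label; defaults to
#'   `table$groups`.
#' @param binarize If `TRUE`, dosages are reduced to carrier status (0/1)
#'   before imputation.
#' @return An object of class `dosage_matrix`: list with `values`
#'   (samples x loci), `sample_ids`, `locus_ids`, `groups`.
#' @export
encode_dosage <- function(table, groups = NULL, binarize = FALSE) {
  groups <- groups %||% table$groups
  if (is.null(groups)) stopf("encode_dosage: no group labels available")
  labelled <- intersect(table$samples, names(groups))
  dropped <- setdiff(table$samples, labelled)
  if (length(dropped) > 0L) {
    message(sprintf("encode_dosage: %d unlabeled sample(s) excluded: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(labelled) < 2L) stopf("encode_dosage: fewer than 2 labelled samples")

  m <- t(table$genotypes[, labelled, drop = FALSE]) * 1.0
  if (binarize) m[m > 0] <- 1
  # mean imputation per locus
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2L]]
  }
  v <- apply(m, 2L, stats::var)
  keep <- is.finite(v) & v > 0
  if (any(!keep)) {
    warnf("encode_dosage: %d zero-variance locus/loci dropped", sum(!keep))
  }
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stopf("encode_dosage: no variable loci left")
  structure(list(values = m,
                 sample_ids = rownames(m),
                 locus_ids = colnames(m),
                 groups = stats::setNames(as.character(groups[rownames(m)]),
                                          rownames(m))),
            class = "dosage_matrix")
}

#' Principal component analysis of a dosage matrix
#'
#' Singular value decomposition of the (column-centered, optionally
#' scaled) matrix. Variance fractions are computed over all non-null
#' components, so they sum to 1; rotation columns are orthonormal.
#'
#' @param m A `dosage_matrix` from [encode_dosage()].
#' @param center,scale Centering/scaling flags (defaults: center, no
#'   scaling — dosages share a common unit).
#' @return List with `rotation` (loci x k), `variance_fraction`, `scores`
#'   (samples x k), `column_means`, `column_scale`.
#' @export
fit_pca <- function(m, center = TRUE, scale = FALSE) {
  x <- scale(m$values, center = center, scale = scale)
  mu <- if (center) attr(x, "scaled:center") else rep(0, ncol(x))
  sc <- if (scale) attr(x, "scaled:scale") else rep(1, ncol(x))
  s <- svd(x)
  keep <- s$d > max(s$d) * 1e-9
  d <- s$d[keep]
  list(rotation = s$v[, keep, drop = FALSE],
       variance_fraction = d^2 / sum(d^2),
       scores = x %*% s$v[, keep, drop = FALSE],
       column_means = stats::setNames(as.numeric(mu), m$locus_ids),
       column_scale = stats::setNames(as.numeric(sc), m$locus_ids))
}

#' Number of principal components reaching a cumulative-variance target
#'
#' The smallest n whose cumulative variance fraction reaches
#' `target_cumulative`, clipped into `[1, cap]`. An explicitly requested
#' `n_pcs` (in the callers) overrides this rule.
#'
#' @param variance_fractions Non-increasing per-PC variance fractions.
#' @param target_cumulative Cumulative variance target (default 0.875).
#' @param cap Upper bound on the retained count (callers default this to
#'   `n_samples - 2` so the within-group covariance stays invertible).
#' @return Integer count of PCs to retain.
#' @export
choose_n_pcs <- function(variance_fractions, target_cumulative = 0.875,
                         cap = length(variance_fractions)) {
  cs <- cumsum(variance_fractions)
  n <- which(cs >= target_cumulative - 1e-12)[1L]
  if (is.na(n)) n <- length(variance_fractions)
  max(1L, min(as.integer(n), as.integer(cap), length(variance_fractions)))
}

#' Discriminant analysis of principal components (two groups)
#'
#' PCA reduces the dosage matrix to `n_pcs` orthogonal axes; a linear
#' discriminant of the two group labels is then fit on the retained PC
#' scores. With two groups the discriminant subspace is one-dimensional
#' and the coefficient vector has the closed form `W^-1 (mu1 - mu2)`,
#' where `W` is the pooled within-group covariance of the PC scores and
#' `mu1`, `mu2` the group centroids (a ridge of `1e-8 * trace(W)` is
#' added to the diagonal against singularity). Each locus receives a
#' composite loading (PC rotation times discriminant coefficients); the
#' squared loadings normalized to sum to one are the per-locus
#' contributions used for divergent-locus selection.
#'
#' @param m A `dosage_matrix` with exactly two group labels, each carried
#'   by at least 2 samples.
#' @param n_pcs Number of PCs to retain; `NULL` applies [choose_n_pcs()]
#'   with `variance_target`, capped at `n_samples - 2`.
#' @param variance_target Cumulative-variance target used when `n_pcs` is
#'   `NULL`.
#' @param center,scale Passed to [fit_pca()].
#' @return An object of class `dapc_model`: list with `column_means`,
#'   `n_pcs`, `pc_rotation`, `pc_variance_fraction`,
#'   `cumulative_variance`, `discriminant_coefficients`,
#'   `individual_scores`, `loadings` (signed composite loadings),
#'   `contributions` (non-negative, sum 1), `groups`, `group_levels`.
#' @export
fit_dapc <- function(m, n_pcs = NULL, variance_target = 0.875,
                     center = TRUE, scale = FALSE) {
  lv <- sort(unique(unname(m$groups)))
  if (length(lv) != 2L) {
    stopf("fit_dapc: exactly 2 group labels required, got %d", length(lv))
  }
  sizes <- table(m$groups)
  if (any(sizes < 2L)) {
    stopf("fit_dapc: every group needs >= 2 samples")
  }
  pca <- fit_pca(m, center = center, scale = scale)
  n_avail <- length(pca$variance_fraction)
  cap <- max(1L, length(m$sample_ids) - 2L)
  if (is.null(n_pcs)) {
    n_pcs <- choose_n_pcs(pca$variance_fraction, variance_target, cap = cap)
  }
  n_pcs <- max(1L, min(as.integer(n_pcs), n_avail))

  S <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  g <- m$groups
  s1 <- S[g == lv[1L], , drop = FALSE]
  s2 <- S[g == lv[2L], , drop = FALSE]
  W <- ((nrow(s1) - 1) * stats::cov(s1) + (nrow(s2) - 1) * stats::cov(s2)) /
    (nrow(S) - 2)
  ridge <- 1e-8 * sum(diag(W))
  if (ridge <= 0) ridge <- 1e-8
  coef <- solve(W + diag(ridge, n_pcs), colMeans(s1) - colMeans(s2))
  coef <- coef / sqrt(sum(coef^2))

  ind <- as.numeric(S %*% coef)
  loadings <- as.numeric(pca$rotation[, seq_len(n_pcs), drop = FALSE] %*% coef)
  contrib <- loadings^2 / sum(loadings^2)

  structure(list(
    column_means = pca$column_means,
    n_pcs = n_pcs,
    pc_rotation = pca$rotation[, seq_len(n_pcs), drop = FALSE],
    pc_variance_fraction = pca$variance_fraction[seq_len(n_pcs)],
    cumulative_variance = sum(pca$variance_fraction[seq_len(n_pcs)]),
    discriminant_coefficients = coef,
    individual_scores = stats::setNames(ind, m$sample_ids),
    loadings = stats::setNames(loadings, m$locus_ids),
    contributions = stats::setNames(contrib, m$locus_ids),
    groups = m$groups,
    group_levels = lv),
    class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<dapc_model> %d PCs retained (%.1f%% of variance), groups %s vs %s,\n",
    "  %d loci; top contribution %.4f\n"),
    x$n_pcs, 100 * x$cumulative_variance, x$group_levels[1L],
    x$group_levels[2L], length(x$contributions), max(x$contributions)))
  invisible(x)
}

#' Select divergent loci from DAPC contributions
#'
#' Picks the `ceiling(q * n_loci)` loci with the largest contributions to
#' the discriminant axis — the upper tail of the loading-score
#' distribution. Ties at the threshold are broken by locus order with a
#' warning.
#'
#' @param model A `dapc_model`, or a (named) numeric vector of
#'   contributions.
#' @param q Upper-tail fraction (default 0.025).
#' @return List with `locus_ids`, `threshold_value` (smallest selected
#'   contribution), `q`, `k`.
#' @export
select_divergent <- function(model, q = 0.025) {
  if (q <= 0 || q >= 1) stopf("q must be in (0, 1)")
  contrib <- if (inherits(model, "dapc_model")) model$contributions
             else stats::setNames(as.numeric(model), names(model))
  if (is.null(names(contrib))) {
    names(contrib) <- paste0("locus_", seq_along(contrib))
  }
  n <- length(contrib)
  k <- as.integer(ceiling(q * n))
  ord <- order(-contrib, seq_len(n)) # stable: ties broken by locus order
  sel <- ord[seq_len(k)]
  thr <- contrib[sel[k]]
  if (k < n && contrib[ord[k + 1L]] == thr) {
    warnf("select_divergent: tie at the selection threshold broken by locus order")
  }
  list(locus_ids = names(contrib)[sel], threshold_value = unname(thr),
       q = q, k = k)
}

#' Permutation null for the maximum DAPC contribution
#'
#' Refits the DAPC under `n_perm` random permutations of the group labels
#' (group sizes preserved) and records the maximum per-locus contribution
#' of each null fit. Comparing the observed maximum against this
#' distribution indicates whether the top-ranked loci exceed what label
#' noise alone produces.
#'
#' @param m A `dosage_matrix`.
#' @param n_pcs Retained-PC count passed to [fit_dapc()] (`NULL` for the
#'   variance-target rule).
#' @param q Selection fraction recorded alongside the null (the statistic
#'   itself is the maximum contribution).
#' @param n_perm Number of permutations (0 gives an empty distribution).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_perm` with the per-permutation
#'   maximum contributions.
#' @export
permutation_null <- function(m, n_pcs = NULL, q = 0.025, n_perm = 99,
                             seed = 1L) {
  if (n_perm < 0) stopf("n_perm must be >= 0")
  if (n_perm == 0L) return(numeric(0))
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mp <- m
      mp$groups <- stats::setNames(sample(unname(m$groups)), names(m$groups))
      max(fit_dapc(mp, n_pcs = n_pcs)$contributions)
    }, numeric(1L))
  })
}
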