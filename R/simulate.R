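#' Simulation parameters for truth-known CNV catalogs
#'
#' Defaults emulate the statistical structure of a 20-genome, two-ecotype
#' caribou-style dataset at desk scale: a multi-hundred-Mb multi-scaffold
#' assembly, 500 CNV loci >= 1 kb with deletions heavily outnumbering
#' duplications (del_fraction 0.863 = 1466/1698), a heavy-tailed
#' log-normal length law targeting a ~200 kb mean, half the loci placed
#' inside a handful of wide planted hotspots, Beta-distributed carrier
#' frequencies with mean ~0.355, and 10 divergent loci whose carrier
#' frequency differs by 0.6 between the two groups.
#'
#' @param n_scaffolds Number of scaffolds (used when `scaffold_lengths` is
#'   `NULL`).
#' @param scaffold_lengths Explicit scaffold lengths in bp.
#' @param n_samples_per_group Samples per group (two groups are
#'   generated).
#' @param group_labels Labels of the two groups.
#' @param n_loci Number of CNV loci.
#' @param del_fraction Probability that a locus is a deletion.
#' @param length_meanlog,length_sdlog Log-normal length-law parameters
#'   (bp); the law is truncated to `[1000, scaffold length]`.
#' @param hotspot_count Number of planted hotspot intervals.
#' @param hotspot_width Width of each planted hotspot (bp).
#' @param hotspot_placement_weight Fraction of loci whose midpoints are
#'   drawn inside planted hotspots.
#' @param freq_shape1,freq_shape2 Beta law of the background carrier
#'   frequency (mean `shape1 / (shape1 + shape2)`).
#' @param n_divergent Number of planted group-divergent loci.
#' @param delta_freq Carrier-frequency difference planted at divergent
#'   loci.
#' @param missing_rate Per-genotype missingness probability.
#' @param n_genes Number of simulated gene models.
#' @param seed Integer seed (mandatory; every artifact is a pure function
#'   of the parameters and this seed).
#' @return A named list of class `sim_params`.
#' @export
sim_params <- function(n_scaffolds = 8L,
                       scaffold_lengths = NULL,
                       n_samples_per_group = 10L,
                       group_labels = c("sedentary", "migratory"),
                       n_loci = 500L,
                       del_fraction = 0.863,
                       length_meanlog = log(5e4),
                       length_sdlog = 1.66,
                       hotspot_count = 4L,
                       hotspot_width = 8e6,
                       hotspot_placement_weight = 0.5,
                       freq_shape1 = 2,
                       freq_shape2 = 3.63,
                       n_divergent = 10L,
                       delta_freq = 0.6,
                       missing_rate = 0.02,
                       n_genes = 1000L,
                       seed = 1L) {
  p <- list(n_scaffolds = as.integer(n_scaffolds),
            scaffold_lengths = scaffold_lengths,
            n_samples_per_group = as.integer(n_samples_per_group),
            group_labels = group_labels,
            n_loci = as.integer(n_loci),
            del_fraction = del_fraction,
            length_meanlog = length_meanlog,
            length_sdlog = length_sdlog,
            hotspot_count = as.integer(hotspot_count),
            hotspot_width = hotspot_width,
            hotspot_placement_weight = hotspot_placement_weight,
            freq_shape1 = freq_shape1,
            freq_shape2 = freq_shape2,
            n_divergent = as.integer(n_divergent),
            delta_freq = delta_freq,
            missing_rate = missing_rate,
            n_genes = as.integer(n_genes),
            seed = as.integer(seed))
  for (f in c("del_fraction", "hotspot_placement_weight", "missing_rate",
              "delta_freq")) {
    if (p[[f]] < 0 || p[[f]] > 1) stopf("%s must lie in [0, 1]", f)
  }
  if (p$n_scaffolds < 1L && is.null(p$scaffold_lengths)) {
    stopf("n_scaffolds must be >= 1")
  }
  if (length(p$group_labels) != 2L) stopf("exactly 2 group labels required")
  if (p$n_divergent > p$n_loci) stopf("n_divergent exceeds n_loci")
  class(p) <- "sim_params"
  p
}

# default scaffold length ladder (bp): 1.6 Gb over 8 scaffolds, echoing an
# L90-dominated mammalian assembly where a few large scaffolds carry most bp
default_scaffold_lengths <- function(n) {
  base <- c(400e6, 320e6, 240e6, 200e6, 160e6, 120e6, 100e6, 60e6)
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, rep(50e6, n - length(base)))
}

#' Simulate a genome index
#'
#' @param params A [sim_params()] list.
#' @param seed Optional seed override (defaults to `params$seed`).
#' @return A [genome_index()]; deterministic given parameters and seed.
#' @export
simulate_genome <- function(params = sim_params(), seed = NULL) {
  seed <- seed %||% params$seed
  lens <- params$scaffold_lengths %||%
    default_scaffold_lengths(params$n_scaffolds)
  if (length(lens) == 0L) stopf("simulate_genome: no scaffolds requested")
  genome_index(sprintf("scaf%02d", seq_along(lens)), lens)
}

#' Simulate non-overlapping gene models
#'
#' Genes of 1-50 kb are placed uniformly (probability proportional to
#' scaffold length) without overlap; annotation strings are sampled from a
#' small vocabulary of adaptation-flavoured functional terms so
#' downstream reports look realistic.
#'
#' @param genome A [genome_index()].
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return data.frame of gene models (see [read_gff3()]).
#' @export
simulate_gene_models <- function(genome, n_genes = 1000L, seed = 1L) {
  if (n_genes == 0L) {
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  vocab <- c("muscle contraction", "heart development",
             "regulation of heart rate", "cardiac muscle contraction",
             "musculoskeletal movement", "locomotory behavior",
             "fatty acid metabolism", "response to cold", "response to UV",
             "innate immune response", "defense response to bacterium",
             "skin barrier", "inflammatory response",
             "sensory perception of sound", "visual perception",
             "retina development", "regulation of circadian sleep/wake cycle",
             "social behavior", "regulation of appetite",
             "regulation of protein metabolic process", "")
  with_seed(seed, {
    placed_start <- numeric(0); placed_end <- numeric(0)
    placed_sc <- character(0)
    tries <- 0L
    while (length(placed_start) < n_genes && tries < 50L * n_genes) {
      tries <- tries + 1L
      need <- n_genes - length(placed_start)
      sc_i <- sample.int(length(genome$name), need, replace = TRUE,
                         prob = genome$length)
      len <- round(stats::runif(need, 1e3, 5e4))
      start <- floor(stats::runif(need) * (genome$length[sc_i] - len))
      end <- start + len
      for (j in seq_len(need)) {
        same <- placed_sc == genome$name[sc_i[j]]
        if (!any(same & placed_start < end[j] & placed_end > start[j])) {
          placed_sc <- c(placed_sc, genome$name[sc_i[j]])
          placed_start <- c(placed_start, start[j])
          placed_end <- c(placed_end, end[j])
        }
      }
    }
    if (length(placed_start) < n_genes) {
      stopf("simulate_gene_models: could not place %d non-overlapping genes",
            n_genes)
    }
    ord <- order(match(placed_sc, genome$name), placed_start)
    data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
               scaffold = placed_sc[ord],
               start = placed_start[ord],
               end = placed_end[ord],
               strand = sample(c("+", "-"), n_genes, replace = TRUE),
               annotation = sample(vocab, n_genes, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a genotyped CNV catalog with planted structure
#'
#' Generation steps (all seeded): (i) non-overlapping hotspot intervals
#' are placed on scaffolds wide enough to hold them; (ii) a
#' `hotspot_placement_weight` fraction of locus midpoints is drawn inside
#' hotspots, the rest uniformly over the genome; (iii) each locus is a DEL
#' with probability `del_fraction`, else a DUP; (iv) lengths follow the
#' truncated log-normal law; (v) every locus gets a background carrier
#' frequency from the Beta law, identical in both groups; (vi)
#' `n_divergent` randomly chosen loci get group-specific frequencies
#' `(f, f + delta_freq)` with `f` redrawn from the Beta law truncated so
#' the full difference is achievable; (vii) diploid genotypes are drawn
#' per sample under Hardy-Weinberg from the allele frequency
#' `1 - sqrt(1 - f)` implied by the carrier frequency; (viii) genotypes go
#' missing at `missing_rate`. Loci are re-drawn until every locus has at
#' least two observed carriers (so generated catalogs pass
#' [filter_cnvs()] unchanged) and until every planted divergent locus
#' realizes an observed between-group carrier-frequency difference of at
#' least `delta_freq` — "planted" is a property of the emitted data, not
#' just of the generating law.
#'
#' @param genome A [genome_index()] (typically [simulate_genome()]).
#' @param params A [sim_params()] list.
#' @return List with `table` (a [cnv_table()]) and `truth` (planted
#'   hotspot intervals, divergent locus ids, per-locus group carrier
#'   frequencies).
#' @export
simulate_cnv_catalog <- function(genome, params = sim_params()) {
  p <- params
  with_seed(p$seed, {
    # (i) planted hotspot intervals, non-overlapping, on wide-enough scaffolds
    hot <- place_hotspots(genome, p$hotspot_count, p$hotspot_width)

    # (ii) midpoints
    n <- p$n_loci
    in_hot <- stats::runif(n) < p$hotspot_placement_weight &
      nrow(hot) > 0L
    mid <- numeric(n); sc <- character(n)
    if (any(in_hot)) {
      hi <- sample.int(nrow(hot), sum(in_hot), replace = TRUE)
      mid[in_hot] <- floor(hot$start[hi] +
                             stats::runif(sum(in_hot)) * (hot$end[hi] - hot$start[hi]))
      sc[in_hot] <- hot$scaffold[hi]
    }
    if (any(!in_hot)) {
      sc_i <- sample.int(length(genome$name), sum(!in_hot), replace = TRUE,
                         prob = genome$length)
      mid[!in_hot] <- floor(stats::runif(sum(!in_hot)) * genome$length[sc_i])
      sc[!in_hot] <- genome$name[sc_i]
    }

    # (iii) SV type, (iv) lengths (truncated log-normal, >= 1 kb)
    svtype <- ifelse(stats::runif(n) < p$del_fraction, "DEL", "DUP")
    scaf_len <- genome$length[match(sc, genome$name)]
    len <- numeric(n)
    todo <- rep(TRUE, n)
    while (any(todo)) {
      draw <- round(stats::rlnorm(sum(todo), p$length_meanlog, p$length_sdlog))
      ok <- draw >= 1000 & draw <= scaf_len[todo]
      len[which(todo)[ok]] <- draw[ok]
      todo[which(todo)[ok]] <- FALSE
    }
    start <- pmax(0, pmin(mid - floor(len / 2), scaf_len - len))
    end <- start + len

    # (v)-(vi) carrier frequencies per group; the background law is
    # truncated below at 0.05 because the catalog, by construction, holds
    # only variants segregating in at least two genomes
    f_bg <- stats::rbeta(n, p$freq_shape1, p$freq_shape2)
    while (any(f_bg < 0.05)) {
      f_bg[f_bg < 0.05] <- stats::rbeta(sum(f_bg < 0.05),
                                        p$freq_shape1, p$freq_shape2)
    }
    f1 <- f_bg; f2 <- f_bg
    divergent_idx <- if (p$n_divergent > 0L) sort(sample.int(n, p$n_divergent))
                     else integer(0)
    if (length(divergent_idx) > 0L && p$delta_freq > 0) {
      # base frequency truncated so f + delta stays inside [0, 1]
      hi_cap <- max(1 - p$delta_freq - 0.02, 0.02)
      f_div <- vapply(seq_along(divergent_idx), function(i) {
        repeat {
          f <- stats::rbeta(1L, p$freq_shape1, p$freq_shape2)
          if (f >= 0.05 && f <= hi_cap) return(f)
        }
      }, numeric(1L))
      lo_group <- sample(1:2, length(divergent_idx), replace = TRUE)
      f1[divergent_idx] <- ifelse(lo_group == 1L, f_div,
                                  pmin(1, f_div + p$delta_freq))
      f2[divergent_idx] <- ifelse(lo_group == 1L,
                                  pmin(1, f_div + p$delta_freq), f_div)
    }

    # (vii)-(viii) Hardy-Weinberg genotypes + missingness, conditioned on
    # every locus keeping >= 2 observed carriers
    n_g <- p$n_samples_per_group
    samples <- c(sprintf("%s_%02d", p$group_labels[1L], seq_len(n_g)),
                 sprintf("%s_%02d", p$group_labels[2L], seq_len(n_g)))
    groups <- stats::setNames(rep(p$group_labels, each = n_g), samples)
    geno <- matrix(NA_integer_, n, 2L * n_g)
    draw_block <- function(f, n_samp, n_loci_blk) {
      a <- 1 - sqrt(1 - f) # implied allele frequency
      matrix(stats::rbinom(n_loci_blk * n_samp, 2L, rep(a, n_samp)),
             nrow = n_loci_blk)
    }
    is_div <- seq_len(n) %in% divergent_idx
    redo <- seq_len(n)
    it <- 0L
    while (length(redo) > 0L && it < 500L) {
      it <- it + 1L
      g1 <- draw_block(f1[redo], n_g, length(redo))
      g2 <- draw_block(f2[redo], n_g, length(redo))
      blk <- cbind(g1, g2)
      blk[matrix(stats::runif(length(blk)) < p$missing_rate,
                 nrow = nrow(blk))] <- NA_integer_
      geno[redo, ] <- blk
      carriers <- rowSums(geno[redo, , drop = FALSE] >= 1L, na.rm = TRUE)
      # planted divergent loci are conditioned on actually realizing the
      # planted carrier-frequency difference in the sampled genotypes
      obs1 <- geno[redo, seq_len(n_g), drop = FALSE]
      obs2 <- geno[redo, n_g + seq_len(n_g), drop = FALSE]
      rf1 <- rowSums(obs1 >= 1L, na.rm = TRUE) /
        pmax(rowSums(!is.na(obs1)), 1L)
      rf2 <- rowSums(obs2 >= 1L, na.rm = TRUE) /
        pmax(rowSums(!is.na(obs2)), 1L)
      ok_div <- !is_div[redo] | abs(rf1 - rf2) >= p$delta_freq - 1e-9
      redo <- redo[carriers < 2L | !ok_div]
    }
    if (length(redo) > 0L) {
      stopf("simulate_cnv_catalog: could not realize >= 2 carriers at %d locus/loci (frequencies too low)",
            length(redo))
    }

    ord <- order(match(sc, genome$name), start)
    loci <- data.frame(locus_id = sprintf("cnv%05d", seq_len(n)),
                       scaffold = sc[ord], start = start[ord], end = end[ord],
                       svtype = svtype[ord], stringsAsFactors = FALSE)
    geno <- geno[ord, , drop = FALSE]
    table <- cnv_table(loci, geno, samples, groups = groups)

    div_ids <- loci$locus_id[match(divergent_idx, ord)]
    truth <- list(
      hotspot_intervals = hot,
      divergent_locus_ids = sort(div_ids),
      group_frequencies = data.frame(
        locus_id = loci$locus_id,
        freq_group1 = f1[ord], freq_group2 = f2[ord],
        divergent = loci$locus_id %in% div_ids,
        stringsAsFactors = FALSE))
    list(table = table, truth = truth)
  })
}

# place n non-overlapping hotspot intervals of the given width
place_hotspots <- function(genome, n, width) {
  if (n == 0L) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  eligible <- which(genome$length >= width)
  if (length(eligible) == 0L) {
    stopf("hotspot width %.0f exceeds every scaffold length", width)
  }
  sc <- character(0); st <- numeric(0)
  tries <- 0L
  while (length(sc) < n && tries < 1000L) {
    tries <- tries + 1L
    i <- if (length(eligible) == 1L) eligible else
      sample(eligible, 1L, prob = genome$length[eligible])
    s <- floor(stats::runif(1L) * (genome$length[i] - width))
    same <- sc == genome$name[i]
    if (!any(same & st < s + width & st + width > s)) {
      sc <- c(sc, genome$name[i]); st <- c(st, s)
    }
  }
  if (length(sc) < n) stopf("could not place %d non-overlapping hotspots", n)
  ord <- order(match(sc, genome$name), st)
  data.frame(scaffold = sc[ord], start = st[ord], end = st[ord] + width,
             stringsAsFactors = FALSE)
}

#' Write a complete truth-known fixture bundle
#'
#' Emits, under `out_dir`: `genome.fai` (scaffold lengths), `cnvs.vcf`
#' (svtyper-dialect SV VCF), `genes.gff3`, `groups.tsv` (sample/group)
#' and `truth.json` (planted hotspots, divergent loci, group carrier
#' frequencies). The files parse back through the `sv_io` readers into
#' objects equal to the in-memory originals, and regenerating with the
#' same parameters yields byte-identical files.
#'
#' @param params A [sim_params()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (the five files) and the
#'   in-memory `genome`, `table`, `genes`, `truth` objects.
#' @export
make_fixture_bundle <- function(params = sim_params(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(params)
  sim <- simulate_cnv_catalog(genome, params)
  genes <- simulate_gene_models(genome, params$n_genes,
                                seed = child_seed(params$seed, 2L))
  paths <- list(
    genome = file.path(out_dir, "genome.fai"),
    vcf = file.path(out_dir, "cnvs.vcf"),
    gff3 = file.path(out_dir, "genes.gff3"),
    groups = file.path(out_dir, "groups.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_fai(genome, paths$genome)
  write_sv_vcf(sim$table, genome, paths$vcf)
  write_gff3(genes, paths$gff3, source = "cnvscape_sim")
  writeLines(c("sample\tgroup",
               sprintf("%s\t%s", names(sim$table$groups),
                       unname(sim$table$groups))),
             paths$groups)
  jsonlite::write_json(
    list(hotspot_intervals = sim$truth$hotspot_intervals,
         divergent_locus_ids = sim$truth$divergent_locus_ids,
         group_frequencies = sim$truth$group_frequencies,
         seed = params$seed),
    paths$truth, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, genome = genome, table = sim$table,
                 genes = genes, truth = sim$truth))
}

#' Read a sample -> group table
#'
#' @param path Two-column TSV with header `sample`/`group`.
#' @return Named character vector sample -> group.
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.character(tab$group), tab$sample)
}
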