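#' Assemble a run configuration
#'
#' Collects paths and analysis parameters for the pipeline runners. Every
#' default equals the documented per-module default. Configurations can be
#' seeded from a JSON file; explicitly passed arguments win over file
#' values.
#'
#' @param vcf,genome,gff3,groups Input paths (SV VCF, .fai/TSV scaffold
#'   lengths, GFF3 gene models, sample->group TSV).
#' @param out_dir Output directory.
#' @param min_length,min_carriers Locus filter parameters.
#' @param window,step,hotspot_quantile Sliding-window scan parameters.
#' @param n_pcs,variance_target,q,scale,binarize DAPC parameters
#'   (`n_pcs = NULL` applies the cumulative-variance rule).
#' @param n_perm Label permutations for the DAPC null (0 = skip).
#' @param seed Integer seed for every stochastic step.
#' @param config_file Optional JSON file of the same keys.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(vcf = NULL, genome = NULL, gff3 = NULL, groups = NULL,
                       out_dir = ".",
                       min_length = 1000, min_carriers = 2,
                       window = 2e6, step = 1000, hotspot_quantile = 0.975,
                       n_pcs = NULL, variance_target = 0.875, q = 0.025,
                       scale = FALSE, binarize = FALSE,
                       n_perm = 0L, seed = 1L, config_file = NULL) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    file_cfg <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    explicit <- names(as.list(match.call()))[-1L]
    for (key in setdiff(intersect(names(file_cfg), names(cfg)), explicit)) {
      cfg[[key]] <- file_cfg[[key]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

check_input <- function(path, what) {
  if (is.null(path)) stopf("no %s path configured", what)
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  path
}

load_inputs <- function(config, need_gff3 = FALSE, need_groups = FALSE) {
  genome <- read_genome_index(check_input(config$genome, "genome index"))
  groups <- NULL
  if (!is.null(config$groups)) {
    groups <- read_groups(check_input(config$groups, "groups"))
  } else if (need_groups) {
    stopf("no groups path configured")
  }
  table <- read_sv_vcf(check_input(config$vcf, "VCF"), genome, groups = groups)
  genes <- NULL
  if (!is.null(config$gff3)) {
    genes <- read_gff3(check_input(config$gff3, "GFF3"))
  } else if (need_gff3) {
    stopf("no GFF3 path configured")
  }
  list(genome = genome, table = table, genes = genes)
}

#' Run the catalog characterization pipeline
#'
#' filter -> summarize -> KS spatial-randomness test -> sliding-window
#' hotspot scan -> gene overlap. Writes `characterize.json` (machine
#' readable summary including the echoed configuration), per-sample count
#' and overlap TSVs, and BED files of the filtered CNVs and hotspots into
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the computed objects (`summary`, `ks`,
#'   `hotspots`, `overlap`, `table`).
#' @export
run_characterize <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_inputs(config)
  filtered <- filter_cnvs(inp$table, config$min_length, config$min_carriers)
  summary <- summarize_catalog(filtered, inp$genome)
  ks <- spatial_randomness_test(filtered, inp$genome, seed = config$seed)
  track <- window_counts(filtered, inp$genome,
                         window = config$window, step = config$step)
  hotspots <- detect_hotspots(track, quantile = config$hotspot_quantile,
                              table = filtered)
  overlap <- NULL
  if (!is.null(inp$genes)) {
    overlap <- overlap_cnv_genes(filtered, inp$genes, genome = inp$genome)
  }

  write_bed(data.frame(scaffold = filtered$loci$scaffold,
                       start = filtered$loci$start,
                       end = filtered$loci$end,
                       name = filtered$loci$locus_id,
                       score = filtered$loci$svtype,
                       stringsAsFactors = FALSE),
            file.path(config$out_dir, "cnvs_filtered.bed"), genome = inp$genome)
  if (nrow(hotspots) > 0L) {
    write_bed(data.frame(scaffold = hotspots$scaffold,
                         start = hotspots$start, end = hotspots$end,
                         name = sprintf("hotspot%03d", seq_len(nrow(hotspots))),
                         score = hotspots$n_cnvs, stringsAsFactors = FALSE),
              file.path(config$out_dir, "hotspots.bed"), genome = inp$genome)
  } else {
    file.create(file.path(config$out_dir, "hotspots.bed"))
  }
  psc <- data.frame(sample = names(summary$per_sample_counts),
                    n_cnvs = as.integer(summary$per_sample_counts))
  utils::write.table(psc, file.path(config$out_dir, "per_sample_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(overlap)) {
    utils::write.table(overlap$pairs,
                       file.path(config$out_dir, "cnv_gene_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  json <- list(
    config = config[c("min_length", "min_carriers", "window", "step",
                      "hotspot_quantile", "seed")],
    catalog = unclass(summary)[c("n_total", "n_del", "n_dup", "mean_length",
                                 "mean_per_sample", "min_per_sample",
                                 "max_per_sample", "mean_locus_frequency",
                                 "covered_bp", "coverage_fraction",
                                 "n_scaffolds_with_cnv")],
    length_comparison = if (summary$n_del >= 2L && summary$n_dup >= 2L) {
      lens <- cnv_lengths(filtered)
      length_comparison(lens[filtered$loci$svtype == "DUP"],
                        lens[filtered$loci$svtype == "DEL"])
    },
    spatial = list(ks_D = ks$D, ks_p = ks$p, n_cnv = ks$n_x, n_draws = ks$n_y),
    hotspots = list(n_hotspots = nrow(hotspots),
                    n_cnvs_in_hotspots = sum(hotspots$n_cnvs),
                    mean_cnvs_per_hotspot =
                      if (nrow(hotspots)) mean(hotspots$n_cnvs) else 0,
                    max_cnvs_per_hotspot =
                      if (nrow(hotspots)) max(hotspots$n_cnvs) else 0),
    gene_overlap = if (!is.null(overlap)) {
      overlap[c("n_cnvs_overlapping", "fraction_overlapping",
                "n_distinct_genes", "n_pairs")]
    })
  jsonlite::write_json(json, file.path(config$out_dir, "characterize.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary, ks = ks, hotspots = hotspots,
                 overlap = overlap, table = filtered, track = track))
}

#' Run the DAPC divergence scan
#'
#' encode -> PCA -> retained-PC choice -> discriminant fit ->
#' upper-tail selection, with an optional label-permutation null. Writes
#' per-locus contributions, per-sample discriminant scores, the selected
#' loci (TSV + BED) and `dapc.json` into `out_dir`.
#'
#' @param config A [run_config()] with `vcf`, `genome` and `groups` set.
#' @return Invisibly, a list with `model`, `hits`, `null_max` and the
#'   encoded matrix.
#' @export
run_dapc <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- load_inputs(config, need_groups = TRUE)
  filtered <- filter_cnvs(inp$table, config$min_length, config$min_carriers)
  m <- encode_dosage(filtered, binarize = isTRUE(config$binarize))
  model <- fit_dapc(m, n_pcs = config$n_pcs,
                    variance_target = config$variance_target,
                    scale = isTRUE(config$scale))
  hits <- select_divergent(model, q = config$q)
  null_max <- NULL
  if (config$n_perm > 0L) {
    null_max <- permutation_null(m, n_pcs = config$n_pcs, q = config$q,
                                 n_perm = config$n_perm, seed = config$seed)
    utils::write.table(data.frame(perm = seq_along(null_max),
                                  max_contribution = null_max),
                       file.path(config$out_dir, "dapc_null.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  contrib <- sort(model$contributions, decreasing = TRUE)
  utils::write.table(
    data.frame(locus_id = names(contrib), contribution = contrib,
               selected = names(contrib) %in% hits$locus_ids),
    file.path(config$out_dir, "dapc_contributions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(model$individual_scores),
               group = unname(model$groups[names(model$individual_scores)]),
               score = unname(model$individual_scores)),
    file.path(config$out_dir, "dapc_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- filtered$loci[filtered$loci$locus_id %in% hits$locus_ids, , drop = FALSE]
  write_bed(data.frame(scaffold = sel$scaffold, start = sel$start,
                       end = sel$end, name = sel$locus_id,
                       score = sprintf("%.6g",
                                       model$contributions[sel$locus_id]),
                       stringsAsFactors = FALSE),
            file.path(config$out_dir, "dapc_selected.bed"), genome = inp$genome)

  jsonlite::write_json(
    list(config = config[c("min_length", "min_carriers", "n_pcs",
                           "variance_target", "q", "scale", "binarize",
                           "n_perm", "seed")],
         n_pcs = model$n_pcs,
         cumulative_variance = model$cumulative_variance,
         n_loci = length(model$contributions),
         k_selected = hits$k,
         threshold_value = hits$threshold_value,
         selected_locus_ids = hits$locus_ids,
         null_max_contribution = null_max),
    file.path(config$out_dir, "dapc.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, hits = hits, null_max = null_max, matrix = m))
}

#' Generate a fixture bundle from a configuration
#'
#' Delegates to [make_fixture_bundle()] with [sim_params()] defaults,
#' honouring `config$seed` and `config$out_dir`.
#'
#' @param config A [run_config()]; extra simulation parameters may be
#'   supplied via `params`.
#' @param params Optional [sim_params()] override.
#' @return Invisibly, the [make_fixture_bundle()] result.
#' @export
run_simulate <- function(config, params = NULL) {
  params <- params %||% sim_params(seed = config$seed)
  make_fixture_bundle(params, config$out_dir)
}

#' Summarize pipeline outputs into one report
#'
#' Reads `characterize.json` and/or `dapc.json` from `out_dir` and writes
#' a flat `report.tsv` (one row per statistic).
#'
#' @param config A [run_config()].
#' @return Invisibly, the report data.frame.
#' @export
run_report <- function(config) {
  rows <- list()
  add <- function(section, lst) {
    for (nm in names(lst)) {
      v <- lst[[nm]]
      if (is.null(v) || is.list(v) || length(v) != 1L) next
      rows[[length(rows) + 1L]] <<- data.frame(
        section = section, statistic = nm, value = format(v, digits = 10),
        stringsAsFactors = FALSE)
    }
  }
  found <- FALSE
  cj <- file.path(config$out_dir, "characterize.json")
  if (file.exists(cj)) {
    found <- TRUE
    j <- jsonlite::read_json(cj, simplifyVector = TRUE)
    for (sec in c("catalog", "length_comparison", "spatial", "hotspots",
                  "gene_overlap")) {
      if (!is.null(j[[sec]])) add(sec, j[[sec]])
    }
  }
  dj <- file.path(config$out_dir, "dapc.json")
  if (file.exists(dj)) {
    found <- TRUE
    j <- jsonlite::read_json(dj, simplifyVector = TRUE)
    add("dapc", j[c("n_pcs", "cumulative_variance", "n_loci", "k_selected",
                    "threshold_value")])
  }
  if (!found) stopf("no characterize.json or dapc.json under %s", config$out_dir)
  report <- do.call(rbind, rows)
  utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `characterize`, `dapc`, `report`. Logs go to
#' stderr; machine-readable outputs are written under `--out-dir`.
#' Typically invoked as
#' `Rscript -e 'cnvscape::cli_main()' simulate --out-dir fixtures --seed 7`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   trailing `commandArgs()`).
#' @return Exit status (0 on success), invisibly. Errors raise conditions;
#'   wrap with `tryCatch` or let Rscript translate them to non-zero exits.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("-h", "--help")) {
    message("usage: cnvscape <simulate|characterize|dapc|report> [options]")
    return(invisible(1L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  opts <- list(
    optparse::make_option("--vcf", type = "character", default = NULL),
    optparse::make_option("--genome", type = "character", default = NULL),
    optparse::make_option("--gff3", type = "character", default = NULL),
    optparse::make_option("--groups", type = "character", default = NULL),
    optparse::make_option("--out-dir", type = "character", default = ".",
                          dest = "out_dir"),
    optparse::make_option("--min-length", type = "double", default = 1000,
                          dest = "min_length"),
    optparse::make_option("--min-carriers", type = "integer", default = 2L,
                          dest = "min_carriers"),
    optparse::make_option("--window", type = "double", default = 2e6),
    optparse::make_option("--step", type = "double", default = 1000),
    optparse::make_option("--hotspot-quantile", type = "double",
                          default = 0.975, dest = "hotspot_quantile"),
    optparse::make_option("--n-pcs", type = "integer", default = NULL,
                          dest = "n_pcs"),
    optparse::make_option("--variance-target", type = "double",
                          default = 0.875, dest = "variance_target"),
    optparse::make_option("--q", type = "double", default = 0.025),
    optparse::make_option("--scale", action = "store_true", default = FALSE),
    optparse::make_option("--binarize", action = "store_true",
                          default = FALSE),
    optparse::make_option("--n-perm", type = "integer", default = 0L,
                          dest = "n_perm"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--config", type = "character", default = NULL))
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = rest)
  parsed$help <- NULL
  cfg_file <- parsed$config
  parsed$config <- NULL
  # flags win over config-file values: only keep flags actually supplied
  supplied <- vapply(names(parsed), function(nm) {
    any(startsWith(rest, paste0("--", gsub("_", "-", nm))))
  }, logical(1L))
  cfg <- do.call(run_config, c(parsed[supplied], list(config_file = cfg_file)))
  switch(sub,
         simulate = run_simulate(cfg),
         characterize = run_characterize(cfg),
         dapc = run_dapc(cfg),
         report = run_report(cfg),
         stopf("unknown subcommand '%s'", sub))
  invisible(0L)
}
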