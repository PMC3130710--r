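#' Pipeline configuration
#'
#' Validated configuration for the end-to-end pipeline. Accepts a named
#' list or a YAML file path; unknown keys are rejected so typos cannot
#' silently fall back to defaults. Defaults mirror the emulated study:
#' 34,273 transcript features with 5 animals per group, 500 proteins with 7
#' animals per group measured in two technical iTRAQ replicates, a
#' 205-metabolite panel with 9 animals per group, FDR threshold 0.02.
#'
#' @param x named list of overrides, or path to a YAML file.
#' @return list of class `pipeline_config` with all keys populated.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    fdr_threshold = 0.02,
    n_features_transcript = 34273L,
    n_per_group_transcript = 5L,
    n_proteins = 500L,
    n_per_group_protein = 7L,
    n_metabolites = 205L,
    n_per_group_metabolite = 9L,
    frac_de = 899 / 34273,
    effect_min = 0.5,
    effect_max = 2.5,
    var_prior_df = 4,
    var_prior_scale = 0.05,
    peptides_min = 1L,
    peptides_mean = 6,
    noise_cv = 0.2,
    outlier_fraction = 0.01,
    bias_range = 1.5,
    protein_attenuation = 0.6,
    n_sets = 50L,
    n_planted = 3L,
    planted_excess = 0.5,
    outlier_z = 3,
    mismatch_log2_threshold = 1,
    filter_r2_min = 0.70,
    filter_min_peptides = 2L,
    filter_min_obs = 4L,
    bias_mean = "geometric",
    adjust_bias = TRUE,
    pca_components = 2L,
    pca_z = 3,
    contamination_markers = character(),
    contamination_z = 3
  )
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("configuration error: unknown config keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  cfg$contamination_markers <- as.character(unlist(cfg$contamination_markers))
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold >= 1)
    stop("configuration error: fdr_threshold must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_sim_config <- function(cfg) {
  sim_config(n_proteins = cfg$n_proteins,
             peptides_min = cfg$peptides_min,
             peptides_mean = cfg$peptides_mean,
             noise_cv = cfg$noise_cv,
             outlier_fraction = cfg$outlier_fraction,
             bias_range = cfg$bias_range,
             n_per_group = cfg$n_per_group_protein,
             n_features_transcript = cfg$n_features_transcript,
             n_metabolites = cfg$n_metabolites,
             frac_de = cfg$frac_de,
             effect_min = cfg$effect_min,
             effect_max = cfg$effect_max,
             var_prior_df = cfg$var_prior_df,
             var_prior_scale = cfg$var_prior_scale,
             seed = cfg$seed)
}

pipeline_quant_params <- function(cfg) {
  quant_params(outlier_z = cfg$outlier_z,
               adjust_bias = cfg$adjust_bias,
               bias_mean = cfg$bias_mean,
               filter_r2_min = cfg$filter_r2_min,
               filter_min_peptides = cfg$filter_min_peptides,
               filter_min_obs = cfg$filter_min_obs,
               mismatch_log2_threshold = cfg$mismatch_log2_threshold)
}

#' Simulate a coordinated polyomic study
#'
#' Draws the three layers with linked ground truth: a transcript matrix;
#' a protein cohort whose proteins map to a subset of transcript features
#' and whose true effects are the transcript effects attenuated by
#' `protein_attenuation` (protein-level responses of this magnitude
#' relative to mRNA match the study the generator emulates); a metabolite
#' concentration table; and a gene-set collection over the transcript
#' universe with planted enriched sets.
#'
#' @param cfg a [pipeline_config()].
#' @return list with components `transcript`, `protein` (truth, designs,
#'   runs, symbol map), `metabolite`, `genesets`.
#' @export
simulate_polyomic_study <- function(cfg) {
  sc <- pipeline_sim_config(cfg)
  tx <- simulate_expression_matrix(sc,
                                   n_per_group = cfg$n_per_group_transcript,
                                   seed = cfg$seed)
  tx_ids <- rownames(tx$matrix$values)

  # proteins cover a subset of genes, preferentially including DE genes so
  # the layers share signal (as real proteome coverage of liver enzymes does)
  set.seed(cfg$seed + 7L)
  de_idx <- which(tx$truth$de_flags)
  n_de_prot <- min(length(de_idx), ceiling(cfg$n_proteins / 4))
  gene_idx <- c(sample(de_idx, n_de_prot),
                sample(setdiff(seq_along(tx_ids), de_idx),
                       cfg$n_proteins - n_de_prot))
  prot_effects <- tx$truth$effect_sizes[gene_idx] * cfg$protein_attenuation
  truth <- simulate_protein_truth_from_effects(sc, prot_effects,
                                               seed = cfg$seed + 11L)
  symbol_map <- data.frame(from = truth$protein_ids,
                           to = tx_ids[gene_idx],
                           stringsAsFactors = FALSE)
  designs <- simulate_run_designs(sc, sample_ids = truth$sample_ids,
                                  seed = cfg$seed + 13L)
  runs <- lapply(designs, function(d) simulate_itraq_run(sc, truth, d))

  mets <- simulate_metabolite_table(sc,
                                    n_per_group = cfg$n_per_group_metabolite,
                                    seed = cfg$seed + 17L)
  gs <- simulate_genesets(tx_ids, tx$truth$de_flags,
                          n_sets = cfg$n_sets,
                          n_planted = cfg$n_planted,
                          planted_excess = cfg$planted_excess,
                          seed = cfg$seed + 19L)
  list(transcript = tx,
       protein = list(truth = truth, designs = designs, runs = runs,
                      symbol_map = symbol_map),
       metabolite = mets,
       genesets = gs)
}

#' Protein truth from prescribed effect sizes
#'
#' Variant of [simulate_protein_truth()] used when protein effects must be
#' linked to another layer's truth rather than drawn fresh.
#'
#' @param config a [sim_config()].
#' @param effect_sizes per-protein log2 KO effects (length `n_proteins`).
#' @param seed integer seed.
#' @return a `sim_truth` object.
#' @export
simulate_protein_truth_from_effects <- function(config, effect_sizes,
                                                seed = config$seed) {
  stopifnot(length(effect_sizes) == config$n_proteins)
  truth <- simulate_protein_truth(config, seed = seed)
  truth$effect_sizes <- effect_sizes
  truth$de_flags <- effect_sizes != 0
  lin <- 2^outer(effect_sizes, as.numeric(truth$groups == "KO"))
  lin <- lin / rowMeans(lin)
  l2r <- log2(lin)
  dimnames(l2r) <- dimnames(truth$protein_log2_ratio)
  truth$protein_log2_ratio <- l2r
  truth
}

#' Run the full pipeline on a simulated study
#'
#' Orchestrates every stage: simulation, iTRAQ quantification, sample QC
#' (PCA outliers and marker-based contamination screening, with flagged
#' samples excluded downstream), differential analysis per omic layer,
#' gene-set over-representation of the transcript list, transcript-protein
#' concordance, and a plain-text run report. With `out_dir` set, stage
#' outputs are written as TSV/GMT plus a JSON manifest.
#'
#' @param cfg a [pipeline_config()] (or list/path coercible to one).
#' @return list of class `pipeline_result` with components `sim`, `quant`,
#'   `qc_flags`, `de` (per layer), `enrichment`, `concordance`, `report`
#'   (character lines) and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)

  sim <- simulate_polyomic_study(cfg)
  quant <- quantify_run_set(sim$protein$runs, sim$protein$designs,
                            pipeline_quant_params(cfg))

  prot_groups <- ifelse(grepl("^KO", colnames(quant$log2_matrix)), "KO", "WT")
  prot_vals <- quant$log2_matrix
  complete <- stats::complete.cases(prot_vals)
  prot_em <- expression_matrix(prot_vals[complete, , drop = FALSE],
                               prot_groups, scale_tag = "log2")

  qc_flags <- pca_outlier_flags(prot_em, k = cfg$pca_components,
                                z_threshold = cfg$pca_z)
  if (length(cfg$contamination_markers))
    qc_flags <- qc_flags | contamination_screen(prot_em,
                                                cfg$contamination_markers,
                                                cfg$contamination_z)
  flagged <- names(qc_flags)[qc_flags]
  # mirror the study's QC behavior: flagged animals are omitted downstream
  if (length(flagged)) prot_em <- drop_samples(prot_em, flagged)

  de <- list(
    transcript = run_de(sim$transcript$matrix, cfg$fdr_threshold),
    protein = run_de(prot_em, cfg$fdr_threshold),
    metabolite = run_de(sim$metabolite$matrix, cfg$fdr_threshold)
  )

  tx_sig <- significant_features(de$transcript)$feature_id
  enr <- if (length(tx_sig)) enrich(tx_sig, sim$genesets$collection) else NULL

  conc <- match_features(de$transcript, de$protein,
                         symbol_map = sim$protein$symbol_map)
  conc_stats <- if (conc$n_overlap >= 3L) fold_change_correlation(conc$pairs)
                else NULL

  res <- structure(list(config = cfg, sim = sim, quant = quant,
                        qc_flags = qc_flags, de = de, enrichment = enr,
                        concordance = list(match = conc, stats = conc_stats)),
                   class = "pipeline_result")
  res$report <- pipeline_report(res)
  if (!is.null(cfg$out_dir)) res$manifest <- write_pipeline_outputs(res)
  res
}

#' Render the plain-text run report
#'
#' One section per stage with record counts at each filtering step and the
#' formatted result tables (feature, adjusted p, signed fold change per
#' layer; set frequencies in the sample-vs-background style). The body is
#' deterministic for a fixed config and seed — no timestamps.
#'
#' @param res a `pipeline_result`.
#' @return character vector of report lines.
#' @export
pipeline_report <- function(res) {
  cfg <- res$config
  fmt_de <- function(d, label) {
    sig <- significant_features(d)
    sig <- sig[order(sig$adj_p), , drop = FALSE]
    c(sprintf("[%s] %d features tested, %d significant at FDR < %g",
              label, nrow(d$table), d$n_significant, d$fdr_threshold),
      sprintf("  %-12s %9s %11s", "feature", "adj.p", "fold.change"),
      sprintf("  %-12s %9.2e %11.1f", utils::head(sig$feature_id, 10),
              utils::head(sig$adj_p, 10), utils::head(sig$signed_fc, 10)))
  }
  lines <- c("== pipeline run report ==",
             "",
             "[config]",
             sprintf("  seed=%d fdr_threshold=%g n_proteins=%d noise_cv=%g bias_range=%g",
                     cfg$seed, cfg$fdr_threshold, cfg$n_proteins,
                     cfg$noise_cv, cfg$bias_range),
             "",
             "[simulation]",
             sprintf("  transcripts=%d (KO/WT %d/%d), proteins=%d, metabolites=%d, gene sets=%d",
                     cfg$n_features_transcript, cfg$n_per_group_transcript,
                     cfg$n_per_group_transcript, cfg$n_proteins,
                     cfg$n_metabolites, cfg$n_sets),
             sprintf("  true DE transcripts=%d, true DE proteins=%d",
                     sum(res$sim$transcript$truth$de_flags),
                     sum(res$sim$protein$truth$de_flags)),
             "",
             "[quantification]",
             sprintf("  spectra=%d estimates=%d zero.dropped=%d outliers.removed=%d",
                     res$quant$qc$n_spectra, res$quant$qc$n_estimates,
                     res$quant$qc$n_zero_dropped,
                     res$quant$qc$n_outliers_removed),
             sprintf("  filtered.out=%d mismatch.excluded=%d proteins.quantified=%d",
                     res$quant$qc$n_filtered_out,
                     res$quant$qc$n_mismatch_excluded,
                     res$quant$qc$n_proteins_quantified),
             "",
             "[sample QC]",
             if (any(res$qc_flags))
               sprintf("  flagged and excluded: %s",
                       paste(names(res$qc_flags)[res$qc_flags], collapse = ", "))
             else "  no samples flagged",
             "",
             fmt_de(res$de$transcript, "transcripts"),
             "",
             fmt_de(res$de$protein, "proteins"),
             "",
             fmt_de(res$de$metabolite, "metabolites"),
             "",
             "[enrichment]")
  if (!is.null(res$enrichment)) {
    top <- utils::head(as.data.frame(res$enrichment), 10)
    lines <- c(lines,
               sprintf("  %-8s %9s %9s %9s", "set", "adj.p", "sample%", "backgr%"),
               sprintf("  %-8s %9.2e %8.1f%% %8.1f%%", top$set_id, top$adj_p,
                       top$sample_freq, top$background_freq))
  } else lines <- c(lines, "  (no significant transcripts; enrichment skipped)")
  lines <- c(lines, "", "[concordance]")
  if (!is.null(res$concordance$stats)) {
    s <- res$concordance$stats
    lines <- c(lines,
               sprintf("  %d overlapping genes; Pearson r = %.4f, R^2 = %.4f",
                       s$n, s$pearson_r, s$r_squared))
  } else {
    lines <- c(lines, sprintf("  %d overlapping genes (too few for correlation)",
                              res$concordance$match$n_overlap))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}

write_pipeline_outputs <- function(res) {
  cfg <- res$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  outputs <- character()

  for (i in seq_along(res$sim$protein$runs)) {
    f <- p(sprintf("peptides_%s.tsv", res$sim$protein$designs[[i]]$run_id))
    utils::write.table(res$sim$protein$runs[[i]], f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
  }
  write_expression_tsv(res$sim$transcript$matrix, p("transcripts.tsv"))
  write_expression_tsv(res$sim$metabolite$matrix, p("metabolites.tsv"))
  write_gmt(res$sim$genesets$collection, p("genesets.gmt"))
  utils::write.table(res$quant$composite, p("protein_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (layer in names(res$de)) {
    utils::write.table(res$de[[layer]]$table, p(sprintf("de_%s.tsv", layer)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$enrichment))
    utils::write.table(as.data.frame(res$enrichment), p("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$concordance$match$pairs, p("concordance_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$report, p("report.txt"))
  outputs <- c(outputs, p(c("transcripts.tsv", "metabolites.tsv",
                            "genesets.gmt", "protein_ratios.tsv",
                            "de_transcript.tsv", "de_protein.tsv",
                            "de_metabolite.tsv", "concordance_pairs.tsv",
                            "report.txt")))
  manifest <- list(seed = cfg$seed,
                   config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
                   outputs = basename(outputs))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  manifest
}

#' Command-line entry point
#'
#' Parses CLI arguments and dispatches the pipeline stages. Intended to be
#' invoked through the thin wrapper script shipped at
#' `system.file("cli", "itraqr.R", package = "itraqr")`:
#' `Rscript itraqr.R <subcommand> --config cfg.yml [--out dir] [--seed n]`.
#' Subcommands: `simulate`, `quant`, `de`, `enrich`, `concord`, `report`,
#' `all` (all run the pipeline up to the requested stage; `all` and
#' `report` are equivalent). Exit codes: 0 success, 2 configuration error,
#' 3 data error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (invisibly).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: itraqr.R <simulate|quant|de|enrich|concord|report|all> [--config FILE] [--out DIR] [--seed N]"
  fail <- function(status, msg) {
    message(msg)
    return(invisible(status))
  }
  if (length(args) < 1L) return(fail(2L, usage))
  cmd <- args[[1]]
  if (!cmd %in% c("simulate", "quant", "de", "enrich", "concord",
                  "report", "all"))
    return(fail(2L, paste0("unknown subcommand '", cmd, "'\n", usage)))
  opts <- list(config = NULL, out = NULL, seed = NULL)
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    if (!key %in% names(opts) || i == length(rest))
      return(fail(2L, paste0("bad option '", rest[[i]], "'\n", usage)))
    opts[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  cfg <- tryCatch({
    base <- if (is.null(opts$config)) list() else pipeline_config(opts$config)
    base <- if (is.list(base)) unclass(base) else base
    if (!is.null(opts$seed)) base$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) base$out_dir <- opts$out
    pipeline_config(base)
  }, error = function(e) e)
  if (inherits(cfg, "error")) return(fail(2L, conditionMessage(cfg)))

  message("effective config: ",
          paste(sprintf("%s=%s", names(cfg),
                        vapply(cfg, function(v)
                          paste(format(v), collapse = ","), "")),
                collapse = " "))
  res <- tryCatch(run_pipeline(cfg), error = function(e) e)
  if (inherits(res, "error")) return(fail(3L, conditionMessage(res)))
  writeLines(res$report)
  invisible(0L)
}
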