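#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' object. Defaults emulate the study design the package targets: 8-plex
#' iTRAQ runs (channels 113-119 and 121, channel 113 holding the pooled
#' internal standard), two technical replicate runs per sample with rotated
#' channel assignment, 34,273 transcript features with roughly 2.6% of them
#' differentially expressed, and a 205-metabolite plasma panel.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_min,peptides_mean peptide count per protein is drawn as
#'   `peptides_min + rpois(peptides_mean - peptides_min)`.
#' @param channels character vector of reporter channel labels.
#' @param reference_channel label of the internal-standard channel.
#' @param intensity_meanlog,intensity_sdlog natural-log location and scale of
#'   the lognormal protein-level base intensity (between-protein dynamic
#'   range).
#' @param peptide_sdlog natural-log scale of the within-protein peptide
#'   response spread. Kept moderate (0.35, about a 2-fold spread per SD):
#'   because the through-origin fit weights pairs by intensity, this spread
#'   sets the effective number of peptides behind each ratio, and is
#'   calibrated so that synthetic technical replicates reproduce the
#'   slope-of-1 concordance observed between real replicate runs.
#' @param noise_cv coefficient of variation of multiplicative reporter-ion
#'   noise (0 disables noise).
#' @param outlier_fraction fraction of sample-channel peptide observations
#'   distorted by an aberrant multiplicative factor (drawn log-uniform in
#'   \[3, 10\]).
#' @param bias_range maximal per-channel multiplicative bias; each sample
#'   channel's bias is drawn log-uniform in \[1/bias_range, bias_range\].
#' @param n_per_group animals per group (KO and WT).
#' @param n_features_transcript transcript feature count.
#' @param n_metabolites metabolite feature count (the assayed panel size;
#'   205 by default, configurable because panel definitions vary).
#' @param frac_de fraction of features carrying a true group effect.
#' @param effect_min,effect_max absolute log2 effect sizes of differential
#'   features are drawn uniformly from this interval, with random sign.
#' @param var_prior_df,var_prior_scale prior degrees of freedom and scale of
#'   the scaled inverse-chi-square distribution generating per-feature
#'   residual variances (so the empirical-Bayes prior is recoverable).
#' @param seed integer seed; identical `(config, seed)` gives identical
#'   output from every generator.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 500L,
                       peptides_min = 1L,
                       peptides_mean = 6,
                       channels = c("113", "114", "115", "116",
                                    "117", "118", "119", "121"),
                       reference_channel = "113",
                       intensity_meanlog = log(1e4),
                       intensity_sdlog = 1,
                       peptide_sdlog = 0.35,
                       noise_cv = 0.2,
                       outlier_fraction = 0.01,
                       bias_range = 1.5,
                       n_per_group = 5L,
                       n_features_transcript = 34273L,
                       n_metabolites = 205L,
                       frac_de = 899 / 34273,
                       effect_min = 0.5,
                       effect_max = 2.5,
                       var_prior_df = 4,
                       var_prior_scale = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_min = as.integer(peptides_min),
    peptides_mean = peptides_mean,
    channels = as.character(channels),
    reference_channel = as.character(reference_channel),
    intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog,
    peptide_sdlog = peptide_sdlog,
    noise_cv = noise_cv,
    outlier_fraction = outlier_fraction,
    bias_range = bias_range,
    n_per_group = as.integer(n_per_group),
    n_features_transcript = as.integer(n_features_transcript),
    n_metabolites = as.integer(n_metabolites),
    frac_de = frac_de,
    effect_min = effect_min,
    effect_max = effect_max,
    var_prior_df = var_prior_df,
    var_prior_scale = var_prior_scale,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stop_if(cfg$n_proteins < 1L, "configuration error: n_proteins must be positive")
  stop_if(length(cfg$channels) < 2L, "configuration error: need at least two channels")
  stop_if(anyDuplicated(cfg$channels) > 0L, "configuration error: duplicated channel labels")
  stop_if(!cfg$reference_channel %in% cfg$channels,
          "configuration error: reference channel not among channels")
  for (fr in c("noise_cv", "outlier_fraction", "frac_de")) {
    v <- cfg[[fr]]
    stop_if(!is.finite(v) || v < 0, sprintf("configuration error: %s must be >= 0", fr))
  }
  stop_if(cfg$frac_de > 1, "configuration error: frac_de must be in [0, 1]")
  stop_if(cfg$outlier_fraction > 1, "configuration error: outlier_fraction must be in [0, 1]")
  stop_if(cfg$bias_range < 1, "configuration error: bias_range must be >= 1")
  stop_if(cfg$n_per_group < 2L, "configuration error: n_per_group must be >= 2")
  stop_if(cfg$peptides_min < 1L, "configuration error: peptides_min must be >= 1")
  stop_if(cfg$peptides_mean < cfg$peptides_min,
          "configuration error: peptides_mean must be >= peptides_min")
  stop_if(cfg$var_prior_df <= 0 || cfg$var_prior_scale <= 0,
          "configuration error: variance prior must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("iTRAQ simulation configuration\n")
  cat(sprintf("  proteins: %d (peptides/protein: min %d, mean %.1f)\n",
              x$n_proteins, x$peptides_min, x$peptides_mean))
  cat(sprintf("  channels: %s (reference %s)\n",
              paste(x$channels, collapse = ","), x$reference_channel))
  cat(sprintf("  noise CV %.2f, outlier fraction %.3f, bias range %.2fx\n",
              x$noise_cv, x$outlier_fraction, x$bias_range))
  cat(sprintf("  expression: %d transcripts, %d metabolites, %d/group, frac DE %.4f\n",
              x$n_features_transcript, x$n_metabolites, x$n_per_group, x$frac_de))
  cat(sprintf("  variance prior: d0 = %.1f, s0^2 = %.3f; seed %d\n",
              x$var_prior_df, x$var_prior_scale, x$seed))
  invisible(x)
}
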