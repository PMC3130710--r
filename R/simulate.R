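#' Simulate per-protein ground truth for an iTRAQ experiment
#'
#' Draws the true protein abundance profile of a two-group (KO vs WT) cohort.
#' Differential proteins carry a log2 effect in the knockout group; the
#' internal standard is modeled as the pool of all samples, so the stored
#' truth is each sample's log2 ratio against the pooled mean, the quantity
#' the quantifier estimates.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return a list of class `sim_truth` with elements `protein_ids`,
#'   `sample_ids`, `groups` (factor KO/WT), `protein_log2_ratio`
#'   (proteins x samples matrix of true log2(sample/reference)), `de_flags`
#'   and `effect_sizes`.
#' @export
simulate_protein_truth <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_proteins
  n_samp <- 2L * config$n_per_group
  protein_ids <- sprintf("PROT%04d", seq_len(n))
  sample_ids <- c(sprintf("KO%d", seq_len(config$n_per_group)),
                  sprintf("WT%d", seq_len(config$n_per_group)))
  groups <- factor(rep(c("KO", "WT"), each = config$n_per_group),
                   levels = c("KO", "WT"))

  n_de <- round(config$frac_de * n)
  de_flags <- rep(FALSE, n)
  de_flags[sample.int(n, n_de)] <- TRUE
  effect_sizes <- numeric(n)
  effect_sizes[de_flags] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, config$effect_min, config$effect_max)

  # relative abundance per sample, then re-express against the pooled mean
  rho <- outer(effect_sizes, as.numeric(groups == "KO"))     # log2 scale
  lin <- 2^rho
  lin <- lin / rowMeans(lin)
  l2r <- log2(lin)
  dimnames(l2r) <- list(protein_ids, sample_ids)

  structure(list(protein_ids = protein_ids, sample_ids = sample_ids,
                 groups = groups, protein_log2_ratio = l2r,
                 de_flags = de_flags, effect_sizes = effect_sizes),
            class = "sim_truth")
}

#' Build run designs for a multiplexed two-replicate iTRAQ experiment
#'
#' Samples are packed into runs of `length(channels) - 1` sample channels
#' (the remaining channel holds the pooled internal standard). Every sample
#' is measured in two technical replicate runs; the channel assignment
#' rotates by one position between replicates so that channel bias and
#' sample ratio are separately identifiable. Each run receives its own
#' per-channel bias vector drawn log-uniform in `[1/bias_range, bias_range]`
#' (reference channel bias is fixed at 1).
#'
#' @param config a [sim_config()].
#' @param sample_ids samples to assign (default: all samples of the cohort).
#' @param n_replicates technical replicates per sample (default 2).
#' @param seed integer seed.
#' @return list of run designs; each design is a list with `run_id`,
#'   `replicate_id`, `channel_to_sample` (named character vector),
#'   `reference_channel`, `bias` (named per-channel factors),
#'   `correction_matrix` and `seed`.
#' @export
simulate_run_designs <- function(config,
                                 sample_ids = NULL,
                                 n_replicates = 2L,
                                 seed = config$seed) {
  set.seed(seed)
  if (is.null(sample_ids)) {
    sample_ids <- c(sprintf("KO%d", seq_len(config$n_per_group)),
                    sprintf("WT%d", seq_len(config$n_per_group)))
  }
  sample_channels <- setdiff(config$channels, config$reference_channel)
  n_slot <- length(sample_channels)
  blocks <- split(sample_ids, ceiling(seq_along(sample_ids) / n_slot))

  designs <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (b in seq_along(blocks)) {
      samp <- blocks[[b]]
      # rotate channel slots between replicates
      slots <- sample_channels[((seq_along(samp) + rep_i - 2L) %% n_slot) + 1L]
      c2s <- stats::setNames(samp, slots)
      bias <- stats::setNames(rep(1, length(config$channels)), config$channels)
      lbr <- log(config$bias_range)
      bias[slots] <- exp(stats::runif(length(slots), -lbr, lbr))
      designs[[length(designs) + 1L]] <- list(
        run_id = sprintf("run%d_rep%d", b, rep_i),
        replicate_id = sprintf("rep%d", rep_i),
        channel_to_sample = c2s,
        reference_channel = config$reference_channel,
        bias = bias,
        correction_matrix = diag(length(config$channels)),
        seed = seed + 1000L * rep_i + b
      )
    }
  }
  designs
}

#' Simulate one multiplexed iTRAQ run at the reporter-ion level
#'
#' Generates a peptide-spectrum table for a single run. Each protein
#' contributes a Poisson-shifted number of peptides with lognormal base
#' intensities; the internal-standard channel carries the pooled mean of the
#' true per-sample abundances times multiplicative noise, and each sample
#' channel carries `2^log2_ratio x channel_bias` times that base, times
#' noise, with a configurable fraction of observations distorted by an
#' aberrant factor (log-uniform in \[3, 10\], sample channel only).
#'
#' @param config a [sim_config()].
#' @param truth a [simulate_protein_truth()] result.
#' @param design one run design from [simulate_run_designs()].
#' @param seed integer seed (default `design$seed`).
#' @return a `data.frame` with columns `run_id`, `protein_id`, `peptide_key`
#'   and one intensity column per channel label.
#' @export
simulate_itraq_run <- function(config, truth, design, seed = design$seed) {
  if (config$n_proteins < 1L || length(config$channels) < 2L)
    stop("configuration error: need at least one protein and two channels",
         call. = FALSE)
  if (!all(design$channel_to_sample %in% truth$sample_ids))
    stop("configuration error: design samples missing from truth", call. = FALSE)
  set.seed(seed)

  n <- config$n_proteins
  k <- config$peptides_min +
    stats::rpois(n, max(config$peptides_mean - config$peptides_min, 0))
  total <- sum(k)
  prot <- rep(truth$protein_ids, k)
  pep <- sprintf("%s_pep%02d", prot,
                 unlist(lapply(k, seq_len), use.names = FALSE))
  prot_abund <- stats::rlnorm(n, config$intensity_meanlog,
                              config$intensity_sdlog)
  base <- rep(prot_abund, k) *
    stats::rlnorm(total, 0, config$peptide_sdlog)

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  rnoise <- function(m) {
    if (config$noise_cv == 0) rep(1, m)
    else stats::rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  out <- matrix(0, nrow = total, ncol = length(config$channels),
                dimnames = list(NULL, config$channels))
  # internal standard: pooled mean of true abundances is the base intensity
  out[, design$reference_channel] <- base * rnoise(total)
  rel <- 2^truth$protein_log2_ratio  # proteins x samples, rowMeans == 1
  for (ch in names(design$channel_to_sample)) {
    samp <- design$channel_to_sample[[ch]]
    y <- base * rep(rel[, samp], k) * design$bias[[ch]] * rnoise(total)
    if (config$outlier_fraction > 0) {
      hit <- stats::runif(total) < config$outlier_fraction
      if (any(hit))
        y[hit] <- y[hit] * exp(stats::runif(sum(hit), log(3), log(10)))
    }
    out[, ch] <- y
  }

  df <- data.frame(run_id = design$run_id, protein_id = prot,
                   peptide_key = pep, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(out, check.names = FALSE))
  df
}

#' Simulate a complete two-replicate iTRAQ experiment
#'
#' Convenience wrapper: draws protein truth, builds rotated run designs and
#' simulates every run.
#'
#' @inheritParams simulate_run_designs
#' @return list with `truth`, `designs` and `runs` (list of peptide tables
#'   parallel to `designs`).
#' @export
simulate_itraq_experiment <- function(config, n_replicates = 2L,
                                      seed = config$seed) {
  truth <- simulate_protein_truth(config, seed = seed)
  designs <- simulate_run_designs(config, sample_ids = truth$sample_ids,
                                  n_replicates = n_replicates,
                                  seed = seed + 1L)
  runs <- lapply(designs, function(d) simulate_itraq_run(config, truth, d))
  list(truth = truth, designs = designs, runs = runs)
}

#' Simulate a two-group expression matrix with known truth
#'
#' Log2-scale feature x sample matrix for a KO/WT design. Per-feature
#' residual variances are drawn from a scaled inverse-chi-square
#' distribution with `var_prior_df` degrees of freedom and scale
#' `var_prior_scale`, so the empirical-Bayes variance prior used by the
#' moderated t-test is recoverable from the simulated data.
#'
#' @param config a [sim_config()].
#' @param n_features number of features (default transcript count).
#' @param n_per_group samples per group (default from config).
#' @param feature_prefix prefix for generated feature ids.
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (list: `de_flags`, `effect_sizes`, `variances`).
#' @export
simulate_expression_matrix <- function(config,
                                       n_features = config$n_features_transcript,
                                       n_per_group = config$n_per_group,
                                       feature_prefix = "gene",
                                       seed = config$seed) {
  if (config$frac_de > 1) stop("frac_de must be in [0, 1]", call. = FALSE)
  if (n_per_group < 2L) stop("need at least 2 samples per group", call. = FALSE)
  set.seed(seed)

  feature_ids <- sprintf("%s%05d", feature_prefix, seq_len(n_features))
  sample_ids <- c(sprintf("KO%d", seq_len(n_per_group)),
                  sprintf("WT%d", seq_len(n_per_group)))
  groups <- factor(rep(c("KO", "WT"), each = n_per_group),
                   levels = c("KO", "WT"))

  n_de <- round(config$frac_de * n_features)
  de_flags <- rep(FALSE, n_features)
  if (n_de > 0) de_flags[sample.int(n_features, n_de)] <- TRUE
  effects <- numeric(n_features)
  effects[de_flags] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, config$effect_min, config$effect_max)

  variances <- config$var_prior_df * config$var_prior_scale /
    stats::rchisq(n_features, df = config$var_prior_df)
  baseline <- stats::rnorm(n_features, mean = 7, sd = 1.5)

  mu <- baseline + outer(effects, as.numeric(groups == "KO"))
  noise <- matrix(stats::rnorm(n_features * length(sample_ids)),
                  nrow = n_features) * sqrt(variances)
  vals <- mu + noise
  dimnames(vals) <- list(feature_ids, sample_ids)

  list(matrix = expression_matrix(vals, groups, scale_tag = "log2"),
       truth = list(de_flags = de_flags, effect_sizes = effects,
                    variances = variances))
}

#' Simulate a plasma metabolite concentration table
#'
#' Same two-group generative model as [simulate_expression_matrix()] but on
#' the positive concentration scale (lognormal noise). Specific metabolites
#' can be planted with a chosen log2 effect via `planted`.
#'
#' @inheritParams simulate_expression_matrix
#' @param n_features metabolite panel size (default `config$n_metabolites`).
#' @param n_per_group samples per group; the cohort default is 9.
#' @param planted optional named numeric vector of log2 effects, names
#'   matching generated feature ids (e.g. `c(met00001 = log2(244.3))`).
#' @return list with `matrix` (scale tag `linear-positive`) and `truth`.
#' @export
simulate_metabolite_table <- function(config,
                                      n_features = config$n_metabolites,
                                      n_per_group = 9L,
                                      planted = NULL,
                                      seed = config$seed) {
  if (n_per_group < 2L) stop("need at least 2 samples per group", call. = FALSE)
  set.seed(seed)

  feature_ids <- sprintf("met%05d", seq_len(n_features))
  sample_ids <- c(sprintf("KO%d", seq_len(n_per_group)),
                  sprintf("WT%d", seq_len(n_per_group)))
  groups <- factor(rep(c("KO", "WT"), each = n_per_group),
                   levels = c("KO", "WT"))

  n_de <- round(config$frac_de * n_features)
  de_flags <- rep(FALSE, n_features)
  if (n_de > 0) de_flags[sample.int(n_features, n_de)] <- TRUE
  effects <- numeric(n_features)
  effects[de_flags] <- sample(c(-1, 1), n_de, replace = TRUE) *
    stats::runif(n_de, config$effect_min, config$effect_max)
  if (!is.null(planted)) {
    idx <- match(names(planted), feature_ids)
    if (anyNA(idx)) stop("planted metabolite id not in panel", call. = FALSE)
    effects[idx] <- planted
    de_flags[idx] <- planted != 0
  }

  variances <- config$var_prior_df * config$var_prior_scale /
    stats::rchisq(n_features, df = config$var_prior_df)
  baseline <- stats::rlnorm(n_features, meanlog = log(50), sdlog = 1)

  logmu <- log2(baseline) + outer(effects, as.numeric(groups == "KO"))
  noise <- matrix(stats::rnorm(n_features * length(sample_ids)),
                  nrow = n_features) * sqrt(variances)
  vals <- 2^(logmu + noise)
  dimnames(vals) <- list(feature_ids, sample_ids)

  list(matrix = expression_matrix(vals, groups, scale_tag = "linear-positive"),
       truth = list(de_flags = de_flags, effect_sizes = effects,
                    variances = variances))
}

#' Simulate a gene-set collection with planted over-representation
#'
#' Unplanted sets draw members uniformly from the feature universe. Planted
#' sets draw a stated excess fraction of their members from the
#' differentially expressed features, so their sample frequency k/n exceeds
#' the background frequency K/N by construction.
#'
#' @param feature_ids feature universe.
#' @param de_flags logical vector parallel to `feature_ids`.
#' @param n_sets number of sets.
#' @param set_size_range integer range of set sizes.
#' @param n_planted number of sets planted as enriched.
#' @param planted_excess fraction of a planted set's members drawn from DE
#'   features (0 plants nothing).
#' @param seed integer seed.
#' @return list with `collection` (a [geneset_collection()]) and `truth`
#'   (`enriched_set_ids`).
#' @export
simulate_genesets <- function(feature_ids, de_flags,
                              n_sets = 50L,
                              set_size_range = c(20L, 200L),
                              n_planted = 3L,
                              planted_excess = 0.5,
                              seed = 1L) {
  stopifnot(length(feature_ids) == length(de_flags), n_planted <= n_sets)
  if (planted_excess < 0 || planted_excess > 1)
    stop("planted_excess must be in [0, 1]", call. = FALSE)
  set.seed(seed)

  de_ids <- feature_ids[de_flags]
  set_ids <- sprintf("SET%03d", seq_len(n_sets))
  planted_ids <- if (n_planted > 0) set_ids[seq_len(n_planted)] else character()
  sets <- vector("list", n_sets)
  names(sets) <- set_ids
  for (i in seq_len(n_sets)) {
    m <- sample(seq(set_size_range[1], set_size_range[2]), 1L)
    if (set_ids[i] %in% planted_ids && planted_excess > 0 && length(de_ids)) {
      m_de <- min(round(planted_excess * m), length(de_ids))
      members <- c(sample(de_ids, m_de),
                   sample(setdiff(feature_ids, de_ids), m - m_de))
    } else {
      members <- sample(feature_ids, m)
    }
    sets[[i]] <- sort(members)
  }
  descr <- stats::setNames(sprintf("simulated set %d", seq_len(n_sets)), set_ids)
  list(collection = geneset_collection(sets, universe = feature_ids,
                                       descriptions = descr),
       truth = list(enriched_set_ids = planted_ids))
}
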