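#' Quantifier tuning parameters
#'
#' Bundles the knobs of the iTRAQ quantification pipeline with the defaults
#' used throughout: automated outlier rejection at |standardized residual|
#' > 3 for at most 2 rounds, channel-bias normalization over high-confidence
#' proteins (R^2 > 0.9, >= 3 unique peptides) to a geometric-mean fold
#' change of 1, quality filtering at R^2 > 0.70 with >= 2 unique peptides
#' and >= 4 observations, and exclusion of technical replicates disagreeing
#' by more than 1 log2 unit (a 2-fold mismatch).
#'
#' @param outlier_z standardized-residual cutoff for regression outliers.
#' @param outlier_rounds maximal outlier-removal rounds.
#' @param adjust_bias apply channel-bias adjustment (TRUE) or skip it.
#' @param bias_mean `"geometric"` (default) or `"arithmetic"` mean used to
#'   define the per-channel fold-change center.
#' @param bias_r2_min,bias_min_peptides high-confidence thresholds feeding
#'   the bias estimate.
#' @param filter_r2_min minimum fit R^2 (strict inequality).
#' @param filter_min_peptides,filter_min_obs minimum unique peptides and
#'   observations retained by [filter_estimates()].
#' @param mismatch_log2_threshold |log2(slope_A/slope_B)| above which
#'   technical replicates are flagged as mismatched and excluded.
#' @return a list of class `quant_params`.
#' @export
quant_params <- function(outlier_z = 3,
                         outlier_rounds = 2L,
                         adjust_bias = TRUE,
                         bias_mean = c("geometric", "arithmetic"),
                         bias_r2_min = 0.9,
                         bias_min_peptides = 3L,
                         filter_r2_min = 0.70,
                         filter_min_peptides = 2L,
                         filter_min_obs = 4L,
                         mismatch_log2_threshold = 1) {
  structure(list(outlier_z = outlier_z,
                 outlier_rounds = as.integer(outlier_rounds),
                 adjust_bias = isTRUE(adjust_bias),
                 bias_mean = match.arg(bias_mean),
                 bias_r2_min = bias_r2_min,
                 bias_min_peptides = as.integer(bias_min_peptides),
                 filter_r2_min = filter_r2_min,
                 filter_min_peptides = as.integer(filter_min_peptides),
                 filter_min_obs = as.integer(filter_min_obs),
                 mismatch_log2_threshold = mismatch_log2_threshold),
            class = "quant_params")
}

#' Correct reporter intensities for iTRAQ isotope impurities
#'
#' Each iTRAQ reagent leaks a known fraction of its signal into neighboring
#' reporter masses. With the column-stochastic impurity matrix M (columns =
#' true channel, rows = observed channel), the observed intensities satisfy
#' `M %*% corrected = observed`; this solves that linear system per spectrum
#' and floors negative solutions at zero.
#'
#' @param rows peptide-spectrum `data.frame` with one intensity column per
#'   channel label.
#' @param design run design carrying `correction_matrix` (dimnames = channel
#'   labels) — an identity matrix is a no-op.
#' @return `rows` with corrected intensities.
#' @export
apply_isotope_correction <- function(rows, design) {
  chs <- colnames(design$correction_matrix)
  if (is.null(chs)) {
    chs <- setdiff(names(rows), c("run_id", "protein_id", "peptide_key"))
    if (length(chs) != ncol(design$correction_matrix))
      stop("configuration error: correction matrix does not match channels",
           call. = FALSE)
    dimnames(design$correction_matrix) <- list(chs, chs)
  }
  M <- design$correction_matrix
  if (nrow(M) != ncol(M) || !all(chs %in% names(rows)))
    stop("configuration error: correction matrix does not match channels",
         call. = FALSE)
  if (abs(det(M)) < .Machine$double.eps)
    stop("configuration error: singular correction matrix", call. = FALSE)
  obs <- t(as.matrix(rows[, chs, drop = FALSE]))
  corrected <- solve(M, obs)
  corrected[corrected < 0] <- 0
  rows[, chs] <- t(corrected)
  rows
}

all_channels <- function(design) {
  unique(c(design$reference_channel, names(design$channel_to_sample)))
}

#' Assemble reference/sample intensity pairs for one protein
#'
#' Each quantified spectrum of a protein contributes one x-y pair: x is the
#' internal-standard (reference channel) intensity, y the sample-channel
#' intensity. Pairs with a zero x or y carry no ratio information and are
#' dropped and counted.
#'
#' @param rows peptide-spectrum table of a single run.
#' @param design the run design.
#' @param protein_id protein accession to extract.
#' @param sample_id sample whose channel is regressed against the reference.
#' @return list with `pairs` (`data.frame` of `x`, `y`, `peptide_key`) and
#'   `n_dropped` (zero-intensity exclusions).
#' @export
build_ratio_pairs <- function(rows, design, protein_id, sample_id) {
  idx <- match(sample_id, design$channel_to_sample)
  if (is.na(idx))
    stop(sprintf("unknown sample_id '%s' in run design", sample_id),
         call. = FALSE)
  ch <- names(design$channel_to_sample)[idx]
  sub <- rows[rows$protein_id == protein_id, , drop = FALSE]
  x <- sub[[design$reference_channel]]
  y <- sub[[ch]]
  keep <- x > 0 & y > 0
  list(pairs = data.frame(x = x[keep], y = y[keep],
                          peptide_key = sub$peptide_key[keep],
                          stringsAsFactors = FALSE),
       n_dropped = sum(!keep))
}

#' Protein ratio by least-squares regression through the origin
#'
#' The relative concentration of a protein is the slope of the line through
#' the origin fitted to its reference/sample intensity pairs:
#' `slope = sum(x*y) / sum(x^2)`. Because squared error grows with
#' intensity, high-intensity pairs inherently carry more weight. Fit quality
#' uses the through-origin (uncentered) convention
#' `R^2 = 1 - sum((y - slope*x)^2) / sum(y^2)`, clipped to \[0, 1\]; note
#' this differs from the centered R^2 of an intercept model.
#'
#' @param pairs `data.frame` with columns `x` and `y` (see
#'   [build_ratio_pairs()]).
#' @return list with `slope` and `r_squared`, or `NULL` when no usable pair
#'   exists (no-estimate result).
#' @export
fit_protein_ratio <- function(pairs) {
  pairs <- pairs[pairs$x > 0, , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)
  sxx <- sum(pairs$x^2)
  slope <- sum(pairs$x * pairs$y) / sxx
  syy <- sum(pairs$y^2)
  r2 <- if (syy == 0) 1 else 1 - sum((pairs$y - slope * pairs$x)^2) / syy
  list(slope = slope, r_squared = min(max(r2, 0), 1))
}

#' Iteratively remove regression outliers from a pair set
#'
#' Automates the visual outlier rejection of the interactive workflow: fit
#' the through-origin line, standardize residuals by their root mean square,
#' drop pairs with |standardized residual| > `z`, and refit — for at most
#' `max_rounds` rounds. Nothing is attempted below 4 pairs and removal
#' never leaves fewer than 3 pairs (the worst offenders go first when the
#' guard binds).
#'
#' @param pairs pair `data.frame`.
#' @param z standardized-residual cutoff (default 3).
#' @param max_rounds maximal removal rounds (default 2).
#' @return list with `pairs` (kept) and `removed_count`.
#' @export
remove_regression_outliers <- function(pairs, z = 3, max_rounds = 2L) {
  removed <- 0L
  if (nrow(pairs) < 4L) return(list(pairs = pairs, removed_count = 0L))
  for (round in seq_len(max_rounds)) {
    fit <- fit_protein_ratio(pairs)
    if (is.null(fit)) break
    res <- pairs$y - fit$slope * pairs$x
    rms <- sqrt(mean(res^2))
    if (rms == 0) break
    sr <- abs(res / rms)
    bad <- which(sr > z)
    if (length(bad) == 0L) break
    max_removable <- nrow(pairs) - 3L
    if (max_removable <= 0L) break
    if (length(bad) > max_removable)
      bad <- bad[order(sr[bad], decreasing = TRUE)][seq_len(max_removable)]
    pairs <- pairs[-bad, , drop = FALSE]
    removed <- removed + length(bad)
  }
  list(pairs = pairs, removed_count = removed)
}

#' Quantify every protein in one run
#'
#' Applies isotope correction, then for every (protein, sample channel)
#' builds the x-y pairs, removes regression outliers and fits the
#' through-origin slope, returning one estimate row per combination with
#' its fit metadata.
#'
#' @param rows peptide-spectrum table of the run.
#' @param design the run design.
#' @param params a [quant_params()].
#' @return `data.frame` of per-protein per-sample estimates with columns
#'   `run_id`, `replicate_id`, `channel`, `sample_id`, `protein_id`,
#'   `slope`, `r_squared`, `n_unique_peptides`, `n_observations`,
#'   `max_intensity`, `outliers_removed`, `n_zero_dropped`.
#' @export
quantify_run <- function(rows, design, params = quant_params()) {
  rows <- apply_isotope_correction(rows, design)
  prot_ids <- unique(rows$protein_id)
  chans <- names(design$channel_to_sample)
  by_prot <- split(seq_len(nrow(rows)), rows$protein_id)

  n_out <- length(prot_ids) * length(chans)
  res <- list(protein_id = character(n_out), channel = character(n_out),
              slope = rep(NA_real_, n_out), r_squared = rep(NA_real_, n_out),
              n_unique_peptides = integer(n_out), n_observations = integer(n_out),
              max_intensity = rep(NA_real_, n_out),
              outliers_removed = integer(n_out), n_zero_dropped = integer(n_out))
  i <- 0L
  refch <- design$reference_channel
  for (p in prot_ids) {
    sub <- rows[by_prot[[p]], , drop = FALSE]
    x_all <- sub[[refch]]
    for (ch in chans) {
      i <- i + 1L
      y_all <- sub[[ch]]
      keep <- x_all > 0 & y_all > 0
      pairs <- data.frame(x = x_all[keep], y = y_all[keep],
                          peptide_key = sub$peptide_key[keep],
                          stringsAsFactors = FALSE)
      orm <- remove_regression_outliers(pairs, z = params$outlier_z,
                                        max_rounds = params$outlier_rounds)
      fit <- fit_protein_ratio(orm$pairs)
      res$protein_id[i] <- p
      res$channel[i] <- ch
      res$n_zero_dropped[i] <- sum(!keep)
      res$outliers_removed[i] <- orm$removed_count
      if (!is.null(fit)) {
        res$slope[i] <- fit$slope
        res$r_squared[i] <- fit$r_squared
        res$n_unique_peptides[i] <- length(unique(orm$pairs$peptide_key))
        res$n_observations[i] <- nrow(orm$pairs)
        res$max_intensity[i] <- max(orm$pairs$x, orm$pairs$y)
      }
    }
  }
  est <- as.data.frame(res, stringsAsFactors = FALSE)
  est <- est[!is.na(est$slope), , drop = FALSE]
  est$run_id <- design$run_id
  est$replicate_id <- if (!is.null(design$replicate_id)) design$replicate_id
                      else design$run_id
  est$sample_id <- unname(design$channel_to_sample[est$channel])
  rownames(est) <- NULL
  est[, c("run_id", "replicate_id", "channel", "sample_id", "protein_id",
          "slope", "r_squared", "n_unique_peptides", "n_observations",
          "max_intensity", "outliers_removed", "n_zero_dropped")]
}

#' Adjust reporter-channel bias within each run
#'
#' Labeling efficiency and reporter-ion response differ between channels,
#' shifting every ratio of a channel by a common factor. Within each run,
#' the factor is estimated as the (geometric, by default) mean slope of the
#' high-confidence proteins of that channel (R^2 above `bias_r2_min` and at
#' least `bias_min_peptides` unique peptides) and divided out, so that the
#' post-adjustment mean fold change of those proteins is exactly 1. The
#' operation is idempotent. A channel with no high-confidence protein keeps
#' factor 1 with a warning.
#'
#' @param estimates estimate table from [quantify_run()] (one or more runs).
#' @param params a [quant_params()].
#' @return list with `estimates` (slopes divided by their channel factor)
#'   and `bias_factors` (`data.frame`: run_id, channel, sample_id, bias,
#'   n_high_confidence).
#' @export
adjust_channel_bias <- function(estimates, params = quant_params()) {
  key <- interaction(estimates$run_id, estimates$channel, drop = TRUE)
  groups <- split(seq_len(nrow(estimates)), key)
  bias_rows <- vector("list", length(groups))
  adj <- estimates
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    hi <- idx[estimates$r_squared[idx] > params$bias_r2_min &
              estimates$n_unique_peptides[idx] >= params$bias_min_peptides]
    if (length(hi) == 0L) {
      warning(sprintf("no high-confidence proteins in run %s channel %s; bias factor 1",
                      estimates$run_id[idx[1]], estimates$channel[idx[1]]))
      b <- 1
    } else if (params$bias_mean == "geometric") {
      b <- exp(mean(log(estimates$slope[hi])))
    } else {
      b <- mean(estimates$slope[hi])
    }
    adj$slope[idx] <- estimates$slope[idx] / b
    bias_rows[[g]] <- data.frame(run_id = estimates$run_id[idx[1]],
                                 channel = estimates$channel[idx[1]],
                                 sample_id = estimates$sample_id[idx[1]],
                                 bias = b, n_high_confidence = length(hi),
                                 stringsAsFactors = FALSE)
  }
  list(estimates = adj, bias_factors = do.call(rbind, bias_rows))
}

#' Filter protein estimates on fit quality and evidence depth
#'
#' Keeps estimates with R^2 strictly above `filter_r2_min` (a boundary R^2
#' equal to the threshold is rejected), at least `filter_min_peptides`
#' unique peptides and at least `filter_min_obs` observations.
#'
#' @inheritParams adjust_channel_bias
#' @return the retained subset of `estimates`.
#' @export
filter_estimates <- function(estimates, params = quant_params()) {
  keep <- estimates$r_squared > params$filter_r2_min &
    estimates$n_unique_peptides >= params$filter_min_peptides &
    estimates$n_observations >= params$filter_min_obs
  estimates[keep, , drop = FALSE]
}

#' Composite technical replicates into one ratio per protein and sample
#'
#' When both replicate runs yield a (bias-adjusted, filtered) ratio, the
#' composite is their geometric mean; when only one does, the single value
#' is used. Replicates disagreeing by more than `mismatch_log2_threshold`
#' log2 units are flagged as mismatched and excluded from downstream
#' differential analysis.
#'
#' @param replicate_a,replicate_b estimate tables of the two technical
#'   replicates (same columns as [quantify_run()] output).
#' @param mismatch_log2_threshold |log2(slope_A/slope_B)| cutoff (default 1).
#' @return `data.frame` with `protein_id`, `sample_id`, `ratio`, `source`
#'   (`both-replicates` / `single-replicate`) and `mismatch_flag`.
#' @export
composite_ratios <- function(replicate_a, replicate_b,
                             mismatch_log2_threshold = 1) {
  key <- function(e) paste(e$protein_id, e$sample_id, sep = "\r")
  for (e in list(replicate_a, replicate_b)) {
    if (nrow(e) && anyDuplicated(paste(key(e), e$run_id)) > 0L)
      stop("duplicate (protein, sample, run) estimates; aggregate upstream",
           call. = FALSE)
    if (nrow(e) && anyDuplicated(key(e)) > 0L)
      stop("duplicate (protein, sample) estimates within a replicate",
           call. = FALSE)
  }
  ka <- key(replicate_a); kb <- key(replicate_b)
  all_keys <- union(ka, kb)
  ia <- match(all_keys, ka); ib <- match(all_keys, kb)
  sa <- replicate_a$slope[ia]; sb <- replicate_b$slope[ib]
  both <- !is.na(sa) & !is.na(sb)
  ratio <- ifelse(both, sqrt(sa * sb), ifelse(is.na(sa), sb, sa))
  mism <- both & abs(log2(sa / sb)) > mismatch_log2_threshold
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  data.frame(protein_id = vapply(parts, `[[`, "", 1L),
             sample_id = vapply(parts, `[[`, "", 2L),
             ratio = ratio,
             source = ifelse(both, "both-replicates", "single-replicate"),
             mismatch_flag = mism,
             stringsAsFactors = FALSE)
}

#' Quantify a full set of iTRAQ runs into a protein ratio matrix
#'
#' End-to-end quantification: isotope correction and per-run regression
#' ([quantify_run()]), channel-bias adjustment ([adjust_channel_bias()]),
#' quality filtering ([filter_estimates()]) and technical-replicate
#' compositing ([composite_ratios()]), returning the log2 composite ratio
#' matrix (proteins x samples) together with the intermediate tables and a
#' QC report of counts at each stage.
#'
#' @param runs list of peptide-spectrum tables.
#' @param designs list of run designs parallel to `runs`.
#' @param params a [quant_params()].
#' @return object of class `itraq_quant`: list with `log2_matrix`,
#'   `composite`, `estimates` (bias-adjusted, pre-filter), `bias_factors`
#'   and `qc` (named counts).
#' @export
quantify_run_set <- function(runs, designs, params = quant_params()) {
  stopifnot(length(runs) == length(designs))
  if (length(runs) == 0L || all(vapply(runs, nrow, 0L) == 0L)) {
    warning("empty input: no peptide spectra to quantify")
    return(structure(list(log2_matrix = matrix(numeric(), 0, 0),
                          composite = NULL, estimates = NULL,
                          bias_factors = NULL,
                          qc = list(n_spectra = 0L)), class = "itraq_quant"))
  }
  est <- do.call(rbind, lapply(seq_along(runs), function(i)
    quantify_run(runs[[i]], designs[[i]], params)))
  qc <- list(n_spectra = sum(vapply(runs, nrow, 0L)),
             n_estimates = nrow(est),
             n_zero_dropped = sum(est$n_zero_dropped),
             n_outliers_removed = sum(est$outliers_removed))

  if (params$adjust_bias) {
    ba <- adjust_channel_bias(est, params)
    est <- ba$estimates
    bias_factors <- ba$bias_factors
  } else {
    bias_factors <- NULL
  }

  kept <- filter_estimates(est, params)
  qc$n_filtered_out <- nrow(est) - nrow(kept)

  reps <- sort(unique(kept$replicate_id))
  if (length(reps) > 2L)
    stop("more than two technical replicates are not supported", call. = FALSE)
  if (length(reps) == 2L) {
    comp <- composite_ratios(kept[kept$replicate_id == reps[1], ],
                             kept[kept$replicate_id == reps[2], ],
                             params$mismatch_log2_threshold)
  } else {
    comp <- composite_ratios(kept, kept[0, ], params$mismatch_log2_threshold)
  }
  qc$n_mismatch_excluded <- sum(comp$mismatch_flag)

  ok <- comp[!comp$mismatch_flag, , drop = FALSE]
  prots <- sort(unique(ok$protein_id))
  samps <- unique(unlist(lapply(designs, function(d)
    unname(d$channel_to_sample))))
  m <- matrix(NA_real_, length(prots), length(samps),
              dimnames = list(prots, samps))
  m[cbind(match(ok$protein_id, prots), match(ok$sample_id, samps))] <-
    log2(ok$ratio)
  qc$n_proteins_quantified <- length(prots)

  structure(list(log2_matrix = m, composite = comp, estimates = est,
                 bias_factors = bias_factors, qc = qc),
            class = "itraq_quant")
}

#' @export
print.itraq_quant <- function(x, ...) {
  cat("iTRAQ quantification result\n")
  cat(sprintf("  %d spectra -> %d protein/sample estimates -> %d proteins x %d samples\n",
              x$qc$n_spectra, x$qc$n_estimates %||% 0L,
              nrow(x$log2_matrix), ncol(x$log2_matrix)))
  cat(sprintf("  zero-intensity pairs dropped: %d; regression outliers removed: %d\n",
              x$qc$n_zero_dropped %||% 0L, x$qc$n_outliers_removed %||% 0L))
  cat(sprintf("  estimates failing QC filter: %d; replicate mismatches excluded: %d\n",
              x$qc$n_filtered_out %||% 0L, x$qc$n_mismatch_excluded %||% 0L))
  invisible(x)
}

#' @export
summary.itraq_quant <- function(object, ...) {
  print(object)
  if (!is.null(object$bias_factors)) {
    cat("  channel bias factors:\n")
    bf <- object$bias_factors
    for (r in unique(bf$run_id))
      cat(sprintf("    %s: %s\n", r,
                  paste(sprintf("%s=%.3f", bf$channel[bf$run_id == r],
                                bf$bias[bf$run_id == r]), collapse = " ")))
  }
  invisible(object)
}

#' Extract the log2 ratio matrix of a quantification result
#'
#' @param object an `itraq_quant` object.
#' @param ... unused.
#' @return numeric matrix of log2 composite ratios (proteins x samples).
#' @export
coef.itraq_quant <- function(object, ...) object$log2_matrix

`%||%` <- function(a, b) if (is.null(a)) b else a
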