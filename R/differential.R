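#' Per-feature two-group summary statistics
#'
#' Group means, pooled within-group variance and residual degrees of
#' freedom for every feature of a KO/WT expression matrix. Matrices tagged
#' `linear-positive` are log2-transformed first with a positive floor
#' (default: half the smallest positive value) so zeros cannot produce
#' infinities; analysis is always on the log2 scale.
#'
#' @param em an [expression_matrix()].
#' @param floor optional positive floor applied before the log2 transform
#'   of a linear-positive matrix.
#' @return `data.frame` with `feature_id`, `mean_ko`, `mean_wt`, `s2`
#'   (pooled variance) and `df` (residual degrees of freedom,
#'   `n_ko + n_wt - 2`).
#' @export
group_stats <- function(em, floor = NULL) {
  ko <- em$groups == "KO"
  wt <- em$groups == "WT"
  if (sum(ko) < 2L || sum(wt) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  vals <- em$values
  if (em$scale_tag == "linear-positive") {
    if (is.null(floor)) {
      pos <- vals[vals > 0]
      floor <- min(pos) / 2
    }
    vals <- log2(pmax(vals, floor))
  }
  m_ko <- rowMeans(vals[, ko, drop = FALSE])
  m_wt <- rowMeans(vals[, wt, drop = FALSE])
  ss_ko <- rowSums((vals[, ko, drop = FALSE] - m_ko)^2)
  ss_wt <- rowSums((vals[, wt, drop = FALSE] - m_wt)^2)
  df <- sum(ko) + sum(wt) - 2L
  data.frame(feature_id = rownames(vals),
             mean_ko = m_ko, mean_wt = m_wt,
             s2 = (ss_ko + ss_wt) / df,
             df = df, n_ko = sum(ko), n_wt = sum(wt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Newton inversion of the trigamma function
#' @noRd
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior across features
#'
#' Method-of-moments estimation of the scaled inverse-chi-square prior
#' (d0, s0^2) for feature variances: under the hierarchical model the
#' log sample variances follow a scaled log-F distribution whose mean and
#' variance involve digamma/trigamma terms, so matching the empirical
#' moments of `log(s2)` recovers the prior. When the empirical spread of
#' `log(s2)` does not exceed the sampling floor `trigamma(df/2)`, the
#' variances are consistent with a common value: d0 is infinite and s0^2
#' is the mean variance.
#'
#' @param s2 per-feature sample variances.
#' @param df residual degrees of freedom (scalar or per-feature; must be
#'   constant across features).
#' @param min_features minimum number of positive variances required.
#' @return list of class `eb_prior` with `d0` and `s0_sq`.
#' @export
estimate_eb_prior <- function(s2, df, min_features = 50L) {
  df <- unique(df)
  if (length(df) != 1L)
    stop("varying residual df across features is not supported", call. = FALSE)
  if (all(s2 == 0)) stop("degenerate input: all variances are zero",
                         call. = FALSE)
  pos <- s2 > 0
  if (sum(pos) < min_features)
    stop(sprintf("need at least %d features with positive variance",
                 min_features), call. = FALSE)
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2[pos])
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf("empirical-Bayes variance prior: d0 = %s, s0^2 = %.5g\n",
              format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-test
#'
#' Shrinks each feature's variance toward the prior,
#' `s2_post = (d0*s0^2 + df*s2) / (d0 + df)`, and tests the KO-WT mean
#' difference with `t = diff / (s_post * sqrt(1/n_ko + 1/n_wt))` on
#' `df + d0` degrees of freedom (a normal reference when d0 is infinite).
#'
#' @param stats a [group_stats()] table.
#' @param prior an [estimate_eb_prior()] result (or list with `d0`,
#'   `s0_sq`).
#' @return `stats` with added `t_mod`, `df_total` and `p_value` columns.
#' @export
moderated_t_test <- function(stats, prior) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(stats))
             else (d0 * s0 + stats$df * stats$s2) / (d0 + stats$df)
  se <- sqrt(s2_post * (1 / stats$n_ko + 1 / stats$n_wt))
  t_mod <- (stats$mean_ko - stats$mean_wt) / se
  df_total <- stats$df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  out <- stats
  out$t_mod <- t_mod
  out$df_total <- df_total
  out$p_value <- p
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement (delegating to
#' `stats::p.adjust(method = "BH")` after validating the input).
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, elementwise in \[p, 1\].
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change from log2 group means
#'
#' Reports the KO/WT ratio `r = 2^(mean_ko - mean_wt)` in the signed
#' display convention: `r` when `r >= 1`, `-1/r` otherwise, so a value of
#' -10.2 means 10.2-fold lower in the knockout and |signed_fc| >= 1 always.
#'
#' @param mean_ko,mean_wt log2-scale group means (vectorized).
#' @return signed fold changes.
#' @export
signed_fold_change <- function(mean_ko, mean_wt) {
  r <- 2^(mean_ko - mean_wt)
  ifelse(r >= 1, r, -1 / r)
}

#' Two-group differential analysis with moderated t and FDR control
#'
#' The uniform differential stage applied to every omic layer: group
#' statistics on the log2 scale, empirical-Bayes variance prior across all
#' features, moderated t-test, BH adjustment, and signed fold changes from
#' the group means. Features with adjusted p below `fdr_threshold`
#' (default 0.02) form the significant subset; the full table is always
#' returned.
#'
#' @param em an [expression_matrix()].
#' @param fdr_threshold FDR significance cutoff.
#' @param prior optional prior override (list with `d0`, `s0_sq`); estimated
#'   from the data when `NULL`.
#' @param floor see [group_stats()].
#' @return object of class `de_result`: list with `table` (one `DERecord`
#'   row per feature: means, `signed_fc`, `t_mod`, `df_total`, `p_value`,
#'   `adj_p`, `significant`), `prior`, `fdr_threshold` and `n_significant`.
#' @export
run_de <- function(em, fdr_threshold = 0.02, prior = NULL, floor = NULL) {
  if (nrow(em$values) == 0L) {
    empty <- data.frame(feature_id = character(), mean_ko = numeric(),
                        mean_wt = numeric(), s2 = numeric(), df = numeric(),
                        n_ko = integer(), n_wt = integer(), t_mod = numeric(),
                        df_total = numeric(), p_value = numeric(),
                        signed_fc = numeric(), adj_p = numeric(),
                        significant = logical())
    return(structure(list(table = empty, prior = prior,
                          fdr_threshold = fdr_threshold, n_significant = 0L),
                     class = "de_result"))
  }
  st <- group_stats(em, floor = floor)
  if (is.null(prior)) prior <- estimate_eb_prior(st$s2, st$df)
  tt <- moderated_t_test(st, prior)
  tt$signed_fc <- signed_fold_change(tt$mean_ko, tt$mean_wt)
  tt$adj_p <- bh_adjust(tt$p_value)
  tt$significant <- tt$adj_p < fdr_threshold
  structure(list(table = tt, prior = prior, fdr_threshold = fdr_threshold,
                 n_significant = sum(tt$significant)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("differential analysis: %d features, %d significant at FDR < %.3g\n",
              nrow(x$table), x$n_significant, x$fdr_threshold))
  if (!is.null(x$prior))
    cat(sprintf("  variance prior: d0 = %s, s0^2 = %.5g\n",
                format(x$prior$d0, digits = 4), x$prior$s0_sq))
  invisible(x)
}

#' @export
summary.de_result <- function(object, n = 10L, ...) {
  print(object)
  tab <- significant_features(object)
  if (nrow(tab)) {
    tab <- tab[order(tab$adj_p), c("feature_id", "adj_p", "signed_fc")]
    cat(sprintf("  top %d by adjusted p:\n", min(n, nrow(tab))))
    print(utils::head(tab, n), row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Significant subset of a differential result
#'
#' @param x a `de_result`.
#' @return the rows of the result table passing the FDR threshold.
#' @export
significant_features <- function(x) {
  stopifnot(inherits(x, "de_result"))
  x$table[x$table$significant, , drop = FALSE]
}

#' Flag outlier samples by principal component scores
#'
#' PCA on centered, feature-standardized data (constant features dropped);
#' a sample is flagged when its score on any of the first `k` components
#' lies more than `z_threshold` robust standard deviations
#' (1.4826 * MAD) from that component's median, so the flagging is not
#' driven by the outlier itself.
#'
#' @param em an [expression_matrix()].
#' @param k number of leading components to inspect (default 2).
#' @param z_threshold robust-SD cutoff (default 3).
#' @return named logical vector, one flag per sample.
#' @export
pca_outlier_flags <- function(em, k = 2L, z_threshold = 3) {
  n_samp <- ncol(em$values)
  if (n_samp < k)
    stop("fewer samples than requested components", call. = FALSE)
  vals <- em$values
  if (em$scale_tag == "linear-positive") {
    pos <- vals[vals > 0]
    vals <- log2(pmax(vals, min(pos) / 2))
  }
  sds <- apply(vals, 1L, stats::sd)
  vals <- vals[sds > 0, , drop = FALSE]
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = TRUE)
  k <- min(k, ncol(pc$x))
  flags <- rep(FALSE, n_samp)
  for (j in seq_len(k)) {
    sc <- pc$x[, j]
    rsd <- stats::mad(sc)
    if (rsd == 0) next
    flags <- flags | abs(sc - stats::median(sc)) > z_threshold * rsd
  }
  stats::setNames(flags, colnames(em$values))
}

#' Screen samples for contamination via marker proteins
#'
#' Flags samples whose mean abundance over the marker features (e.g.
#' hemoglobin subunits, indicating blood contamination of a liver sample)
#' exceeds the cohort mean by more than `z_threshold` standard deviations.
#' Markers absent from the matrix are skipped with a warning.
#'
#' @param em an [expression_matrix()] (protein layer).
#' @param marker_ids feature ids of the contamination markers.
#' @param z_threshold SD cutoff above the cohort mean (default 3).
#' @return named logical vector, one flag per sample.
#' @export
contamination_screen <- function(em, marker_ids, z_threshold = 3) {
  present <- marker_ids %in% rownames(em$values)
  if (any(!present))
    warning(sprintf("markers absent from matrix and skipped: %s",
                    paste(marker_ids[!present], collapse = ", ")))
  marker_ids <- marker_ids[present]
  flags <- stats::setNames(rep(FALSE, ncol(em$values)), colnames(em$values))
  if (length(marker_ids) == 0L) return(flags)
  vals <- em$values
  if (em$scale_tag == "linear-positive") {
    pos <- vals[vals > 0]
    vals <- log2(pmax(vals, min(pos) / 2))
  }
  score <- colMeans(vals[marker_ids, , drop = FALSE])
  sdev <- stats::sd(score)
  if (is.na(sdev) || sdev == 0) return(flags)
  flags | (score - mean(score)) / sdev > z_threshold
}
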