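#' Match differential features across two omic layers
#'
#' Pairs the significant transcript and protein lists by gene symbol
#' (case-insensitive), optionally routing protein accessions through a
#' two-column symbol map. When several records of a layer map to the same
#' symbol, the representative with the largest |moderated t| is kept and
#' the collapse is reported.
#'
#' @param de_mrna,de_protein `de_result` objects or data.frames with
#'   columns `feature_id`, `signed_fc` and (optionally) `t_mod`.
#' @param symbol_map optional `data.frame` with columns `from`, `to`
#'   mapping protein feature ids to gene symbols.
#' @return list with `pairs` (`data.frame`: `gene_symbol`, `fc_mrna`,
#'   `fc_protein`, `l_mrna`, `l_protein`), `n_overlap` and `n_collapsed`.
#' @export
match_features <- function(de_mrna, de_protein, symbol_map = NULL) {
  tab <- function(x) {
    if (inherits(x, "de_result")) significant_features(x) else x
  }
  a <- tab(de_mrna); b <- tab(de_protein)
  if (!is.null(symbol_map)) {
    idx <- match(toupper(b$feature_id), toupper(symbol_map$from))
    b$feature_id <- ifelse(is.na(idx), b$feature_id, symbol_map$to[idx])
  }
  dedupe <- function(d) {
    d$symbol <- toupper(d$feature_id)
    if (is.null(d$t_mod)) d$t_mod <- rep(Inf, nrow(d))
    d <- d[order(d$symbol, -abs(d$t_mod)), , drop = FALSE]
    dup <- duplicated(d$symbol)
    list(d = d[!dup, , drop = FALSE], n_collapsed = sum(dup))
  }
  da <- dedupe(a); db <- dedupe(b)
  common <- intersect(da$d$symbol, db$d$symbol)
  ia <- match(common, da$d$symbol); ib <- match(common, db$d$symbol)
  fc_m <- da$d$signed_fc[ia]; fc_p <- db$d$signed_fc[ib]
  pairs <- data.frame(gene_symbol = da$d$feature_id[ia],
                      fc_mrna = fc_m, fc_protein = fc_p,
                      l_mrna = signed_log2(fc_m),
                      l_protein = signed_log2(fc_p),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, n_overlap = nrow(pairs),
       n_collapsed = da$n_collapsed + db$n_collapsed)
}

#' Signed-log2 transform of a signed fold change
#'
#' Maps the signed fold-change convention (|fc| >= 1, sign = direction)
#' back to the continuous log2 scale: `sign(fc) * log2(|fc|)`. The signed
#' fold-change scale has a jump discontinuity at +/-1 that would distort a
#' linear correlation; the transform removes it.
#'
#' @param fc signed fold changes.
#' @return log2-scale effects.
#' @export
signed_log2 <- function(fc) sign(fc) * log2(abs(fc))

#' Transcript-protein fold-change concordance
#'
#' Pearson correlation between the signed-log2 fold changes of the two
#' layers over matched genes; both r and r^2 are reported.
#'
#' @param pairs pair `data.frame` from [match_features()] (needs `l_mrna`
#'   and `l_protein`, or `fc_mrna`/`fc_protein` from which they are
#'   derived).
#' @return list with `pearson_r`, `r_squared` and `n`.
#' @export
fold_change_correlation <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs))
    pairs <- pairs$pairs
  if (is.null(pairs$l_mrna)) pairs$l_mrna <- signed_log2(pairs$fc_mrna)
  if (is.null(pairs$l_protein)) pairs$l_protein <- signed_log2(pairs$fc_protein)
  if (nrow(pairs) < 3L)
    stop("insufficient data: need at least 3 matched pairs", call. = FALSE)
  r <- stats::cor(pairs$l_mrna, pairs$l_protein)
  list(pearson_r = r, r_squared = r^2, n = nrow(pairs))
}
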