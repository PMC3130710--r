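#' Sample and background frequencies of a gene set
#'
#' Counts the over-representation contingency quantities for one set: k =
#' differential features in the set, n = size of the differential list,
#' K = set members in the background universe, N = universe size, and the
#' two frequencies reported as percentages to one decimal (sample k/n,
#' background K/N). Differential ids missing from the universe are dropped
#' with a warning and counted (the background defines the sampling frame).
#'
#' @param de_ids differential feature ids (the sample list).
#' @param set_members member ids of the set.
#' @param universe background feature ids.
#' @return list with `k`, `n`, `K`, `N`, `sample_freq`, `background_freq`
#'   (percent, one decimal) and `n_dropped`.
#' @export
annotate_frequencies <- function(de_ids, set_members, universe) {
  de_ids <- unique(de_ids)
  in_univ <- de_ids %in% universe
  n_dropped <- sum(!in_univ)
  if (n_dropped > 0L) {
    warning(sprintf("%d differential ids outside the universe dropped",
                    n_dropped))
    de_ids <- de_ids[in_univ]
  }
  n <- length(de_ids)
  if (n == 0L) stop("empty differential list", call. = FALSE)
  members <- unique(set_members[set_members %in% universe])
  k <- sum(de_ids %in% members)
  K <- length(members)
  N <- length(unique(universe))
  list(k = k, n = n, K = K, N = N,
       sample_freq = round(100 * k / n, 1),
       background_freq = round(100 * K / N, 1),
       n_dropped = n_dropped)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for X hypergeometric with `K`
#' successes in a universe of `N`, drawing `n`: the chance that a random
#' differential list of size n would hit the set at least k times.
#' Computed via the log-space-stable distribution function.
#'
#' @param k observed differential members of the set.
#' @param n differential list size.
#' @param K set size in the universe.
#' @param N universe size.
#' @return the one-sided enrichment p-value.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 1 || k > n || n > N || k > K || K > N)
    stop("inconsistent counts: need k <= min(n, K) and n, K <= N",
         call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Scores every set of the collection against a differential feature list:
#' frequency annotation, one-sided hypergeometric p-value and BH adjustment
#' across the collection, returned sorted by adjusted p (ties broken by raw
#' p). Invoke once per omic layer (e.g. the transcript and protein lists
#' separately).
#'
#' @param de_ids differential feature ids.
#' @param collection a [geneset_collection()].
#' @return `data.frame` of class `enrichment_result`, one row per set:
#'   `set_id`, `name`, `k`, `n`, `K`, `N`, `sample_freq`,
#'   `background_freq`, `p_value`, `adj_p`.
#' @export
enrich <- function(de_ids, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  universe <- collection$universe
  de_ids <- unique(de_ids)
  in_univ <- de_ids %in% universe
  if (any(!in_univ)) {
    warning(sprintf("%d differential ids outside the universe dropped",
                    sum(!in_univ)))
    de_ids <- de_ids[in_univ]
  }
  if (length(de_ids) == 0L) stop("empty differential list", call. = FALSE)

  rows <- lapply(names(collection$sets), function(id) {
    fr <- annotate_frequencies(de_ids, collection$sets[[id]], universe)
    data.frame(set_id = id,
               name = unname(collection$descriptions[[id]]),
               k = fr$k, n = fr$n, K = fr$K, N = fr$N,
               sample_freq = fr$sample_freq,
               background_freq = fr$background_freq,
               p_value = hypergeom_pvalue(fr$k, fr$n, fr$K, fr$N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$adj_p, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("over-representation of %d sets (n = %d differential, N = %d background)\n",
              nrow(x), x$n[1], x$N[1]))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                         c("set_id", "adj_p", "k", "n", "K", "N",
                           "sample_freq", "background_freq")]
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}
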