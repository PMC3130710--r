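#' Published example data shipped with the package
#'
#' Two small reference tables from a published glucagon-receptor-knockout
#' mouse liver study, used in examples and as fixed inputs to the frequency
#' and concordance computations:
#'
#' * `example_go_counts()` — gene-ontology over-representation counts per
#'   biological process for the differential transcript list (k of n
#'   differential features in the set, K of N background features).
#' * `example_fold_changes()` — the 17 genes with a printed signed fold
#'   change at both the mRNA and the protein level.
#'
#' @return a `data.frame`.
#' @export
example_go_counts <- function() {
  utils::read.delim(system.file("extdata", "go_term_counts.tsv",
                                package = "itraqr"),
                    stringsAsFactors = FALSE)
}

#' @rdname example_go_counts
#' @export
example_fold_changes <- function() {
  utils::read.delim(system.file("extdata", "mrna_protein_fold_changes.tsv",
                                package = "itraqr"),
                    stringsAsFactors = FALSE)
}
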