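#' Features-by-samples expression container
#'
#' Lightweight container shared by the transcript, protein and metabolite
#' layers: a numeric matrix with feature ids as rownames, sample ids as
#' colnames, a per-sample two-level group factor (KO/WT) and a scale tag.
#' Matrices tagged `linear-positive` (metabolite concentrations, protein
#' ratios on the fold scale) are log2-transformed by the differential stage;
#' matrices tagged `log2` are analyzed as given.
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param groups factor (or character) of length `ncol(values)` with levels
#'   KO and WT.
#' @param scale_tag `"log2"` or `"linear-positive"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups,
                              scale_tag = c("log2", "linear-positive")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(values)) ||
      (nrow(values) > 0L && is.null(rownames(values))))
    stop("values must carry feature and sample dimnames", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)) > 0L)
    stop("duplicated feature ids", call. = FALSE)
  groups <- factor(as.character(groups), levels = c("KO", "WT"))
  if (length(groups) != ncol(values) || anyNA(groups))
    stop("groups must label every sample as KO or WT", call. = FALSE)
  if (scale_tag == "linear-positive" && any(values <= 0, na.rm = TRUE))
    stop("linear-positive matrix must be strictly positive", call. = FALSE)
  structure(list(values = values, groups = groups, scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  cat(sprintf("  groups: KO n=%d, WT n=%d\n",
              sum(x$groups == "KO"), sum(x$groups == "WT")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Drop samples from an expression matrix
#'
#' Used after QC to exclude flagged samples (e.g. blood-contaminated
#' animals) before differential analysis.
#'
#' @param em an [expression_matrix()].
#' @param drop sample ids (or logical vector) to remove.
#' @return the reduced [expression_matrix()].
#' @export
drop_samples <- function(em, drop) {
  if (is.logical(drop)) drop <- colnames(em$values)[drop]
  keep <- !colnames(em$values) %in% drop
  expression_matrix(em$values[, keep, drop = FALSE], em$groups[keep],
                    em$scale_tag)
}

#' Write / read an expression matrix as TSV
#'
#' The TSV stores the feature id column first, then one column per sample;
#' group labels and scale tag travel in a `#` header comment line.
#'
#' @param em an [expression_matrix()].
#' @param path file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s groups=%s", em$scale_tag,
                     paste(em$groups, collapse = ",")), con)
  df <- data.frame(feature_id = rownames(em$values),
                   em$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# scale="))
    stop("data error: missing scale/group header line", call. = FALSE)
  m <- regmatches(header, regexec("# scale=(\\S+) groups=(\\S+)", header))[[1]]
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  expression_matrix(vals, strsplit(m[3], ",")[[1]], scale_tag = m[2])
}
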