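#' Gene-set collection with an explicit background universe
#'
#' Over-representation statistics are only meaningful against a declared
#' background, so the collection couples the sets with the universe of
#' testable feature ids. Members outside the universe are dropped at
#' construction with a warning (the background defines the sampling frame).
#'
#' @param sets named list of character vectors (set id -> member ids).
#' @param universe character vector of background feature ids.
#' @param descriptions optional named character vector of set descriptions.
#' @return an object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, universe, descriptions = NULL) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) > 0L)
    stop("sets must have unique names", call. = FALSE)
  universe <- unique(as.character(universe))
  cleaned <- lapply(sets, function(m) unique(as.character(m)))
  n_out <- sum(vapply(cleaned, function(m) sum(!m %in% universe), 0L))
  if (n_out > 0L) {
    warning(sprintf("%d set members outside the universe were dropped", n_out))
    cleaned <- lapply(cleaned, function(m) m[m %in% universe])
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(cleaned), names(cleaned))
  structure(list(sets = cleaned, universe = universe,
                 descriptions = descriptions),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("geneset_collection: %d sets over %d background features\n",
              length(x$sets), length(x$universe)))
  if (length(sizes))
    cat(sprintf("  set sizes: min %d, median %d, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member ids.
#'
#' @param collection a [geneset_collection()].
#' @param path file path.
#' @param universe background ids for the returned collection; defaults to
#'   the union of all members.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` a
#'   [geneset_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) stop("data error: GMT line with fewer than 3 fields",
                     call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  descr <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  geneset_collection(sets, universe = universe, descriptions = descr)
}
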