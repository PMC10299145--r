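#' Read a gene-set collection from a GMT file
#'
#' GMT format: one set per line, tab-separated `name<TAB>description<TAB>`
#' member genes.  Duplicate members within a set are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         ": expected at least 3 tab-separated fields")
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicated set name(s) in ", path)
  desc <- vapply(parts, `[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  n_dup <- sum(vapply(sets, anyDuplicated, numeric(1)) > 0)
  if (n_dup > 0) {
    warning(n_dup, " set(s) contained duplicated members; deduplicated")
    sets <- lapply(sets, unique)
  }
  structure(list(sets = stats::setNames(sets, nm),
                 description = stats::setNames(desc, nm)),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: writing then reading reproduces the set names,
#' descriptions and member sets.
#'
#' @param collection A `gene_set_collection` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  lines <- vapply(nm, function(s)
    paste(c(s, collection$description[[s]], collection$sets[[s]]),
          collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "set(s), sizes",
      paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' Hypergeometric gene-set over-representation with Bonferroni correction
#'
#' Tests a query gene list against each set of a collection within an
#' explicit background universe.  Set members and query genes outside the
#' universe are dropped first (counts reported as attributes).  The raw
#' p-value is the one-sided hypergeometric upper tail (the same kernel used
#' for cluster enrichment); the Bonferroni-adjusted p multiplies by the
#' number of sets whose overlap reached `min_count` (the sets actually
#' tested).  Rows are reported for sets with overlap >= `min_count`,
#' enrichment factor > `min_enrichment` and adjusted p < `alpha`, sorted by
#' adjusted p.
#'
#' The enrichment factor is `(overlap / query size) / (set size / universe
#' size)`, i.e. the fold over-representation of the set in the query.
#'
#' @param query Character vector of query gene IDs.
#' @param collection A `gene_set_collection`.
#' @param universe Character vector: the background gene universe.
#' @param min_count Minimum overlap for a set to be tested (default 3).
#' @param min_enrichment Minimum enrichment factor, exclusive (default 1.5).
#' @param alpha Adjusted-p cutoff, exclusive (default 0.05).
#' @return data.frame with columns `set`, `description`, `overlap`,
#'   `set_size`, `query_size`, `universe_size`, `p_value`, `p_adjusted`,
#'   `enrichment_factor`; attributes `n_query_dropped` and
#'   `n_members_dropped` count genes removed by the universe intersection.
#' @export
enrich <- function(query, collection, universe, min_count = 3L,
                   min_enrichment = 1.5, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query0 <- unique(as.character(query))
  query <- intersect(query0, universe)
  n_query_dropped <- length(query0) - length(query)
  sets0 <- collection$sets
  sets <- lapply(sets0, intersect, universe)
  n_members_dropped <- sum(lengths(sets0)) - sum(lengths(sets))

  N <- length(universe); n_q <- length(query)
  overlap <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  set_size <- lengths(sets)
  tested <- overlap >= min_count
  n_tested <- sum(tested)
  p <- rep(NA_real_, length(sets))
  p[tested] <- hyper_upper_tail(overlap[tested], set_size[tested], n_q, N)
  p_adj <- pmin(1, p * n_tested)
  ef <- ifelse(set_size > 0 & n_q > 0,
               (overlap / n_q) / (set_size / N), NA_real_)

  out <- data.frame(set = names(sets),
                    description = unname(collection$description[names(sets)]),
                    overlap = overlap, set_size = set_size,
                    query_size = n_q, universe_size = N,
                    p_value = p, p_adjusted = p_adj,
                    enrichment_factor = ef,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[tested & ef > min_enrichment & p_adj < alpha, , drop = FALSE]
  out <- out[order(out$p_adjusted, out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- n_query_dropped
  attr(out, "n_members_dropped") <- n_members_dropped
  out
}
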