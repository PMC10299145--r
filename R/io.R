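#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' Duplicate gene IDs and non-integer or negative cells are rejected with
#' the offending row/column named.
#'
#' @param path Path to a tab-separated counts file.
#' @return Integer gene-by-sample matrix with dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene column and >= 1 sample column")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(utils::head(genes[duplicated(genes)], 3), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad))
      stop("non-integer count at row ", bad[1] + 1L, " (gene ", genes[bad[1]],
           "), column '", colnames(m)[j], "' in ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count or expression matrix as TSV
#'
#' Genes in rows; the first column (`gene`) carries row names.
#'
#' @param mat Matrix with gene row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-stage design table
#'
#' Two tab-separated columns: sample ID and stage label.
#'
#' @param path Path to the design TSV (with header).
#' @return List with `design` (data.frame `sample`, `stage`) and `indicator`
#'   (samples x stages 0/1 matrix), as produced by [generate_stage_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("design file needs columns: sample, stage")
  names(df)[1:2] <- c("sample", "stage")
  if (anyDuplicated(df$sample)) stop("duplicate sample ID(s) in ", path)
  stage_names <- unique(df$stage)
  indicator <- vapply(stage_names, function(s) as.integer(df$stage == s),
                      integer(nrow(df)))
  indicator <- matrix(indicator, nrow = nrow(df),
                      dimnames = list(df$sample, stage_names))
  df$stage <- factor(df$stage, levels = stage_names)
  list(design = df[, c("sample", "stage")], indicator = indicator)
}

#' Read an undirected edge list (two-column TSV or SIF)
#'
#' SIF lines look like `A pp B` (whitespace-separated, interaction type in
#' the middle, possibly several targets); two-column TSV lines are
#' `from<TAB>to`.  Files ending in `.sif` are parsed as SIF, others as TSV
#' (headerless).  Self-loops are dropped with a warning and duplicate edges
#' collapsed; the returned edges are symmetrised canonically
#' (`from < to`).
#'
#' @param path Path to the edge file.
#' @return data.frame with character columns `from`, `to`.
#' @export
read_edges <- function(path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) == 2L)
    if (length(bad))
      stop("malformed SIF line ", bad[1], " in ", path,
           ": expected 'source interaction target...' or a lone node")
    from <- to <- character(0)
    for (p in parts) {
      if (length(p) < 3L) next   # isolated node line
      from <- c(from, rep(p[1], length(p) - 2L))
      to <- c(to, p[-(1:2)])
    }
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 2L) stop("edge list needs two columns in ", path)
    # tolerate an optional header line
    if (nrow(df) && all(tolower(unlist(df[1, 1:2])) %in%
                        c("from", "to", "source", "target", "gene1", "gene2")))
      df <- df[-1, , drop = FALSE]
    from <- as.character(df[[1]]); to <- as.character(df[[2]])
  }
  loops <- from == to
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s)")
    from <- from[!loops]; to <- to[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
}

#' Write an edge list as two-column TSV
#' @param edges data.frame with columns `from`, `to`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene label list (one gene ID per line)
#' @param path Path to the label file.
#' @return Character vector of unique gene IDs.
#' @export
read_labels <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Write a gene label list (one gene ID per line)
#' @param labels Character vector of gene IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Write a cluster set as a GMT-like TSV
#'
#' One cluster per line: cluster ID, density, then tab-joined members.
#'
#' @param cluster_set A `cluster_set` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cluster_set, path) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  lines <- vapply(seq_along(cluster_set$clusters), function(i) {
    cl <- cluster_set$clusters[[i]]
    paste(c(sprintf("cluster%03d", i), format(cl$density, digits = 6),
            cl$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
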