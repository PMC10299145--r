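#' Remove lowly expressed genes
#'
#' Drops genes whose total read count across samples falls below
#' `min_total` (default 10, i.e. genes with fewer than ten reads overall are
#' removed).  Gene and sample order are preserved.
#'
#' @param counts Non-negative integer gene-by-sample matrix with gene row
#'   names.
#' @param min_total Minimum total count a gene must reach to be retained.
#' @return The filtered count matrix, with attribute `n_removed` giving the
#'   number of genes dropped.
#' @export
filter_low_counts <- function(counts, min_total = 10L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  keep <- rowSums(counts) >= min_total
  if (!any(keep))
    stop("all ", nrow(counts), " genes fall below min_total = ", min_total,
         "; lower the threshold")
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors by the median-of-ratios method: each gene's
#' geometric mean across samples is the reference (genes containing any zero
#' are excluded from the reference set), each sample's factor is the median
#' over genes of count / reference, and factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Non-negative gene-by-sample count matrix.
#' @return Named numeric vector of positive per-sample size factors with
#'   geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has nonzero counts in every sample; ",
         "add a pseudocount before estimating size factors")
  log_counts <- log(counts[all_pos, , drop = FALSE])
  log_geomean <- rowMeans(log_counts)
  sf <- apply(log_counts, 2, function(lc) exp(stats::median(lc - log_geomean)))
  sf <- sf / exp(mean(log(sf)))   # geometric mean 1
  stats::setNames(sf, colnames(counts))
}

#' Variance-stabilising shifted-log transform
#'
#' Normalises counts by the per-sample size factors and applies a shifted
#' log2: `value(g, s) = log2(count(g, s) / factor(s) + pseudocount)`.  The
#' transform is monotone in the counts and finite everywhere; it compresses
#' the count range so that per-gene variance is comparable across expression
#' levels, which is what the downstream variance ranking and Pearson
#' correlations rely on.
#'
#' @param counts Non-negative gene-by-sample count matrix.
#' @param size_factors Positive per-sample factors, e.g. from
#'   [estimate_size_factors()]; recycled names must match `counts` columns.
#' @param pseudocount Positive shift added before the log (default 1).
#' @return Numeric gene-by-sample matrix of transformed values.
#' @export
vst_transform <- function(counts, size_factors = estimate_size_factors(counts),
                          pseudocount = 1) {
  counts <- as.matrix(counts)
  if (length(size_factors) != ncol(counts))
    stop("size_factors length must equal the number of samples")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(sweep(counts, 2, size_factors, "/") + pseudocount)
}

#' Select the high-variance gene subset
#'
#' Ranks genes by their sample variance and keeps the top
#' `ceiling((1 - variance_quantile) * G)` genes, so the default
#' `variance_quantile = 0.95` keeps the top 5% most variable genes.
#' The count rule makes the output size deterministic; variance ties are
#' broken by gene ID ascending.
#'
#' @param expr Numeric gene-by-sample matrix with gene row names, at least
#'   two samples.
#' @param variance_quantile Quantile in (0,1); genes above it are kept.
#' @return The row subset of `expr` holding the selected genes, in their
#'   original row order.
#' @export
select_high_variance <- function(expr, variance_quantile = 0.95) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2L)
    stop("variance is undefined with fewer than 2 samples")
  if (!(variance_quantile > 0 && variance_quantile < 1))
    stop("variance_quantile must lie in (0,1)")
  g <- nrow(expr)
  # epsilon guard: (1 - q) * g can exceed its exact value by float error,
  # which would push ceiling() one past the intended count
  n_keep <- as.integer(ceiling((1 - variance_quantile) * g - 1e-9))
  n_keep <- max(n_keep, 1L)
  v <- rowSums((expr - rowMeans(expr))^2) / (ncol(expr) - 1)
  ids <- rownames(expr)
  if (is.null(ids)) ids <- sprintf("row%06d", seq_len(g))
  ord <- order(-v, ids)
  keep <- sort(ord[seq_len(n_keep)])
  expr[keep, , drop = FALSE]
}
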