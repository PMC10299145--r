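# internal shared kernel: one-sided hypergeometric upper tail P(X >= a)
# for a 2x2 table with margins (N genes, K labelled, n drawn, a overlap)
hyper_upper_tail <- function(a, K, n, N) {
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Regulatory-gene enrichment of one cluster
#'
#' Builds the 2x2 contingency table (regulatory / non-regulatory versus in /
#' out of cluster) over the background gene universe and computes the
#' one-sided hypergeometric upper-tail p-value
#' `P(X >= a) = sum_{k >= a} C(K, k) C(N - K, n - k) / C(N, n)`
#' with `N` the background size, `K` the number of regulatory genes, `n` the
#' cluster size and `a` the regulatory genes inside the cluster -- the
#' one-sided Fisher exact test for over-representation.
#'
#' @param cluster Character vector of cluster member gene IDs (subset of the
#'   background).
#' @param labels Character vector of regulatory gene IDs (subset of the
#'   background).
#' @param background Character vector: the gene universe.
#' @return An object of class `cluster_enrichment`: list with `table`
#'   (named counts `a`, `b`, `c`, `d`), `p_value`, `n` (cluster size).
#' @export
cluster_enrichment <- function(cluster, labels, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background universe")
  cluster <- unique(as.character(cluster))
  labels <- unique(as.character(labels))
  if (length(setdiff(cluster, background)))
    stop("cluster contains genes outside the background")
  if (length(setdiff(labels, background)))
    stop("labels contain genes outside the background")
  N <- length(background); K <- length(labels); n <- length(cluster)
  a <- length(intersect(cluster, labels))
  tab <- c(a = a, b = n - a, c = K - a, d = N - K - (n - a))
  structure(list(table = tab,
                 p_value = hyper_upper_tail(a, K, n, N),
                 n = n),
            class = "cluster_enrichment")
}

#' Enrichment table for a whole cluster set
#'
#' Applies [cluster_enrichment()] to every cluster of a [dpcluso_cluster()]
#' result.
#'
#' @param cluster_set A `cluster_set` object.
#' @param labels Regulatory gene IDs.
#' @param background Gene universe (defaults to the union of all graph nodes
#'   seen in the clusters is NOT assumed; pass the clustered network's node
#'   set explicitly).
#' @return data.frame with columns `cluster`, `n`, `a`, `b`, `c`, `d`,
#'   `p_value`, one row per cluster, in cluster order.
#' @export
enrich_clusters <- function(cluster_set, labels, background) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  rows <- lapply(seq_along(cluster_set$clusters), function(i) {
    ce <- cluster_enrichment(cluster_set$clusters[[i]]$members, labels, background)
    data.frame(cluster = i, n = ce$n,
               a = ce$table[["a"]], b = ce$table[["b"]],
               c = ce$table[["c"]], d = ce$table[["d"]],
               p_value = ce$p_value)
  })
  if (!length(rows))
    return(data.frame(cluster = integer(0), n = integer(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      p_value = numeric(0)))
  do.call(rbind, rows)
}

#' Per-gene significance scores (SScore)
#'
#' Each gene's SScore is `-log10` of the smallest enrichment p-value among
#' the clusters containing it; genes covered by no cluster score 0
#' (equivalently p = 1).  A gene in several clusters inherits its best
#' (lowest) p-value.
#'
#' @param cluster_set A `cluster_set` object.
#' @param enrichment The matching [enrich_clusters()] data.frame.
#' @param background Gene universe over which scores are reported.
#' @return data.frame with columns `gene`, `sscore`, `min_p` (NA when
#'   uncovered), `best_cluster` (NA when uncovered), one row per background
#'   gene.
#' @export
sscore_table <- function(cluster_set, enrichment, background) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  background <- unique(as.character(background))
  min_p <- stats::setNames(rep(NA_real_, length(background)), background)
  best <- stats::setNames(rep(NA_integer_, length(background)), background)
  for (i in seq_along(cluster_set$clusters)) {
    p <- enrichment$p_value[enrichment$cluster == i]
    if (!length(p)) stop("no enrichment row for cluster ", i)
    for (g in intersect(cluster_set$clusters[[i]]$members, background)) {
      if (is.na(min_p[[g]]) || p < min_p[[g]]) {
        min_p[[g]] <- p
        best[[g]] <- i
      }
    }
  }
  sscore <- ifelse(is.na(min_p), 0, -log10(min_p))
  data.frame(gene = background, sscore = unname(sscore),
             min_p = unname(min_p), best_cluster = unname(best),
             stringsAsFactors = FALSE)
}

#' ROC curve of SScores against regulatory labels
#'
#' Sweeps a threshold `th` over the descending unique scores (plus a
#' sentinel above the maximum): at each threshold a gene is predicted
#' regulatory when its SScore >= th, giving TP/FP/TN/FN counts,
#' `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`.  The area under the
#' (FPR, TPR) curve is computed by the trapezoidal rule; the curve runs from
#' (0, 0) to (1, 1).
#'
#' @param scores Either the [sscore_table()] data.frame or a named numeric
#'   vector of per-gene scores.
#' @param labels Character vector of positive (regulatory) gene IDs; every
#'   scored gene not listed is a negative.
#' @return An object of class `roc_result`: list with `points` (data.frame
#'   of `threshold`, `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$sscore, scores$gene)
  labels <- unique(as.character(labels))
  is_pos <- names(scores) %in% labels
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L) stop("no positive (regulatory) gene among the scores")
  if (n_neg == 0L) stop("no negative (non-regulatory) gene among the scores")
  th <- sort(unique(scores), decreasing = TRUE)
  th <- c(max(scores) + 1, th)   # sentinel: nothing predicted positive
  tp <- vapply(th, function(t) sum(scores[is_pos] >= t), numeric(1))
  fp <- vapply(th, function(t) sum(scores[!is_pos] >= t), numeric(1))
  fn <- n_pos - tp; tn <- n_neg - fp
  pts <- data.frame(threshold = th, tp = tp, fp = fp, tn = tn, fn = fn,
                    tpr = tp / n_pos, fpr = fp / n_neg)
  # trapezoid over the swept curve, closed at (1, 1)
  fpr <- c(pts$fpr, 1); tpr <- c(pts$tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC over", nrow(x$points), "thresholds; AUC =", signif(x$auc, 4), "\n")
  invisible(x)
}

#' Pick the clustering density with the best AUC
#'
#' Given the per-density AUC map from the ROC evaluation of each cluster
#' set, returns the density achieving the maximum AUC; ties go to the
#' smallest density.
#'
#' @param auc_by_density Named numeric vector: names are density values,
#'   entries the AUCs.
#' @return The chosen density as a numeric scalar.
#' @export
select_best_density <- function(auc_by_density) {
  if (!length(auc_by_density)) stop("empty AUC map")
  d <- as.numeric(names(auc_by_density))
  if (anyNA(d)) stop("names of auc_by_density must be numeric densities")
  best <- which(auc_by_density == max(auc_by_density))
  d[best][which.min(d[best])]
}

#' Clusters significantly enriched for regulatory genes
#'
#' @param enrichment An [enrich_clusters()] data.frame.
#' @param alpha Significance level; clusters with `p_value < alpha`
#'   (strictly) are kept.
#' @return The significant rows, sorted by p-value ascending.
#' @export
significant_clusters <- function(enrichment, alpha = 0.05) {
  sig <- enrichment[enrichment$p_value < alpha, , drop = FALSE]
  sig[order(sig$p_value, sig$cluster), , drop = FALSE]
}

#' Candidate regulatory genes from significant clusters
#'
#' The candidates are the known regulatory genes that occur in at least one
#' significant cluster, ranked by SScore descending (ties by gene ID); each
#' candidate's best (lowest-p) cluster is recorded.
#'
#' @param sig_clusters Output of [significant_clusters()].
#' @param cluster_set The `cluster_set` the enrichment was computed on.
#' @param labels Regulatory gene IDs.
#' @param scores The [sscore_table()] data.frame.
#' @return data.frame with columns `gene`, `sscore`, `best_cluster`,
#'   possibly empty.
#' @export
candidate_regulatory_genes <- function(sig_clusters, cluster_set, labels, scores) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  labels <- unique(as.character(labels))
  in_sig <- unique(unlist(lapply(sig_clusters$cluster, function(i)
    cluster_set$clusters[[i]]$members), use.names = FALSE))
  cand <- intersect(labels, in_sig)
  if (!length(cand))
    return(data.frame(gene = character(0), sscore = numeric(0),
                      best_cluster = integer(0), stringsAsFactors = FALSE))
  sub <- scores[match(cand, scores$gene), ]
  sub <- sub[order(-sub$sscore, sub$gene), ]
  data.frame(gene = sub$gene, sscore = sub$sscore,
             best_cluster = sub$best_cluster, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Evaluate a density sweep by ROC/AUC
#'
#' For each cluster set of a [dpcluso_sweep()], computes cluster
#' enrichments, SScores, and the ROC/AUC of the scores against the
#' regulatory labels; then selects the best density.
#'
#' @param sweep Named list of `cluster_set` objects (names = densities).
#' @param labels Regulatory gene IDs.
#' @param background Gene universe (the clustered network's node set).
#' @return List with `auc` (named numeric per density), `best_density`,
#'   and `by_density` (per density: `enrichment`, `scores`, `roc`).
#' @export
evaluate_density_sweep <- function(sweep, labels, background) {
  by_density <- lapply(sweep, function(cs) {
    enr <- enrich_clusters(cs, labels, background)
    sc <- sscore_table(cs, enr, background)
    list(enrichment = enr, scores = sc, roc = roc_curve(sc, labels))
  })
  auc <- vapply(by_density, function(x) x$roc$auc, numeric(1))
  list(auc = auc,
       best_density = select_best_density(auc),
       by_density = by_density)
}
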