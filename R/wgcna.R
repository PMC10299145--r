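#' Signed weighted adjacency matrix
#'
#' Computes the signed soft-thresholded adjacency
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^power` from Pearson correlations of
#' gene expression profiles.  Anti-correlated genes get adjacency near 0,
#' perfectly correlated genes adjacency 1; raising to `power` suppresses weak
#' correlations so the network approximates scale-free topology.
#'
#' Zero-variance genes have undefined correlations; these are set to 0
#' (adjacency `(1/2)^power`) with a warning.
#'
#' @param expr Numeric gene-by-sample matrix (genes in rows), >= 3 samples.
#' @param power Soft-thresholding exponent beta (>= 1).
#' @return Symmetric gene-by-gene matrix in \[0,1\] with unit diagonal.
#' @export
signed_adjacency <- function(expr, power = 12) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples to estimate correlations")
  if (power < 1) stop("power must be >= 1")
  cors <- suppressWarnings(stats::cor(t(expr)))
  if (anyNA(cors)) {
    warning("zero-variance gene(s): undefined correlations set to 0")
    cors[is.na(cors)] <- 0
  }
  adj <- ((1 + cors) / 2)^power
  diag(adj) <- 1
  adj
}

# Scale-free topology fit of a connectivity vector: bin log10(k) into
# `n_bins` equal-occupancy bins, estimate the log-density of connectivity per
# bin (count / bin width), and regress log10(density) on log10(mean k).
# Returns the plain R^2 of that fit: how well a power law describes the
# connectivity distribution.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < 2L) return(0)
  lk <- log10(k)
  breaks <- unique(stats::quantile(lk, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3L) return(0)
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  widths <- diff(breaks)
  mean_k <- tapply(k, bin, mean)
  ok <- counts > 0 & widths > 0 & is.finite(mean_k)
  if (sum(ok) < 3L) return(0)
  x <- log10(mean_k[ok])
  y <- log10(counts[ok] / widths[ok])
  fit <- stats::lm(y ~ x)
  summary(fit)$r.squared
}

#' Choose the soft-thresholding power
#'
#' For each candidate power, builds the signed adjacency, computes node
#' connectivities `k_i = sum_{j != i} a_ij`, and evaluates the scale-free
#' topology fit index (R^2 of the log-log regression of connectivity
#' density on connectivity, over equal-occupancy bins).  The chosen power is
#' the smallest candidate whose fit index reaches `r2_target`; if none does,
#' the power with the maximal fit index is chosen with a warning.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param powers Candidate integer powers (non-empty).
#' @param r2_target Scale-free fit threshold (default 0.80).
#' @param n_bins Number of connectivity bins for the fit (default 10).
#' @return An object of class `soft_threshold` : list with `table`
#'   (data.frame of `power`, `fit_index`, `mean_connectivity`), `power`
#'   (chosen), `r2_target`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.80, n_bins = 10L) {
  if (!length(powers)) stop("powers must be non-empty")
  powers <- sort(unique(as.numeric(powers)))
  fit_index <- mean_k <- numeric(length(powers))
  base <- signed_adjacency(expr, power = 1)
  for (i in seq_along(powers)) {
    adj <- base^powers[i]
    k <- rowSums(adj) - 1
    if (all(k == 0)) stop("all connectivities are zero; cannot assess scale-free fit")
    fit_index[i] <- scale_free_fit(k, n_bins = n_bins)
    mean_k[i] <- mean(k)
  }
  tab <- data.frame(power = powers, fit_index = fit_index,
                    mean_connectivity = mean_k)
  hit <- which(fit_index >= r2_target)
  if (length(hit)) {
    chosen <- powers[hit[1]]
  } else {
    chosen <- powers[which.max(fit_index)]
    warning("no candidate power reached the scale-free fit target ",
            r2_target, "; using power ", chosen, " (fit index ",
            signif(max(fit_index), 3), ")")
  }
  structure(list(table = tab, power = chosen, r2_target = r2_target),
            class = "soft_threshold")
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("Soft-threshold scan (target fit index ", x$r2_target, ")\n", sep = "")
  print(transform(x$table, fit_index = signif(fit_index, 3),
                  mean_connectivity = signif(mean_connectivity, 4)),
        row.names = FALSE)
  cat("chosen power:", x$power, "\n")
  invisible(x)
}

#' Topological overlap matrix
#'
#' Converts an adjacency matrix into the (unsigned) topological overlap
#' measure
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu * a_uj` and connectivity
#' `k_i = sum_{j != i} a_ij`; the diagonal is set to 1.  TOM rewards gene
#' pairs that share network neighbourhoods beyond their direct connection.
#'
#' @param adj Symmetric adjacency matrix in \[0,1\] with unit diagonal.
#' @return Symmetric matrix in \[0,1\] with unit diagonal; the clustering
#'   dissimilarity is `1 - TOM`.
#' @export
tom_similarity <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric")
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must lie in [0,1]")
  k <- rowSums(adj) - diag(adj)
  # l_ij over u != i, j: full product minus the u = i and u = j terms
  l <- adj %*% adj - sweep(adj, 1, diag(adj), "*") - sweep(adj, 2, diag(adj), "*")
  min_k <- outer(k, k, pmin)
  tom <- (l + adj) / (min_k + 1 - adj)
  diag(tom) <- 1
  tom
}

# colour aliases for size-ranked module labels (largest first), matching the
# conventional palette order; ranks beyond the table fall back to "moduleNN"
.module_colours <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Builds an average-linkage dendrogram on the TOM dissimilarity and cuts it
#' statically at a height given by a quantile of the merge heights (default
#' the 0.95 quantile).  Resulting clusters smaller than `min_module_size`
#' are assigned to the reserved unassigned label `"grey"`; the remaining
#' modules are labelled by size rank using the conventional colour aliases
#' (largest module = "turquoise").
#'
#' @param diss_tom Square symmetric dissimilarity matrix (`1 - TOM`) with
#'   gene dimnames.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_quantile Quantile of merge heights at which the tree is cut
#'   (default 0.95).
#' @return An object of class `module_assignment`: list with `labels` (named
#'   gene-to-module map), `sizes` (named module sizes, grey included),
#'   `min_module_size`, `cut_height`, and `tree` (the hclust object).
#' @export
detect_modules <- function(diss_tom, min_module_size = 30L, cut_quantile = 0.95) {
  diss_tom <- as.matrix(diss_tom)
  genes <- rownames(diss_tom)
  if (is.null(genes)) genes <- sprintf("gene%05d", seq_len(nrow(diss_tom)))
  if (nrow(diss_tom) < max(2L, min_module_size)) {
    warning("fewer genes (", nrow(diss_tom), ") than min_module_size (",
            min_module_size, "); all genes unassigned")
    labels <- stats::setNames(rep("grey", nrow(diss_tom)), genes)
    return(structure(list(labels = labels,
                          sizes = c(grey = length(labels)),
                          min_module_size = min_module_size,
                          cut_height = NA_real_, tree = NULL),
                     class = "module_assignment"))
  }
  tree <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- stats::quantile(tree$height, cut_quantile)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    rank_order <- keep[order(-sizes[keep], as.integer(keep))]
    alias <- c(.module_colours, sprintf("module%02d",
                                        seq_len(max(0, length(rank_order) - length(.module_colours)))))
    for (i in seq_along(rank_order))
      labels[cl == as.integer(rank_order[i])] <- alias[i]
  }
  names(labels) <- genes
  structure(list(labels = labels,
                 sizes = sort(table(labels), decreasing = TRUE),
                 min_module_size = min_module_size,
                 cut_height = unname(h),
                 tree = tree),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- sum(names(x$sizes) != "grey")
  cat("Module assignment:", n_mod, "module(s),",
      if ("grey" %in% names(x$sizes)) x$sizes[["grey"]] else 0,
      "unassigned gene(s)\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' Summarises each module by its eigengene: the first principal component of
#' the module's standardised expression across samples.  Each eigengene is
#' scaled to unit variance and sign-oriented so that its correlation with
#' the module's mean standardised expression is non-negative.  A one-gene
#' module's eigengene is that gene's z-scored profile.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param labels Named gene-to-module map (e.g. from [detect_modules()]);
#'   the `"grey"` unassigned label is skipped.
#' @return Module-by-sample numeric matrix of eigengenes.
#' @export
module_eigengenes <- function(expr, labels) {
  expr <- as.matrix(expr)
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  labels <- labels[rownames(expr)]
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no non-grey module to summarise")
  mods <- names(sort(table(labels[labels %in% mods]), decreasing = TRUE))
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(mods, colnames(expr)))
  for (m in mods) {
    sub <- expr[labels == m, , drop = FALSE]
    std <- t(scale(t(sub)))
    std[!is.finite(std)] <- 0   # zero-variance genes contribute nothing
    if (nrow(std) == 1L) {
      v <- drop(std)
    } else {
      v <- svd(std, nu = 0, nv = 1)$v[, 1]
    }
    if (stats::sd(v) == 0) v <- v + stats::rnorm(length(v), sd = 1e-12)
    ref <- colMeans(std)
    if (stats::sd(ref) > 0 && stats::cor(v, ref) < 0) v <- -v
    me[m, ] <- v / stats::sd(v)
  }
  me
}

#' Merge modules with close eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - cor(ME_a, ME_b)` is smallest, as long as it is below
#' `merge_cut_height`, recomputing eigengenes after each merge.  The merged
#' module keeps the label of the larger member.  This removes redundant
#' splits of a single underlying expression programme.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param labels Named gene-to-module map or a `module_assignment`.
#' @param merge_cut_height Dissimilarity threshold below which modules merge
#'   (default 0.25, i.e. eigengene correlation above 0.75).
#' @return Named gene-to-module map after merging.
#' @export
merge_close_modules <- function(expr, labels, merge_cut_height = 0.25) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  labels <- labels[rownames(expr)]
  if (merge_cut_height <= 0) return(labels)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, labels)
    d <- 1 - stats::cor(t(me))
    diag(d) <- Inf
    idx <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[idx[1], idx[2]] >= merge_cut_height) break
    a <- rownames(d)[idx[1]]; b <- rownames(d)[idx[2]]
    sizes <- table(labels)
    into <- if (sizes[[a]] >= sizes[[b]]) a else b
    from <- if (into == a) b else a
    labels[labels == from] <- into
  }
  labels
}

#' Refine module membership by eigengene correlation
#'
#' Reassigns every gene to the module whose eigengene it correlates with
#' best, provided that membership reaches `min_kme`; genes below the bound
#' for every module go to the unassigned label `"grey"`.  A static
#' dendrogram cut inevitably drags some unstructured genes into the module
#' whose branch they happen to join and strands a few genuine members on
#' side branches; the kME sweep fixes both, the cleanup role the dynamic
#' tree-cut family performs for poorly attached leaves.  Modules that fall
#' below `min_module_size` after refinement are dissolved into grey.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param labels Named gene-to-module map or `module_assignment`.
#' @param min_kme Minimum module membership to stay assigned (default 0.5).
#' @param min_module_size Modules smaller than this after refinement are
#'   dissolved (default 30).
#' @return Named gene-to-module map.
#' @export
prune_modules <- function(expr, labels, min_kme = 0.5, min_module_size = 30L) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  labels <- labels[rownames(expr)]
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods) || min_kme <= 0) return(labels)
  me <- module_eigengenes(expr, labels)
  kme <- module_membership(expr, me)
  best <- colnames(kme)[max.col(kme, ties.method = "first")]
  best_kme <- kme[cbind(seq_len(nrow(kme)), max.col(kme, ties.method = "first"))]
  labels <- stats::setNames(ifelse(best_kme >= min_kme, best, "grey"),
                            rownames(expr))
  sizes <- table(labels)
  small <- setdiff(names(sizes)[sizes < min_module_size], "grey")
  labels[labels %in% small] <- "grey"
  labels
}

#' Correlate module eigengenes with stage indicators
#'
#' Pearson correlation of each module eigengene with each stage's binary
#' one-vs-rest indicator, with two-sided p-values from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param me Module-by-sample eigengene matrix.
#' @param traits Sample-by-stage 0/1 indicator matrix (same samples).
#' @return An object of class `module_trait_correlation`: list with `r` and
#'   `p` (module-by-stage matrices) and `n` (sample count).
#' @export
module_trait_correlation <- function(me, traits) {
  me <- as.matrix(me); traits <- as.matrix(traits)
  if (ncol(me) != nrow(traits))
    stop("sample count mismatch between eigengenes and traits")
  n <- ncol(me)
  if (n < 3L) stop("need at least 3 samples for a correlation test")
  r <- stats::cor(t(me), traits)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p <- pmin(p, 1)
  structure(list(r = r, p = p, n = n), class = "module_trait_correlation")
}

#' @export
print.module_trait_correlation <- function(x, ...) {
  cat("Module-trait Pearson correlations (n =", x$n, "samples)\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Select modules positively associated with a stage
#'
#' Returns the modules whose eigengene correlates positively (`r > 0`) and
#' significantly (`p < alpha`) with the named stage, sorted by correlation
#' descending.
#'
#' @param mtc A [module_trait_correlation()] result.
#' @param stage Stage (trait column) name.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of module labels (possibly empty).
#' @export
select_key_modules <- function(mtc, stage, alpha = 0.05) {
  stopifnot(inherits(mtc, "module_trait_correlation"))
  if (!stage %in% colnames(mtc$r))
    stop("unknown stage: ", stage)
  r <- mtc$r[, stage]; p <- mtc$p[, stage]
  hits <- names(r)[r > 0 & p < alpha]
  hits[order(-r[hits])]
}

#' Signed module membership (kME)
#'
#' kME of gene g for module m is the Pearson correlation between g's
#' expression profile and module m's eigengene.  Zero-variance genes get
#' kME 0 with a warning.
#'
#' @param expr Numeric gene-by-sample matrix.
#' @param me Module-by-sample eigengene matrix.
#' @return Gene-by-module matrix of kME values in \[-1, 1\].
#' @export
module_membership <- function(expr, me) {
  expr <- as.matrix(expr); me <- as.matrix(me)
  if (ncol(expr) != ncol(me)) stop("sample count mismatch")
  kme <- suppressWarnings(stats::cor(t(expr), t(me)))
  if (anyNA(kme)) {
    warning("zero-variance gene(s): kME set to 0")
    kme[is.na(kme)] <- 0
  }
  kme
}

#' Hub genes per module
#'
#' A module's hub genes are its members whose module membership reaches the
#' threshold (`kME >= 0.80` by default; the bound is inclusive).
#'
#' @param kme Gene-by-module kME matrix from [module_membership()].
#' @param labels Named gene-to-module map or `module_assignment`.
#' @param threshold Inclusive kME cutoff (default 0.80).
#' @return Named list: for each non-grey module, the character vector of its
#'   hub genes.
#' @export
select_hub_genes <- function(kme, labels, threshold = 0.80) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  labels <- labels[rownames(kme)]
  mods <- intersect(colnames(kme), setdiff(unique(labels), "grey"))
  out <- lapply(mods, function(m) {
    members <- rownames(kme)[labels == m]
    members[kme[members, m] >= threshold]
  })
  stats::setNames(out, mods)
}
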