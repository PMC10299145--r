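#' Configuration for the synthetic count-matrix generator
#'
#' Describes a planted-module RNA-seq experiment: a set of developmental
#' stages with per-stage replicate counts, co-expression modules whose genes
#' share a latent factor, and a fraction of unstructured "noise" genes.
#' The defaults emulate a 9-sample insect developmental series (egg, third
#' instar larva, pupa, adult) with four stage-associated modules of 50 genes
#' each plus 50 noise genes.
#'
#' Each module is tied to one stage: its latent factor is shifted upwards by
#' `stage_effect` latent standard deviations in the samples of that stage, so
#' the module's genes are elevated there.
#'
#' @param n_genes Total number of genes (planted module genes + noise genes).
#' @param stages Named integer vector: per-stage sample counts, in stage order.
#' @param module_sizes Integer vector of planted module sizes; its length is
#'   the number of modules.
#' @param within_module_correlation Target pairwise correlation, in (0,1), of
#'   genes within a module on the latent (log) scale.
#' @param stage_association Character vector mapping each module to a stage
#'   name; recycled over modules if length 1.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_range Length-2 numeric: per-sample library sizes are
#'   drawn uniformly from this interval.
#' @param noise_gene_fraction Fraction of genes carrying no module structure.
#'   Defaults to `(n_genes - sum(module_sizes)) / n_genes`; if supplied it
#'   must agree with that value.
#' @param stage_effect Mean shift, in latent standard deviations, of a
#'   module's factor in its associated stage's samples.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_count_matrix()], [generate_stage_design()]
#' @export
synthetic_config <- function(n_genes = 250L,
                             stages = c(egg = 2L, larva3 = 3L, pupa = 2L, adult = 2L),
                             module_sizes = rep(50L, 4L),
                             within_module_correlation = 0.9,
                             stage_association = c("egg", "larva3", "pupa", "adult"),
                             dispersion = 0.1,
                             library_size_range = c(1e5, 2e5),
                             noise_gene_fraction = NULL,
                             stage_effect = 2,
                             seed = 1L) {
  if (length(stages) < 1L || is.null(names(stages)) || any(!nzchar(names(stages))))
    stop("configuration error in field 'stages': need a named vector of per-stage sample counts")
  stages <- vapply(stages, as.integer, integer(1))
  if (any(stages < 1L))
    stop("configuration error in field 'stages': per-stage sample counts must be >= 1")
  if (anyDuplicated(names(stages)))
    stop("configuration error in field 'stages': duplicated stage names")
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("configuration error in field 'n_genes': must be positive")
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 1L))
    stop("configuration error in field 'module_sizes': sizes must be positive")
  n_modules <- length(module_sizes)
  if (sum(module_sizes) > n_genes)
    stop("configuration error in field 'module_sizes': sum of module sizes (",
         sum(module_sizes), ") exceeds n_genes (", n_genes, ")")
  n_noise <- n_genes - sum(module_sizes)
  derived_fraction <- n_noise / n_genes
  if (!is.null(noise_gene_fraction) &&
      abs(noise_gene_fraction - derived_fraction) > 1e-8)
    stop("configuration error in field 'noise_gene_fraction': supplied value ",
         noise_gene_fraction, " does not match (n_genes - sum(module_sizes)) / n_genes = ",
         signif(derived_fraction, 6))
  if (n_modules > 0L) {
    if (length(stage_association) == 1L)
      stage_association <- rep(stage_association, n_modules)
    if (length(stage_association) != n_modules)
      stop("configuration error in field 'stage_association': length ",
           length(stage_association), " but ", n_modules, " modules")
    missing_stage <- setdiff(stage_association, names(stages))
    if (length(missing_stage))
      stop("configuration error in field 'stage_association': unknown stage(s) ",
           paste(missing_stage, collapse = ", "))
  } else {
    stage_association <- character(0)
  }
  if (!(within_module_correlation > 0 && within_module_correlation < 1))
    stop("configuration error in field 'within_module_correlation': must lie in (0,1)")
  if (dispersion <= 0)
    stop("configuration error in field 'dispersion': must be positive")
  if (length(library_size_range) != 2L || any(library_size_range <= 0) ||
      library_size_range[1] > library_size_range[2])
    stop("configuration error in field 'library_size_range': need an increasing pair of positive reals")

  structure(list(
    n_genes = n_genes,
    n_samples = sum(stages),
    stages = stages,
    n_modules = n_modules,
    module_sizes = module_sizes,
    within_module_correlation = within_module_correlation,
    stage_association = stage_association,
    dispersion = dispersion,
    library_size_range = as.numeric(library_size_range),
    noise_gene_fraction = derived_fraction,
    stage_effect = stage_effect,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic expression configuration\n")
  cat("  genes:", x$n_genes, "(", sum(x$module_sizes), "in", x$n_modules,
      "modules,", x$n_genes - sum(x$module_sizes), "noise )\n")
  cat("  samples:", x$n_samples, "over stages",
      paste0(names(x$stages), ":", x$stages, collapse = ", "), "\n")
  cat("  within-module correlation:", x$within_module_correlation,
      " stage effect:", x$stage_effect, "SD  dispersion:", x$dispersion, "\n")
  invisible(x)
}

#' Sample-to-stage design table
#'
#' Lays out one sample per row in stage order, with replicate-numbered sample
#' IDs, and a binary one-vs-rest stage indicator matrix (one column per
#' stage).  The layout is a deterministic function of the configuration.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with `design` (data.frame of `sample`, `stage`) and
#'   `indicator` (samples x stages 0/1 matrix with column sums equal to the
#'   per-stage counts).
#' @export
generate_stage_design <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  stage_names <- names(config$stages)
  stage_of_sample <- rep(stage_names, times = config$stages)
  sample_id <- unlist(lapply(stage_names, function(s)
    paste0(s, "_", seq_len(config$stages[[s]]))), use.names = FALSE)
  design <- data.frame(sample = sample_id,
                       stage = factor(stage_of_sample, levels = stage_names),
                       stringsAsFactors = FALSE)
  indicator <- vapply(stage_names,
                      function(s) as.integer(stage_of_sample == s),
                      integer(length(stage_of_sample)))
  indicator <- matrix(indicator, nrow = length(stage_of_sample),
                      dimnames = list(sample_id, stage_names))
  list(design = design, indicator = indicator)
}

#' Generate a planted-module count matrix
#'
#' Draws a gene-by-sample matrix of negative-binomial read counts whose log
#' means follow a latent-factor model.  Each module m has one latent factor
#' per sample, `z[m, j] ~ N(effect * 1[stage(j) == stage(m)], 1)`; a gene g
#' of module m has latent expression
#' `x[g, j] = sqrt(rho) * z[m, j] + sqrt(1 - rho) * e[g, j]`
#' with `e ~ N(0, 1)`, so any two genes of the module correlate at rho on the
#' latent scale.  Counts are drawn as
#' `NB(mu = L[j] * exp(x[g, j] + b[g]), size = 1 / dispersion)`
#' with per-sample library size `L[j]` and gene baseline `b[g]`.
#' Noise genes carry no shared factor (x = e).
#'
#' @param config A [synthetic_config()] object.
#' @return A list with:
#'   \describe{
#'     \item{counts}{integer gene-by-sample matrix with gene/sample dimnames}
#'     \item{design}{the [generate_stage_design()] output}
#'     \item{truth}{a truth record: `module` (named gene-to-module map,
#'       `"none"` for noise genes), `module_stage` (module-to-stage map),
#'       `latent` (module-by-sample latent factor matrix), and
#'       `library_size`}
#'   }
#' @export
generate_count_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  n_s <- config$n_samples
  sd <- generate_stage_design(config)
  gene_id <- sprintf("gene%04d", seq_len(n_g))

  module_of <- rep("none", n_g)
  mod_names <- if (config$n_modules > 0L) sprintf("M%02d", seq_len(config$n_modules)) else character(0)
  if (config$n_modules > 0L) {
    idx <- 1L
    for (m in seq_len(config$n_modules)) {
      module_of[idx:(idx + config$module_sizes[m] - 1L)] <- mod_names[m]
      idx <- idx + config$module_sizes[m]
    }
  }
  names(module_of) <- gene_id
  module_stage <- stats::setNames(config$stage_association, mod_names)

  lib <- stats::runif(n_s, config$library_size_range[1], config$library_size_range[2])
  names(lib) <- sd$design$sample

  # latent module factors, shifted in the associated stage's samples
  rho <- config$within_module_correlation
  latent <- matrix(0, nrow = config$n_modules, ncol = n_s,
                   dimnames = list(mod_names, sd$design$sample))
  for (m in seq_along(mod_names)) {
    shift <- config$stage_effect * (as.character(sd$design$stage) == module_stage[m])
    latent[m, ] <- stats::rnorm(n_s, mean = shift, sd = 1)
  }

  baseline <- stats::rnorm(n_g, mean = log(1 / n_g), sd = 0.5)
  noise <- matrix(stats::rnorm(n_g * n_s), nrow = n_g)
  x <- sqrt(1 - rho) * noise
  for (m in seq_along(mod_names)) {
    in_m <- module_of == mod_names[m]
    x[in_m, ] <- sqrt(rho) * matrix(latent[m, ], sum(in_m), n_s, byrow = TRUE) +
      sqrt(1 - rho) * noise[in_m, , drop = FALSE]
  }
  # noise genes keep unit-variance idiosyncratic latents
  is_noise <- module_of == "none"
  if (any(is_noise)) x[is_noise, ] <- noise[is_noise, , drop = FALSE]

  mu <- exp(sweep(x + baseline, 2, log(lib), "+"))
  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu, size = 1 / config$dispersion),
                   nrow = n_g, dimnames = list(gene_id, sd$design$sample))
  storage.mode(counts) <- "integer"

  list(counts = counts,
       design = sd,
       truth = list(module = module_of,
                    module_stage = module_stage,
                    latent = latent,
                    library_size = lib))
}

#' Configuration for the synthetic interaction-network generator
#'
#' Planted-partition style generator for an undirected gene interaction
#' network: dense planted clusters (each seeded with a fixed number of
#' regulatory genes) over a sparse Erdos-Renyi background.  Non-regulatory
#' cluster members are drawn independently per cluster, so a node may belong
#' to two planted clusters -- the overlap case that overlapping graph
#' clustering must handle.  Defaults mirror a 338-node network with 30
#' regulatory genes and roughly 1150-1200 edges.
#'
#' @param n_nodes Number of nodes.
#' @param n_regulatory Number of nodes labelled regulatory (must be <=
#'   `n_nodes`).
#' @param n_planted_clusters Number of planted dense clusters.
#' @param planted_cluster_size Nodes per planted cluster.
#' @param planted_regulatory_per_cluster Regulatory genes planted inside each
#'   cluster; `n_planted_clusters * planted_regulatory_per_cluster` must not
#'   exceed `n_regulatory`.
#' @param intra_cluster_edge_prob Edge probability within a planted cluster,
#'   in (0, 1].
#' @param background_edge_prob Edge probability between any node pair outside
#'   the planted structure, in \[0, 1).
#' @param seed Integer seed.
#' @return An object of class `synthetic_network_config`.
#' @export
synthetic_network_config <- function(n_nodes = 338L,
                                     n_regulatory = 30L,
                                     n_planted_clusters = 5L,
                                     planted_cluster_size = 12L,
                                     planted_regulatory_per_cluster = 4L,
                                     intra_cluster_edge_prob = 1.0,
                                     background_edge_prob = 0.015,
                                     seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  n_regulatory <- as.integer(n_regulatory)
  n_planted_clusters <- as.integer(n_planted_clusters)
  planted_cluster_size <- as.integer(planted_cluster_size)
  planted_regulatory_per_cluster <- as.integer(planted_regulatory_per_cluster)
  if (n_nodes < 1L) stop("configuration error in field 'n_nodes': must be positive")
  if (n_regulatory < 0L || n_regulatory > n_nodes)
    stop("configuration error in field 'n_regulatory': must satisfy 0 <= n_regulatory <= n_nodes")
  if (n_planted_clusters < 0L)
    stop("configuration error in field 'n_planted_clusters': must be non-negative")
  if (n_planted_clusters > 0L && planted_cluster_size < 1L)
    stop("configuration error in field 'planted_cluster_size': must be positive")
  if (planted_regulatory_per_cluster < 0L ||
      planted_regulatory_per_cluster > planted_cluster_size)
    stop("configuration error in field 'planted_regulatory_per_cluster': must satisfy 0 <= value <= planted_cluster_size")
  if (n_planted_clusters * planted_regulatory_per_cluster > n_regulatory)
    stop("configuration error in field 'planted_regulatory_per_cluster': ",
         n_planted_clusters, " x ", planted_regulatory_per_cluster,
         " planted regulatory genes exceed n_regulatory = ", n_regulatory)
  if (n_planted_clusters > 0L && planted_cluster_size > n_nodes)
    stop("configuration error in field 'planted_cluster_size': exceeds n_nodes")
  if (!(intra_cluster_edge_prob > 0 && intra_cluster_edge_prob <= 1))
    stop("configuration error in field 'intra_cluster_edge_prob': must lie in (0,1]")
  if (!(background_edge_prob >= 0 && background_edge_prob < 1))
    stop("configuration error in field 'background_edge_prob': must lie in [0,1)")
  structure(list(
    n_nodes = n_nodes,
    n_regulatory = n_regulatory,
    n_planted_clusters = n_planted_clusters,
    planted_cluster_size = planted_cluster_size,
    planted_regulatory_per_cluster = planted_regulatory_per_cluster,
    intra_cluster_edge_prob = intra_cluster_edge_prob,
    background_edge_prob = background_edge_prob,
    seed = as.integer(seed)
  ), class = "synthetic_network_config")
}

#' Generate a synthetic interaction network with planted clusters
#'
#' Produces a simple undirected graph (no self-loops, no duplicate edges) as
#' an edge list, a regulatory label set of exactly `n_regulatory` genes, and
#' the planted truth.  Each planted cluster receives
#' `planted_regulatory_per_cluster` distinct regulatory genes (disjoint
#' across clusters) plus non-regulatory members sampled independently per
#' cluster, then internal pairs are wired with probability
#' `intra_cluster_edge_prob`; all remaining pairs are wired with probability
#' `background_edge_prob`.
#'
#' @param config A [synthetic_network_config()] object.
#' @param node_names Optional character vector of length `n_nodes` supplying
#'   the node IDs (e.g. gene IDs shared with an expression matrix); defaults
#'   to `node0001`, `node0002`, ...
#' @return A list with:
#'   \describe{
#'     \item{edges}{data.frame of `from`, `to` (character node IDs,
#'       `from < to` lexicographically)}
#'     \item{nodes}{character vector of all node IDs (isolated nodes
#'       included)}
#'     \item{regulatory}{character vector of regulatory node IDs}
#'     \item{truth}{list with `clusters` (list of planted-cluster node
#'       vectors) and `regulatory_in_clusters` (regulatory genes planted
#'       inside clusters)}
#'   }
#' @export
generate_interaction_network <- function(config, node_names = NULL) {
  stopifnot(inherits(config, "synthetic_network_config"))
  set.seed(config$seed)
  if (is.null(node_names)) {
    nodes <- sprintf("node%04d", seq_len(config$n_nodes))
  } else {
    node_names <- as.character(node_names)
    if (length(node_names) != config$n_nodes || anyDuplicated(node_names))
      stop("node_names must be ", config$n_nodes, " unique IDs")
    nodes <- node_names
  }
  regulatory <- sort(sample(nodes, config$n_regulatory))
  non_regulatory <- setdiff(nodes, regulatory)

  clusters <- list()
  reg_pool <- regulatory
  for (k in seq_len(config$n_planted_clusters)) {
    n_reg <- config$planted_regulatory_per_cluster
    reg_members <- if (n_reg > 0L) sample(reg_pool, n_reg) else character(0)
    reg_pool <- setdiff(reg_pool, reg_members)
    n_other <- config$planted_cluster_size - n_reg
    other <- if (n_other > 0L) sample(non_regulatory, n_other) else character(0)
    clusters[[k]] <- sort(c(reg_members, other))
  }

  edge_key <- character(0)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  for (cl in clusters) {
    if (length(cl) < 2L) next
    pairs <- utils::combn(cl, 2L)
    keep <- stats::runif(ncol(pairs)) < config$intra_cluster_edge_prob
    edge_key <- c(edge_key, pair_key(pairs[1, keep], pairs[2, keep]))
  }
  if (config$background_edge_prob > 0 && config$n_nodes >= 2L) {
    pairs <- utils::combn(nodes, 2L)
    keep <- stats::runif(ncol(pairs)) < config$background_edge_prob
    edge_key <- c(edge_key, pair_key(pairs[1, keep], pairs[2, keep]))
  }
  edge_key <- sort(unique(edge_key))
  if (length(edge_key)) {
    parts <- strsplit(edge_key, "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }

  list(edges = edges,
       nodes = nodes,
       regulatory = regulatory,
       truth = list(clusters = clusters,
                    regulatory_in_clusters =
                      intersect(regulatory, unique(unlist(clusters)))))
}
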