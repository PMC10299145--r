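#' Pipeline configuration
#'
#' Collects the input paths and every stage parameter of the end-to-end
#' workflow (preprocess, network construction, module detection, overlapping
#' clustering, prioritisation, optional gene-set enrichment), with the
#' conventional defaults.  Unknown parameter names are rejected.
#'
#' @param counts Path to the counts TSV.
#' @param design Path to the sample/stage design TSV.
#' @param edges Path to the interaction edge list (TSV or SIF).
#' @param labels Path to the regulatory-gene label list.
#' @param outdir Output directory (created if absent).
#' @param gene_sets Optional path to a GMT collection for the enrichment
#'   stage.
#' @param stage Stage whose positively associated modules are the key
#'   modules; defaults to the design's second stage (the larval stage in the
#'   default synthetic layout) if `NULL`.
#' @param ... Stage parameters overriding the defaults: `min_total` (10),
#'   `variance_quantile` (0.95), `pseudocount` (1), `power` (NULL = pick by
#'   scale-free fit), `powers` (candidate scan), `r2_target` (0.80),
#'   `min_module_size` (30), `merge_cut_height` (0.25), `cut_quantile`
#'   (0.95), `min_kme` (0.5, module-membership pruning), `kme_threshold`
#'   (0.80), `densities` (0.5..0.9), `cp_min` (0.5),
#'   `min_cluster_size` (2), `alpha` (0.05), `restrict_to_hubs` (TRUE),
#'   `min_count` (3), `min_enrichment` (1.5).
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, edges, labels, outdir,
                            gene_sets = NULL, stage = NULL, seed = 1L, ...) {
  params <- list(min_total = 10L, variance_quantile = 0.95, pseudocount = 1,
                 power = NULL, powers = c(1:10, 12, 14, 16, 18, 20),
                 r2_target = 0.80, min_module_size = 30L,
                 merge_cut_height = 0.25, cut_quantile = 0.95,
                 min_kme = 0.5, kme_threshold = 0.80,
                 densities = c(0.5, 0.6, 0.7, 0.8, 0.9), cp_min = 0.5,
                 min_cluster_size = 2L, alpha = 0.05,
                 restrict_to_hubs = TRUE, min_count = 3L,
                 min_enrichment = 1.5)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(params))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  params[names(extra)] <- extra
  structure(c(list(paths = list(counts = counts, design = design,
                                edges = edges, labels = labels,
                                gene_sets = gene_sets, outdir = outdir),
                   stage = stage, seed = as.integer(seed)),
              params),
            class = "pipeline_config")
}

# internal: md5 of a written artifact, NA when absent
.checksum <- function(path) {
  if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
}

#' Run the end-to-end prioritisation pipeline
#'
#' Executes: count filtering and normalisation -> high-variance gene
#' selection -> signed network and module detection -> module-stage
#' correlation and hub-gene selection -> (optional) restriction of the
#' supplied interaction network to hub genes -> overlapping clustering over
#' the density sweep -> regulatory-gene enrichment, SScores and ROC/AUC per
#' density -> candidate extraction at the best density -> (optional)
#' gene-set enrichment of the candidates.  Every intermediate artifact is
#' written under `outdir`, and a JSON manifest records the configuration,
#' per-stage counts and artifact checksums.
#'
#' A stage failure aborts with the failing stage named; artifacts written
#' before the failure are retained next to a `FAILED` marker file.
#'
#' @param config A [pipeline_config()] object.
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- config$paths
  required <- c(counts = paths$counts, design = paths$design,
                edges = paths$edges, labels = paths$labels)
  missing <- required[!file.exists(required)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "))
  if (!is.null(paths$gene_sets) && !file.exists(paths$gene_sets))
    stop("missing input file(s): gene_sets = ", paths$gene_sets)
  dir.create(paths$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(paths$outdir, f)
  set.seed(config$seed)

  manifest <- list(package_version = as.character(utils::packageVersion("coexreg")),
                   seed = config$seed,
                   parameters = unclass(config)[setdiff(names(config), "paths")],
                   counts = list(), artifacts = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                 out("FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- run_stage("read inputs", {
    list(counts = read_counts(paths$counts),
         design = read_design(paths$design),
         edges = read_edges(paths$edges),
         labels = read_labels(paths$labels),
         gene_sets = if (!is.null(paths$gene_sets)) read_gmt(paths$gene_sets))
  })
  manifest$counts$genes_input <- nrow(inputs$counts)
  manifest$counts$samples <- ncol(inputs$counts)

  expr <- run_stage("preprocess", {
    filtered <- filter_low_counts(inputs$counts, config$min_total)
    manifest$counts$genes_after_filter <- nrow(filtered)
    sf <- estimate_size_factors(filtered)
    vst <- vst_transform(filtered, sf, config$pseudocount)
    sel <- select_high_variance(vst, config$variance_quantile)
    manifest$counts$genes_selected <- nrow(sel)
    write_matrix_tsv(round(sel, 6), out("expression_selected.tsv"))
    message("preprocess: ", nrow(filtered), "/", nrow(inputs$counts),
            " genes pass the count filter; ", nrow(sel), " high-variance genes kept")
    sel
  })

  net <- run_stage("wgcna", {
    if (is.null(config$power)) {
      st <- pick_soft_threshold(expr, powers = config$powers,
                                r2_target = config$r2_target)
      power <- st$power
      utils::write.table(st$table, out("soft_threshold.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      power <- config$power
    }
    adj <- signed_adjacency(expr, power)
    tom <- tom_similarity(adj)
    assignment <- detect_modules(1 - tom,
                                 min_module_size = config$min_module_size,
                                 cut_quantile = config$cut_quantile)
    labels <- merge_close_modules(expr, assignment,
                                  merge_cut_height = config$merge_cut_height)
    labels <- prune_modules(expr, labels, min_kme = config$min_kme)
    n_mod <- length(setdiff(unique(labels), "grey"))
    manifest$counts$modules <- n_mod
    manifest$counts$power <- power
    message("wgcna: power ", power, "; ", n_mod, " module(s) after merging")
    if (n_mod == 0) stop("no module passed min_module_size")
    me <- module_eigengenes(expr, labels)
    mtc <- module_trait_correlation(me, inputs$design$indicator)
    stage <- config$stage
    if (is.null(stage)) {
      lv <- levels(inputs$design$design$stage)
      stage <- if (length(lv) >= 2) lv[2] else lv[1]
    }
    key <- select_key_modules(mtc, stage, alpha = config$alpha)
    kme <- module_membership(expr, me)
    hubs <- select_hub_genes(kme, labels, threshold = config$kme_threshold)
    write_matrix_tsv(round(me, 6), out("eigengenes.tsv"))
    utils::write.table(
      data.frame(gene = names(labels), module = unname(labels),
                 kme = vapply(seq_along(labels), function(i) {
                   m <- labels[[i]]
                   if (m %in% colnames(kme)) kme[names(labels)[i], m] else NA_real_
                 }, numeric(1))),
      out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(module = rownames(mtc$r), round(mtc$r, 4),
                 check.names = FALSE),
      out("module_trait_r.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$key_modules <- length(key)
    manifest$counts$hub_genes <- length(unique(unlist(hubs)))
    message("wgcna: key module(s) for stage '", stage, "': ",
            if (length(key)) paste(key, collapse = ", ") else "(none)")
    list(labels = labels, me = me, mtc = mtc, key = key,
         hubs = hubs, stage = stage)
  })

  graph <- run_stage("hub restriction", {
    edges <- inputs$edges
    nodes <- sort(unique(c(edges$from, edges$to)))
    if (isTRUE(config$restrict_to_hubs)) {
      hub_union <- unique(unlist(net$hubs, use.names = FALSE))
      in_hubs <- intersect(nodes, hub_union)
      if (length(in_hubs)) {
        edges <- edges[edges$from %in% hub_union & edges$to %in% hub_union, ,
                       drop = FALSE]
        nodes <- in_hubs
      } else {
        message("hub restriction: no network node is a hub gene; clustering the full network")
      }
    }
    manifest$counts$network_nodes <- length(nodes)
    manifest$counts$network_edges <- nrow(edges)
    write_edges(edges, out("network_clustered.tsv"))
    list(edges = edges, nodes = nodes)
  })

  sweep <- run_stage("dpcluso", {
    sw <- dpcluso_sweep(graph$edges, densities = config$densities,
                        cp_min = config$cp_min,
                        min_cluster_size = config$min_cluster_size,
                        nodes = graph$nodes)
    manifest$counts$clusters_per_density <-
      lapply(sw, function(cs) length(cs$clusters))
    for (d in names(sw))
      write_clusters(sw[[d]], out(sprintf("clusters_d%s.tsv", d)))
    message("dpcluso: clusters per density: ",
            paste(names(sw), vapply(sw, function(cs) length(cs$clusters), integer(1)),
                  sep = "=", collapse = ", "))
    sw
  })

  prior <- run_stage("prioritize", {
    background <- graph$nodes
    labels_in_bg <- intersect(inputs$labels, background)
    if (!length(labels_in_bg))
      stop("no regulatory label occurs in the clustered network")
    ev <- evaluate_density_sweep(sweep, labels_in_bg, background)
    best <- format(ev$best_density, trim = TRUE)
    enr <- ev$by_density[[best]]$enrichment
    sig <- significant_clusters(enr, alpha = config$alpha)
    scores <- ev$by_density[[best]]$scores
    cand <- candidate_regulatory_genes(sig, sweep[[best]], labels_in_bg, scores)
    utils::write.table(data.frame(density = names(ev$auc), auc = unname(ev$auc)),
                       out("auc_by_density.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(enr, out("enrichment_best_density.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(scores, out("sscores_best_density.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ev$by_density[[best]]$roc$points, out("roc_best_density.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    utils::write.table(cand, out("candidates.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$counts$auc_by_density <- as.list(ev$auc)
    manifest$counts$best_density <- ev$best_density
    manifest$counts$significant_clusters <- nrow(sig)
    manifest$counts$candidates <- nrow(cand)
    message("prioritize: best density ", ev$best_density, " (AUC ",
            signif(ev$auc[[best]], 3), "); ", nrow(sig),
            " significant cluster(s); ", nrow(cand), " candidate gene(s)")
    list(ev = ev, sig = sig, cand = cand, background = background)
  })

  if (!is.null(inputs$gene_sets)) {
    run_stage("genesets", {
      res <- enrich(prior$cand$gene, inputs$gene_sets, prior$background,
                    min_count = config$min_count,
                    min_enrichment = config$min_enrichment,
                    alpha = config$alpha)
      utils::write.table(res, out("geneset_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest$counts$enriched_sets <- nrow(res)
      message("genesets: ", nrow(res), " enriched set(s)")
    })
  }

  artifacts <- list.files(paths$outdir, full.names = FALSE)
  artifacts <- setdiff(artifacts, "manifest.json")
  manifest$artifacts <- lapply(
    stats::setNames(file.path(paths$outdir, artifacts), artifacts), .checksum)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
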