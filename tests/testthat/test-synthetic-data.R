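test_that("count generation is deterministic and respects the config contract", {
  cfg <- synthetic_config(seed = 7)
  a <- generate_count_matrix(cfg)
  b <- generate_count_matrix(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)

  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_identical(dim(a$counts), c(250L, 9L))
  # every gene appears exactly once in the module map
  expect_identical(sort(names(a$truth$module)), sort(rownames(a$counts)))
  expect_identical(as.integer(table(a$truth$module)[c("M01", "none")]), c(50L, 50L))
})

test_that("planted modules are elevated in their associated stage", {
  cfg <- synthetic_config(seed = 11)
  sim <- generate_count_matrix(cfg)
  v <- vst_transform(sim$counts)
  in_stage <- sim$design$design$stage == "larva3"
  m2 <- v[sim$truth$module == "M02", ]
  expect_gt(mean(m2[, in_stage]) - mean(m2[, !in_stage]), 0.5)
})

test_that("within-module correlation survives count noise and the log transform", {
  mean_cor <- vapply(1:20, function(s) {
    sim <- generate_count_matrix(synthetic_config(seed = s))
    v <- vst_transform(sim$counts)
    cm <- stats::cor(t(v[sim$truth$module == "M01", ]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_gt(mean(mean_cor), 0.6)
  expect_gte(sum(mean_cor > 0.6), 18)
})

test_that("all-noise configuration yields no detectable modules", {
  n_nograle <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_genes = 120L, module_sizes = integer(0),
                            stage_association = character(0),
                            noise_gene_fraction = 1.0, seed = s)
    sim <- generate_count_matrix(cfg)
    expect_true(all(sim$truth$module == "none"))
    v <- vst_transform(sim$counts)
    tom <- tom_similarity(signed_adjacency(v, 6))
    ma <- detect_modules(1 - tom, min_module_size = 30)
    lab <- prune_modules(v, merge_close_modules(v, ma))
    length(setdiff(unique(lab), "grey"))
  }, numeric(1))
  expect_gte(sum(n_nograle == 0), 18)
})

test_that("configuration errors name the offending field", {
  expect_error(synthetic_config(n_genes = 100, module_sizes = rep(50, 4)),
               "module_sizes")
  expect_error(synthetic_config(noise_gene_fraction = 0.5), "noise_gene_fraction")
  expect_error(synthetic_config(stage_association = rep("embryo", 4)),
               "stage_association")
  expect_error(synthetic_config(within_module_correlation = 1),
               "within_module_correlation")
  expect_error(synthetic_config(stages = c(2, 3, 2, 2)), "stages")
})

test_that("stage design lays out samples and indicators per stage", {
  cfg <- synthetic_config()
  sd <- generate_stage_design(cfg)
  expect_identical(nrow(sd$design), 9L)
  expect_identical(dim(sd$indicator), c(9L, 4L))
  expect_identical(as.integer(colSums(sd$indicator)), c(2L, 3L, 2L, 2L))
  expect_true(all(rowSums(sd$indicator) == 1))

  one <- synthetic_config(stages = c(larva3 = 4L), n_genes = 60,
                          module_sizes = c(30L), stage_association = "larva3")
  sd1 <- generate_stage_design(one)
  expect_identical(unname(sd1$indicator[, 1]), rep(1L, 4))
  expect_error(synthetic_config(stages = integer(0)), "stages")
})

test_that("network generation is deterministic, simple, and conserves labels", {
  cfg <- synthetic_network_config(seed = 5)
  a <- generate_interaction_network(cfg)
  b <- generate_interaction_network(cfg)
  expect_identical(a, b)

  expect_length(a$regulatory, 30L)
  expect_true(all(a$edges$from != a$edges$to))
  key <- paste(a$edges$from, a$edges$to)
  expect_false(any(duplicated(key)))
  # planted-cluster density within tolerance of the intra-cluster probability
  for (cl in a$truth$clusters)
    expect_gte(cluster_density(cl, a$edges),
               cfg$intra_cluster_edge_prob - 0.15)
})

test_that("network corner cases behave as configured", {
  # probability-1 edges: 5 planted nodes form a complete subgraph
  cfg <- synthetic_network_config(n_nodes = 20, n_regulatory = 5,
                                  n_planted_clusters = 1,
                                  planted_cluster_size = 5,
                                  planted_regulatory_per_cluster = 2,
                                  intra_cluster_edge_prob = 1.0,
                                  background_edge_prob = 0, seed = 2)
  net <- generate_interaction_network(cfg)
  expect_identical(nrow(net$edges), 10L)
  expect_identical(cluster_density(net$truth$clusters[[1]], net$edges), 1)

  # no background, no clusters: empty edge list
  empty <- generate_interaction_network(
    synthetic_network_config(n_nodes = 10, n_regulatory = 2,
                             n_planted_clusters = 0, background_edge_prob = 0,
                             seed = 1))
  expect_identical(nrow(empty$edges), 0L)

  # infeasible regulatory placement surfaces as a configuration error
  expect_error(
    synthetic_network_config(n_planted_clusters = 10, planted_cluster_size = 12,
                             planted_regulatory_per_cluster = 8),
    "planted_regulatory_per_cluster")
  expect_error(synthetic_network_config(n_regulatory = 400), "n_regulatory")
})

test_that("stronger within-module correlation improves module recovery", {
  skip_if_not_installed("mclust")
  recover <- function(rho, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- synthetic_config(n_genes = 120L, module_sizes = rep(40L, 2L),
                              stages = c(egg = 3L, larva3 = 3L, pupa = 3L),
                              stage_association = c("egg", "larva3"),
                              within_module_correlation = rho, seed = s)
      sim <- generate_count_matrix(cfg)
      v <- vst_transform(sim$counts)
      tom <- tom_similarity(signed_adjacency(v, 8))
      ma <- detect_modules(1 - tom, min_module_size = 20)
      lab <- prune_modules(v, ma$labels, min_module_size = 20)
      mclust::adjustedRandIndex(lab, sim$truth$module)
    }, numeric(1)))
  }
  seeds <- 1:20
  expect_lt(recover(0.35, seeds), recover(0.9, seeds))
})
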