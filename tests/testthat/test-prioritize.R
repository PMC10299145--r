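test_that("cluster enrichment equals exhaustive draw enumeration", {
  bg <- paste0("g", 1:10)
  labels <- bg[1:5]
  cl <- bg[c(1, 2, 3, 4)]
  ce <- cluster_enrichment(cl, labels, bg)
  # all C(10,4) draws, counting those with >= 4 labelled genes
  draws <- utils::combn(bg, 4)
  n_hit <- sum(apply(draws, 2, function(d) sum(d %in% labels) >= 4))
  expect_equal(ce$p_value, n_hit / ncol(draws), tolerance = 1e-12)
  expect_equal(ce$p_value, 5 / 210, tolerance = 1e-12)
  expect_identical(unname(ce$table), c(4L, 0L, 1L, 5L))

  # all genes regulatory: p = 1
  expect_equal(cluster_enrichment(cl, bg, bg)$p_value, 1)
  # no regulatory member: p computed normally, <= 1
  p0 <- cluster_enrichment(bg[6:9], labels, bg)$p_value
  expect_lte(p0, 1)
  expect_error(cluster_enrichment(cl, labels, character(0)), "background")
  expect_error(cluster_enrichment(c(cl, "zz"), labels, bg), "outside")
})

test_that("the hypergeometric kernel agrees with fisher.test one-sided p", {
  set.seed(17)
  for (i in 1:15) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    bg <- paste0("g", 1:N)
    labels <- bg[1:K]
    cl <- sample(bg, n)
    a <- sum(cl %in% labels)
    ce <- cluster_enrichment(cl, labels, bg)
    ft <- stats::fisher.test(matrix(c(a, n - a, K - a, N - K - (n - a)), 2),
                             alternative = "greater")
    expect_equal(ce$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("SScores take -log10 of the best containing cluster's p-value", {
  bg <- paste0("g", 1:8)
  cs <- make_cluster_set(list(c("g1", "g2"), c("g2", "g3")))
  enr <- data.frame(cluster = 1:2, p_value = c(0.01, 0.001))
  sc <- sscore_table(cs, enr, bg)
  sc <- stats::setNames(sc$sscore, sc$gene)
  expect_equal(sc[["g1"]], 2)        # only in cluster 1
  expect_equal(sc[["g2"]], 3)        # lowest p of the two clusters
  expect_equal(sc[["g4"]], 0)        # uncovered
})

test_that("ROC endpoints, known AUC values and error cases", {
  # perfect separation
  s <- stats::setNames(c(5, 4, 1, 0), paste0("g", 1:4))
  r <- roc_curve(s, c("g1", "g2"))
  expect_equal(r$auc, 1)
  expect_equal(r$points$tpr[1], 0); expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_equal(r$points$fpr[nrow(r$points)], 1)

  # all scores equal: chance AUC
  flat <- stats::setNames(rep(2, 6), paste0("g", 1:6))
  expect_equal(roc_curve(flat, c("g1", "g2"))$auc, 0.5)

  expect_error(roc_curve(s, character(0)), "positive")
  expect_error(roc_curve(s, names(s)), "negative")
})

test_that("TPR/FPR are non-decreasing and AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    sc <- stats::setNames(round(stats::runif(60), 2), paste0("g", 1:60))
    pos <- sample(names(sc), 20)
    r <- roc_curve(sc, pos)
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_true(all(diff(r$points$fpr) >= 0))
    ref <- pROC::auc(pROC::roc(response = names(sc) %in% pos,
                               predictor = unname(sc), quiet = TRUE,
                               direction = "<"))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  sc <- stats::setNames(stats::rexp(80), paste0("g", 1:80))
  pos <- sample(names(sc), 25)
  base <- roc_curve(sc, pos)$auc
  expect_equal(roc_curve(sc^2, pos)$auc, base, tolerance = 1e-12)
  expect_equal(roc_curve(log1p(sc), pos)$auc, base, tolerance = 1e-12)
  expect_equal(roc_curve(sc * 100 + 3, pos)$auc, base, tolerance = 1e-12)
})

test_that("scores uncorrelated with labels give chance-level AUC", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    sc <- stats::setNames(stats::runif(1000), paste0("g", 1:1000))
    pos <- sample(names(sc), 100)
    auc <- roc_curve(sc, pos)$auc
    auc > 0.4 && auc < 0.6
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("best-density selection maximises AUC with ties to the smaller density", {
  expect_equal(select_best_density(
    c("0.5" = 0.913, "0.6" = 0.950, "0.7" = 0.824, "0.8" = 0.947, "0.9" = 0.934)),
    0.6)
  expect_equal(select_best_density(c("0.7" = 0.2)), 0.7)
  expect_equal(select_best_density(c("0.5" = 0.9, "0.6" = 0.9)), 0.5)
  expect_error(select_best_density(numeric(0)), "empty")
})

test_that("significant clusters use a strict alpha and candidates rank by SScore", {
  enr <- data.frame(cluster = 1:2, p_value = c(0.04, 0.06))
  expect_identical(significant_clusters(enr, 0.05)$cluster, 1L)

  bg <- paste0("g", 1:20)
  cs <- make_cluster_set(list(c("g1", "g2", "g3"), c("g4", "g5")))
  enr <- data.frame(cluster = 1:2, p_value = c(0.001, 0.04))
  sig <- significant_clusters(enr)
  sc <- sscore_table(cs, enr, bg)
  cand <- candidate_regulatory_genes(sig, cs, c("g2", "g4", "g9"), sc)
  expect_identical(cand$gene, c("g2", "g4"))   # g2 has the better SScore
  expect_identical(cand$best_cluster, c(1L, 2L))

  none <- candidate_regulatory_genes(sig, cs, "g9", sc)
  expect_identical(nrow(none), 0L)
})

test_that("the separable planted network yields AUC exactly 1", {
  # clean background, planted cliques made entirely of regulatory genes
  cfg <- synthetic_network_config(n_nodes = 100, n_regulatory = 30,
                                  n_planted_clusters = 3,
                                  planted_cluster_size = 10,
                                  planted_regulatory_per_cluster = 10,
                                  intra_cluster_edge_prob = 1.0,
                                  background_edge_prob = 0, seed = 8)
  net <- generate_interaction_network(cfg)
  sw <- dpcluso_sweep(net$edges, nodes = net$nodes)
  ev <- evaluate_density_sweep(sw, net$regulatory, net$nodes)
  expect_true(all(ev$auc == 1))
})
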