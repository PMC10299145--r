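test_that("signed adjacency follows the soft-threshold formula", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),     # cor +1
             c = c(4, 3, 2, 1),                         # cor -1 with a
             d = c(1, -1, -1, 1))                       # cor 0 with a
  adj <- signed_adjacency(x, 12)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  expect_equal(adj["a", "d"], (1 / 2)^12)
  expect_true(isSymmetric(adj))
  expect_equal(unname(diag(adj)), rep(1, 4))
})

test_that("adjacency decreases monotonically in the power for cor < 1", {
  set.seed(2)
  x <- matrix(rnorm(6 * 10), 6, 10)
  a1 <- signed_adjacency(x, 2); a2 <- signed_adjacency(x, 6)
  off <- upper.tri(a1)
  expect_true(all(a2[off] <= a1[off]))
  expect_warning(signed_adjacency(rbind(x, 0), 2), "zero-variance")
})

test_that("TOM matches hand calculations and the brute-force oracle", {
  tri <- matrix(c(1, 1, 1,
                  1, 1, 1,
                  1, 1, 1), 3, 3)
  expect_equal(tom_similarity(tri)[1, 2], 1)   # (1 + 1) / (2 + 1 - 1)

  # isolated pair: no direct edge, no shared neighbour
  iso <- diag(4)
  expect_equal(tom_similarity(iso)[1, 2], 0)

  set.seed(5)
  for (n in c(8, 15)) {
    adj <- random_adjacency(n)
    expect_lt(max(abs(tom_similarity(adj) - brute_force_tom(adj))), 1e-12)
  }
  expect_error(tom_similarity(matrix(runif(12), 3, 4)), "square")
})

test_that("soft-threshold selection honours the target and fallback rules", {
  set.seed(4)
  sim <- generate_count_matrix(synthetic_config(seed = 4))
  v <- vst_transform(filter_low_counts(sim$counts))
  st <- pick_soft_threshold(v)
  expect_gte(st$table$fit_index[st$table$power == st$power], 0.80)

  # r2_target = 0 chooses the smallest candidate
  st0 <- pick_soft_threshold(v, powers = c(3, 6, 9), r2_target = 0)
  expect_identical(st0$power, 3)

  # a single candidate is chosen regardless, warning when below target
  expect_warning(st1 <- pick_soft_threshold(v, powers = 1, r2_target = 0.99),
                 "target")
  expect_identical(st1$power, 1)
})

test_that("planted blocks are recovered exactly from a block TOM", {
  skip_if_not_installed("mclust")
  set.seed(10)
  fx <- block_expression(c(50, 50), rho = 0.9, n_samples = 30)
  tom <- tom_similarity(signed_adjacency(fx$expr, 6))
  ma <- detect_modules(1 - tom, min_module_size = 30)
  lab <- prune_modules(fx$expr, ma)
  expect_identical(length(setdiff(unique(lab), "grey")), 2L)
  expect_equal(mclust::adjustedRandIndex(lab, fx$truth), 1)
})

test_that("module assignment honours min_module_size and the grey contract", {
  set.seed(11)
  fx <- block_expression(c(20, 20), rho = 0.9, n_samples = 10)
  tom <- tom_similarity(signed_adjacency(fx$expr, 6))
  # min size 1: nothing can be grey
  ma1 <- detect_modules(1 - tom, min_module_size = 1)
  expect_false("grey" %in% ma1$labels)
  # more genes required than present: everything grey, with a warning
  expect_warning(ma2 <- detect_modules(1 - tom, min_module_size = 100),
                 "min_module_size")
  expect_true(all(ma2$labels == "grey"))
})

test_that("eigengenes summarise modules and recover planted factors", {
  # identical profiles: eigengene correlates perfectly with the profile
  prof <- c(1, 3, 2, 5, 4, 6)
  x <- matrix(rep(prof, 5), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  lab <- stats::setNames(rep("blue", 5), rownames(x))
  me <- module_eigengenes(x, lab)
  expect_equal(abs(stats::cor(me["blue", ], prof)), 1, tolerance = 1e-12)
  expect_gte(stats::cor(me["blue", ], prof), 0)   # sign orientation
  expect_equal(stats::sd(me["blue", ]), 1, tolerance = 1e-12)

  # one-gene module: the z-scored profile
  one <- x[1, , drop = FALSE]
  me1 <- module_eigengenes(one, stats::setNames("red", "g1"))
  expect_equal(unname(me1["red", ]), as.numeric(scale(prof)), tolerance = 1e-12)

  # planted factor recovery on the default synthetic fixture
  cors <- vapply(1:20, function(s) {
    sim <- generate_count_matrix(synthetic_config(seed = s))
    v <- vst_transform(sim$counts)
    me <- module_eigengenes(v, sim$truth$module)
    abs(stats::cor(me["M01", ], sim$truth$latent["M01", ]))
  }, numeric(1))
  expect_gte(mean(cors), 0.9)
  expect_true(all(cors >= 0.8))
})

test_that("eigengene merging restores split modules and respects orthogonality", {
  set.seed(13)
  fx <- block_expression(c(60, 60), rho = 0.9, n_samples = 12)
  # split block 1 in half artificially
  lab <- fx$truth
  lab[lab == "B1"] <- rep(c("B1a", "B1b"), each = 30)
  lab[lab == "none"] <- "grey"
  merged <- merge_close_modules(fx$expr, lab)
  mods <- setdiff(unique(merged), "grey")
  expect_identical(length(mods), 2L)
  # the two halves ended up in one module
  halves <- merged[names(fx$truth)[fx$truth == "B1"]]
  expect_identical(length(unique(halves)), 1L)

  # merge height 0 is the identity
  expect_identical(merge_close_modules(fx$expr, lab, 0), lab)
  # orthogonal planted factors do not merge
  expect_identical(sort(unique(merge_close_modules(fx$expr, fx$truth)[
    fx$truth != "none"])), c("B1", "B2"))
})

test_that("module-trait correlation reproduces exact r and p cases", {
  ind <- cbind(stageA = c(1, 1, 1, 0, 0, 0), stageB = c(0, 0, 0, 1, 1, 1))
  me <- rbind(m1 = drop(scale(ind[, "stageA"])),
              m2 = c(1, -1, 0, 0, 1, -1))   # orthogonal to both indicators
  mtc <- module_trait_correlation(me, ind)
  expect_equal(mtc$r["m1", "stageA"], 1, tolerance = 1e-12)
  expect_equal(mtc$r["m2", "stageA"], 0, tolerance = 1e-12)
  expect_equal(mtc$p["m2", "stageA"], 1, tolerance = 1e-12)
  expect_error(module_trait_correlation(me[, 1:2], ind[1:2, ]), "3 samples")
})

test_that("key-module selection filters by sign and significance", {
  mtc <- structure(list(
    r = matrix(c(0.9, -0.8, 0.2), 3, 1,
               dimnames = list(c("m1", "m2", "m3"), "larva3")),
    p = matrix(c(0.001, 0.001, 0.6), 3, 1,
               dimnames = list(c("m1", "m2", "m3"), "larva3")),
    n = 9), class = "module_trait_correlation")
  expect_identical(select_key_modules(mtc, "larva3"), "m1")
  expect_identical(select_key_modules(mtc, "larva3", alpha = 1), c("m1", "m3"))

  mtc$r[, 1] <- c(-0.9, -0.8, -0.2)
  expect_identical(select_key_modules(mtc, "larva3"), character(0))
  expect_error(select_key_modules(mtc, "adult"), "unknown stage")
})

test_that("module membership and hub selection apply the inclusive kME bound", {
  prof <- c(1, 3, 2, 5, 4, 6)
  x <- rbind(g1 = prof, g2 = prof + rnorm(6, sd = 0.1), g3 = rnorm(6))
  colnames(x) <- paste0("s", 1:6)
  lab <- stats::setNames(c("blue", "blue", "blue"), rownames(x))
  me <- module_eigengenes(x, lab)
  kme <- module_membership(x, me)
  expect_gte(kme["g1", "blue"], 0.99)

  # crafted kME matrix: the 0.80 boundary is inclusive
  kme2 <- matrix(c(0.80, 0.799, 0.95), 3, 1,
                 dimnames = list(c("a", "b", "c"), "blue"))
  lab2 <- stats::setNames(rep("blue", 3), c("a", "b", "c"))
  expect_identical(select_hub_genes(kme2, lab2, 0.80)$blue, c("a", "c"))
  expect_identical(select_hub_genes(kme2, lab2, 1.01)$blue, character(0))
})

test_that("kME pruning sends weakly attached genes to grey", {
  set.seed(21)
  fx <- block_expression(c(40, 40), rho = 0.9, n_samples = 12, n_noise = 10)
  lab <- fx$truth
  lab[lab == "none"] <- "B1"   # misassign the noise genes
  pruned <- prune_modules(fx$expr, lab, min_kme = 0.5, min_module_size = 30)
  noise <- names(fx$truth)[fx$truth == "none"]
  expect_gte(sum(pruned[noise] == "grey"), 8)
  expect_true(all(pruned[names(fx$truth)[fx$truth == "B1"]] == "B1"))
})
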