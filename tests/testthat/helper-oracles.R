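# Independent oracles and small fixture builders shared across test files.

# Brute-force TOM by the double loop over the defining formula; O(n^3),
# independent of the matrix-algebra implementation under test.
brute_force_tom <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj) - diag(adj)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  tom
}

# Hypergeometric upper tail by direct summation of the exact pmf with
# integer-valued choose(); exact for small N.
hyper_tail_enumeration <- function(a, K, n, N) {
  ks <- a:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Random symmetric adjacency with unit diagonal, entries in [0,1].
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Random simple undirected graph as an edge-list data.frame.
random_graph <- function(n_nodes, edge_prob) {
  nodes <- sprintf("v%03d", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  data.frame(from = pairs[1, keep], to = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# Replay a cluster's growth in insertion order, verifying the admission
# conditions the greedy procedure claims: each added member's cluster
# property (computed against the cluster before its insertion) reached
# cp_min, the density never fell below d_min after any insertion, and the
# emitted cluster is connected.
replay_cluster_contract <- function(cluster, edges, d_min, cp_min) {
  members <- cluster$members
  nbr <- function(g, set) {
    from <- edges$from; to <- edges$to
    sum((from == g & to %in% set) | (to == g & from %in% set))
  }
  e_int <- 0
  for (i in seq_along(members)) {
    if (i == 1) next
    prev <- members[seq_len(i - 1)]
    e_nk <- nbr(members[i], prev)
    if (e_nk == 0) return("disconnected insertion")
    d_prev <- if (length(prev) == 1) 1 else e_int / choose(length(prev), 2)
    cp <- e_nk / (d_prev * length(prev))
    if (cp < cp_min) return(sprintf("cp %0.3f < cp_min at step %d", cp, i))
    e_int <- e_int + e_nk
    d_new <- e_int / choose(i, 2)
    if (d_new < d_min - 1e-12)
      return(sprintf("density %0.3f < d_min after step %d", d_new, i))
  }
  if (abs(cluster$density - (if (length(members) == 1) 1 else
    e_int / choose(length(members), 2))) > 1e-12)
    return("recorded density mismatch")
  "ok"
}

# Two-block Gaussian latent-factor expression fixture (no count noise):
# `blocks` named sizes, within-block correlation rho, n samples.
block_expression <- function(block_sizes, rho, n_samples, n_noise = 0) {
  n_g <- sum(block_sizes) + n_noise
  ids <- sprintf("g%04d", seq_len(n_g))
  x <- matrix(stats::rnorm(n_g * n_samples), n_g, n_samples,
              dimnames = list(ids, sprintf("s%02d", seq_len(n_samples))))
  x <- sqrt(1 - rho) * x
  block_of <- rep(c(seq_along(block_sizes), 0),
                  c(block_sizes, n_noise))
  for (b in seq_along(block_sizes)) {
    z <- stats::rnorm(n_samples)
    x[block_of == b, ] <- x[block_of == b, , drop = FALSE] +
      sqrt(rho) * matrix(z, block_sizes[b], n_samples, byrow = TRUE)
  }
  if (n_noise > 0)
    x[block_of == 0, ] <- matrix(stats::rnorm(n_noise * n_samples),
                                 n_noise, n_samples)
  list(expr = x,
       truth = stats::setNames(ifelse(block_of == 0, "none",
                                      paste0("B", block_of)), ids))
}

# Minimal cluster_set constructor for prioritisation tests.
make_cluster_set <- function(member_list, d_min = 0.5) {
  clusters <- lapply(member_list, function(m)
    list(members = m, n_nodes = length(m), n_edges = NA_integer_,
         density = NA_real_))
  structure(list(clusters = clusters, d_min = d_min, cp_min = 0.5,
                 min_cluster_size = 2L), class = "cluster_set")
}
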