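# internal: edge list -> sorted node vector + adjacency list of neighbour sets
.build_adjacency <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  all_nodes <- sort(unique(c(from, to, as.character(nodes))))
  adj <- stats::setNames(vector("list", length(all_nodes)), all_nodes)
  if (length(from)) {
    key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    dup <- duplicated(key)
    from <- from[!dup]; to <- to[!dup]
    nb <- split(c(to, from), c(from, to))
    adj[names(nb)] <- lapply(nb, function(v) sort(unique(v)))
  }
  adj[vapply(adj, is.null, logical(1))] <- list(character(0))
  adj
}

#' Edge density of a node set
#'
#' The number of edges internal to `nodes` divided by the maximum possible,
#' `|nodes| * (|nodes| - 1) / 2`.  A singleton's density is defined as 1 by
#' convention (it is vacuously fully connected).
#'
#' @param nodes Character vector of node IDs.
#' @param edges Two-column edge-list data.frame.
#' @return Density in \[0, 1\].
#' @export
cluster_density <- function(nodes, edges) {
  nodes <- unique(as.character(nodes))
  n <- length(nodes)
  if (n < 1L) stop("empty node set has no density")
  if (n == 1L) return(1)
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  internal <- from %in% nodes & to %in% nodes & from != to
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")[internal]
  e <- length(unique(key))
  e / (n * (n - 1) / 2)
}

#' Cluster property of an outside node
#'
#' `cp_nk = E_nk / (d_k * N_k)`, where `E_nk` is the number of edges linking
#' node `n` to the members of cluster `k`, `d_k` is the cluster's density
#' and `N_k` its node count.  It measures how strongly a candidate node is
#' tied to a cluster relative to the cluster's own connectivity, and is the
#' admission criterion of the greedy overlapping clustering.
#'
#' @param node A node ID not in the cluster.
#' @param cluster Character vector of cluster member IDs.
#' @param edges Two-column edge-list data.frame.
#' @param d_k Cluster density; computed from `edges` if missing.
#' @return Non-negative real; 0 when the node has no edge into the cluster.
#' @export
cluster_property <- function(node, cluster, edges, d_k = cluster_density(cluster, edges)) {
  node <- as.character(node)
  cluster <- unique(as.character(cluster))
  if (node %in% cluster) stop("node is already a member of the cluster")
  if (d_k <= 0) stop("cluster property is undefined for density 0")
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  e_nk <- sum((from == node & to %in% cluster) | (to == node & from %in% cluster))
  e_nk / (d_k * length(cluster))
}

#' Overlapping density-based graph clustering
#'
#' Greedy seeded growth in the DPClusO style.  Seeds are taken in decreasing
#' degree order (ties by node ID ascending) among nodes not yet covered by
#' any cluster.  A cluster grows by repeatedly admitting the neighbour `n`
#' with the most edges into the cluster (`E_nk`, ties by node ID) among
#' those that keep the density at or above `d_min` after insertion and whose
#' cluster property `cp_nk = E_nk / (d_k * N_k)` (computed before insertion)
#' is at least `cp_min`.  When no admissible neighbour remains the cluster
#' is emitted if it has at least `min_cluster_size` nodes; its members are
#' marked covered but stay in the graph, so later clusters may overlap them.
#' The procedure repeats until every node is covered.
#'
#' Emitted clusters are connected (growth proceeds through neighbours),
#' satisfy `density >= d_min`, and record their members in insertion order
#' so the admission conditions can be replayed.
#'
#' @param edges Two-column edge-list data.frame (undirected; duplicate edges
#'   and self-loops are dropped).
#' @param d_min Minimum cluster density in (0, 1].
#' @param cp_min Minimum cluster property for admission (default 0.5).
#' @param min_cluster_size Minimum emitted cluster size (default 2).
#' @param nodes Optional full node vector (to include isolated nodes).
#' @return An object of class `cluster_set`: list with `clusters` (each a
#'   list of `members` in insertion order, `n_nodes`, `n_edges`, `density`),
#'   and the parameters used.
#' @export
dpcluso_cluster <- function(edges, d_min, cp_min = 0.5, min_cluster_size = 2L,
                            nodes = NULL) {
  if (!(d_min > 0 && d_min <= 1)) stop("d_min must lie in (0,1]")
  adj <- .build_adjacency(edges, nodes)
  all_nodes <- names(adj)
  clusters <- list()
  if (!length(all_nodes))
    return(structure(list(clusters = clusters, d_min = d_min, cp_min = cp_min,
                          min_cluster_size = as.integer(min_cluster_size)),
                     class = "cluster_set"))
  degree <- lengths(adj)
  covered <- stats::setNames(rep(FALSE, length(all_nodes)), all_nodes)

  while (!all(covered)) {
    unc <- all_nodes[!covered]
    seed <- unc[order(-degree[unc], unc)][1]
    members <- seed
    n_edges <- 0L
    repeat {
      nb <- setdiff(sort(unique(unlist(adj[members], use.names = FALSE))), members)
      if (!length(nb)) break
      n_k <- length(members)
      d_k <- if (n_k == 1L) 1 else n_edges / (n_k * (n_k - 1) / 2)
      e_nk <- vapply(nb, function(v) sum(adj[[v]] %in% members), integer(1))
      new_density <- (n_edges + e_nk) / ((n_k + 1) * n_k / 2)
      cp <- if (d_k > 0) e_nk / (d_k * n_k) else rep(Inf, length(nb))
      ok <- new_density >= d_min & cp >= cp_min
      if (!any(ok)) break
      cand <- nb[ok]
      pick <- cand[order(-e_nk[ok], cand)][1]
      members <- c(members, pick)
      n_edges <- n_edges + e_nk[[pick]]
    }
    if (length(members) >= min_cluster_size) {
      n_k <- length(members)
      clusters[[length(clusters) + 1L]] <- list(
        members = members,
        n_nodes = n_k,
        n_edges = n_edges,
        density = if (n_k == 1L) 1 else n_edges / (n_k * (n_k - 1) / 2))
    }
    covered[members] <- TRUE
  }
  structure(list(clusters = clusters, d_min = d_min, cp_min = cp_min,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster set: ", length(x$clusters), " cluster(s) at d_min = ",
      x$d_min, ", cp_min = ", x$cp_min, "\n", sep = "")
  if (length(x$clusters)) {
    sizes <- vapply(x$clusters, `[[`, integer(1), "n_nodes")
    cat("  sizes: min ", min(sizes), ", median ", stats::median(sizes),
        ", max ", max(sizes), "\n", sep = "")
  }
  invisible(x)
}

#' Cluster the network over a sweep of density thresholds
#'
#' Runs [dpcluso_cluster()] once per density value, returning one cluster
#' set per density.  The conventional sweep is 0.5 to 0.9 in steps of 0.1.
#'
#' @inheritParams dpcluso_cluster
#' @param densities Numeric vector of `d_min` values.
#' @return Named list of `cluster_set` objects, names the density values.
#' @export
dpcluso_sweep <- function(edges, densities = c(0.5, 0.6, 0.7, 0.8, 0.9),
                          cp_min = 0.5, min_cluster_size = 2L, nodes = NULL) {
  out <- lapply(densities, function(d)
    dpcluso_cluster(edges, d_min = d, cp_min = cp_min,
                    min_cluster_size = min_cluster_size, nodes = nodes))
  stats::setNames(out, format(densities, trim = TRUE))
}
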