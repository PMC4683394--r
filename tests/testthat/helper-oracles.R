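# Independent brute-force oracles and small-graph enumeration used across the
# suite. These deliberately avoid the package's internal representations.

# modularity by the per-pair definition:
# Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)
oracle_modularity <- function(edges, membership) {
  nodes <- names(membership)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]
    v <- edges[r, 2]
    A[u, v] <- A[u, v] + 1
    A[v, u] <- A[v, u] + 1
  }
  k <- rowSums(A)
  m2 <- sum(k)
  same <- outer(membership[nodes], membership[nodes], "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

# brute-force neighbor ranking: sort neighbors by (-similarity, degree, index)
oracle_rank <- function(g, v, index) {
  e <- graph_edges(g)
  nbrs <- unique(c(e$to[e$from == v], e$from[e$to == v]))
  if (length(nbrs) == 0) return(character())
  sim <- vapply(nbrs, function(u) pair_similarity(g, v, u, index), numeric(1))
  deg <- vapply(nbrs, function(u) node_degree(g, u), numeric(1))
  idx <- match(nbrs, g$nodes)
  nbrs[order(-round(sim / 1e-12) * 1e-12, deg, idx)]
}

# all set partitions of 1..n (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      rec(c(assign, lab), max(next_label, lab + 1L))
    }
  }
  rec(integer(), 1L)
  out
}

# every labeled simple graph on the given node labels (one per edge subset),
# optionally only those with at least one edge
all_graphs_on <- function(labels, min_edges = 0L) {
  pairs <- t(utils::combn(labels, 2))
  np <- nrow(pairs)
  lapply(Filter(function(mask) sum(mask) >= min_edges,
                lapply(0:(2^np - 1), function(b) as.logical(intToBits(b)[1:np]))),
         function(mask) pairs[mask, , drop = FALSE])
}

random_edge_table <- function(n, p, seed) {
  withr::with_seed(seed, {
    labels <- sprintf("v%02d", seq_len(n))
    pairs <- t(utils::combn(labels, 2))
    keep <- stats::runif(nrow(pairs)) < p
    pairs[keep, , drop = FALSE]
  })
}

random_partition_of <- function(nodes, k, seed) {
  withr::with_seed(seed, {
    labs <- paste0("C", sample.int(k, length(nodes), replace = TRUE))
    tibble::tibble(node = nodes, community = labs)
  })
}

# two K5 cliques joined by a single bridge edge
two_cliques_graph <- function() {
  cl <- function(p) t(utils::combn(paste0(p, 1:5), 2))
  build_graph(rbind(cl("x"), cl("y"), c("x1", "y1")))
}

# the hierarchical toy used for the multi-resolution (nth) mode: four
# triangles, strong pair bonds A-B and C-D, one weak A-C bond
hierarchy_toy <- function() {
  tri <- function(p) cbind(paste0(p, c(1, 1, 2)), paste0(p, c(2, 3, 3)))
  build_graph(rbind(
    tri("a"), tri("b"), tri("c"), tri("d"),
    c("a1", "b1"), c("a2", "b2"),
    c("c1", "d1"), c("c2", "d2"),
    c("a3", "c3")
  ))
}

# TRUE when partition `coarse` is a coarsening of `fine` (every fine block is
# contained in one coarse block)
is_coarsening <- function(fine, coarse) {
  f <- stats::setNames(fine$community, fine$node)
  c_ <- stats::setNames(coarse$community, coarse$node)
  all(tapply(c_[names(f)], f, function(x) length(unique(x))) == 1L)
}
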