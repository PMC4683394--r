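test_that("k = 1 anchors to the single most similar neighbor", {
  g <- two_cliques_graph()
  for (v in g$nodes) {
    top <- rank_neighbors(g, v)$neighbor[1]
    expect_equal(select_anchor(g, v, k = 1), top)
  }
})

test_that("among the k most similar neighbors the smallest degree wins", {
  # v has three neighbors of equal similarity to v (no shared neighbors
  # between any of them and v) but degrees 5, 2, 4
  pad <- function(x, n) cbind(x, paste0(x, "_p", seq_len(n)))
  g <- build_graph(rbind(
    c("v", "h1"), c("v", "h2"), c("v", "h3"),
    pad("h1", 4), pad("h2", 1), pad("h3", 3)
  ))
  expect_equal(node_degree(g, "h1"), 5L)
  expect_equal(node_degree(g, "h2"), 2L)
  expect_equal(node_degree(g, "h3"), 4L)
  expect_equal(select_anchor(g, "v", k = 3), "h2")
  # with k = 1 the degree tie-break inside the tie class already picks h2
  # (all three neighbors are equally similar), so restrict the tie:
  expect_equal(select_anchor(g, "v", k = 1),
               rank_neighbors(g, "v")$neighbor[1])
})

test_that("nth mode past the neighbor count returns the least similar neighbor", {
  # degree-2 node: b's neighbors are a (shares c) and c (shares a); make them
  # asymmetric so the ranking is strict
  g <- build_graph(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"), c("a", "d"), c("b", "d")
  ))
  r <- rank_neighbors(g, "c")
  expect_equal(select_anchor(g, "c", nth = 4), r$neighbor[nrow(r)])
  expect_equal(select_anchor(g, "c", nth = 1), r$neighbor[1])
})

test_that("isolated nodes have no anchor and become singletons", {
  g <- build_graph(cbind("a", "b"), nodes = c("z1", "z2"))
  expect_true(is.na(select_anchor(g, "z1")))
  res <- ksim_detect(g, k = 1)
  expect_setequal(res$isolated_nodes, c("z1", "z2"))
  p <- setNames(res$partition$community, res$partition$node)
  expect_equal(unname(p["z1"]), "z1")
  expect_equal(unname(p["z2"]), "z2")
})

test_that("seed partition separates two bridged triangles and unites K4", {
  g <- build_graph(rbind(
    c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
    c("a1", "b1")
  ))
  p <- initial_partition(g, k = 1)
  memb <- setNames(p$community, p$node)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(memb[c("b1", "b2", "b3")])), 1)

  k4 <- build_graph(t(utils::combn(paste0("k", 1:4), 2)))
  expect_equal(length(unique(initial_partition(k4, k = 1)$community)), 1)

  iso <- build_graph(NULL, nodes = paste0("i", 1:4))
  expect_equal(initial_partition(iso, k = 1)$community, paste0("i", 1:4))
})

test_that("membership sweep applies the strict plurality rule", {
  # star-ish: node v with 3 neighbors in A, 1 in B, currently in B
  g <- build_graph(rbind(
    c("v", "a1"), c("v", "a2"), c("v", "a3"), c("v", "b1"),
    c("a1", "a2"), c("a1", "a3"), c("a2", "a3")
  ))
  p <- tibble::tibble(
    node = c("v", "a1", "a2", "a3", "b1"),
    community = c("B", "A", "A", "A", "B")
  )
  sw <- membership_sweep(g, p)
  expect_equal(sw$moves, 1L)
  expect_equal(sw$partition$community[sw$partition$node == "v"], "A")
})

test_that("a plurality tie keeps the current community", {
  # v: 2 neighbors in A, 2 in B, currently A
  g <- build_graph(rbind(
    c("v", "a1"), c("v", "a2"), c("v", "b1"), c("v", "b2"),
    c("a1", "a2"), c("b1", "b2")
  ))
  p <- tibble::tibble(
    node = c("v", "a1", "a2", "b1", "b2"),
    community = c("A", "A", "A", "B", "B")
  )
  sw <- membership_sweep(g, p)
  expect_equal(sw$partition$community[sw$partition$node == "v"], "A")
})

test_that("a partition satisfying the membership criterion is a fixed point", {
  g <- two_cliques_graph()
  p <- connected_components(g) # one block; trivially stable
  expect_equal(membership_sweep(g, p)$moves, 0L)
  res <- ksim_detect(g, k = 1)
  expect_equal(membership_sweep(g, res$partition)$moves, 0L)
})

test_that("weak community pairs merge and strong ones are kept", {
  # two 'communities' with 1 internal edge each and 2 edges between them
  g <- build_graph(rbind(
    c("a1", "a2"), c("b1", "b2"), c("a1", "b1"), c("a2", "b2")
  ))
  p <- tibble::tibble(node = c("a1", "a2", "b1", "b2"),
                      community = c("A", "A", "B", "B"))
  ec <- enforce_community_criteria(g, p)
  expect_equal(ec$merges, 1L)
  expect_equal(length(unique(ec$partition$community)), 1)

  # karate factions: 34 internal each side, 10 across -- no violation
  gk <- ksim_fixture("karate")
  pk <- ksim_detect(gk, k = 1)$partition
  efm <- edge_fraction_matrix(gk, pk)
  expect_equal(unname(sort(diag(efm$counts))), c(34, 34))
  expect_equal(enforce_community_criteria(gk, pk)$merges, 0L)

  # a single community cannot violate
  expect_equal(enforce_community_criteria(g, connected_components(g))$merges, 0L)
})

test_that("detect separates disjoint cliques in a single pass", {
  cl <- function(p) t(utils::combn(paste0(p, 1:4), 2))
  g <- build_graph(rbind(cl("x"), cl("y")))
  res <- ksim_detect(g, k = 1)
  expect_equal(length(unique(res$partition$community)), 2)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
})

test_that("detect is deterministic over repeated runs", {
  g <- ksim_fixture("karate")
  runs <- lapply(1:10, function(i) ksim_detect(g, k = 1)$partition)
  for (i in 2:10) expect_identical(runs[[1]], runs[[i]])
})

test_that("detect is invariant to node relabeling on a tie-free graph", {
  # bridged K5s: similarity structure has no cross-clique ties that matter
  g <- two_cliques_graph()
  res1 <- ksim_detect(g, k = 1)
  memb1 <- setNames(res1$partition$community, res1$partition$node)

  relab <- setNames(sprintf("q%02d", c(5, 9, 1, 7, 3, 10, 2, 8, 6, 4)), g$nodes)
  e <- graph_edges(g)
  g2 <- build_graph(cbind(relab[e$from], relab[e$to]))
  res2 <- ksim_detect(g2, k = 1)
  memb2 <- setNames(res2$partition$community, res2$partition$node)

  # same grouping after mapping labels back
  grp1 <- split(names(memb1), memb1)
  grp2 <- split(names(memb2), memb2)
  canon <- function(grps, map = identity) {
    s <- lapply(grps, function(x) sort(unname(map(x))))
    unname(s[order(vapply(s, `[`, "", 1L))])
  }
  expect_identical(canon(grp1, function(x) relab[x]), canon(grp2))
})

test_that("after convergence every non-singleton community meets the community criterion", {
  cases <- list(
    ksim_fixture("karate"),
    ksim_fixture("lesmis"),
    build_graph(random_edge_table(25, 0.2, 11))
  )
  for (g in cases) {
    res <- ksim_detect(g, k = 1)
    efm <- edge_fraction_matrix(g, res$partition)
    internal <- diag(efm$counts)
    K <- length(efm$labels)
    sizes <- table(factor(res$partition$community, levels = efm$labels))
    if (K == 1) next
    for (i in seq_len(K)) {
      if (sizes[i] == 1 &&
          node_degree(g, res$partition$node[
            res$partition$community == efm$labels[i]][1]) == 0) next
      cuts <- efm$counts[i, -i]
      expect_gt(internal[i], max(cuts))
    }
  }
})

test_that("multi-resolution (nth) partitions are nested coarsenings on a hierarchical toy", {
  g <- hierarchy_toy()
  parts <- lapply(1:4, function(n) ksim_detect(g, nth = n)$partition)
  counts <- vapply(parts, function(p) length(unique(p$community)), integer(1))
  expect_equal(counts, c(4L, 4L, 2L, 2L))
  for (i in 1:3) expect_true(is_coarsening(parts[[i]], parts[[i + 1]]))
  # the top level groups the strongly bonded triangle pairs
  memb <- setNames(parts[[3]]$community, parts[[3]]$node)
  expect_equal(length(unique(memb[c("a1", "b1")])), 1)
  expect_equal(length(unique(memb[c("c1", "d1")])), 1)
  expect_false(memb[["a1"]] == memb[["c1"]])
})

test_that("iteration cap flags non-convergence instead of erroring", {
  g <- ksim_fixture("lesmis")
  expect_warning(res <- ksim_detect(g, k = 1, max_iterations = 1),
                 "did not converge")
  expect_false(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(nrow(res$partition), 77)
})

test_that("config validation rejects bad parameters", {
  g <- ksim_fixture("karate")
  expect_error(ksim_detect(g, k = 0), "positive integer")
  expect_error(ksim_detect(g, k = 1, max_iterations = 0), "positive integer")
  expect_error(ksim_detect(g, k = 1, nth = 0), "positive integer")
  expect_error(ksim_detect(g, k = 1, index = "nope"))
  expect_error(select_anchor(g, "unknown-node", k = 1), "unknown node")
})
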