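#' Select the anchor neighbor of a node
#'
#' The anchor is the neighbor a node is initially placed in a community with.
#' Among the node's `k` most similar neighbors (ranking of [rank_neighbors()]),
#' the one with the smallest degree is chosen; degree ties fall back to higher
#' similarity and then to smaller canonical node index. With `nth` set
#' (multi-resolution mode) the anchor is instead the `nth`-ranked neighbor, or
#' the least similar neighbor when `nth` exceeds the number of neighbors.
#'
#' @param g A `ksim_graph` or edge table.
#' @param v Node label.
#' @param k Size of the candidate set of most similar neighbors.
#' @param index Similarity index name, see [similarity_indexes()].
#' @param nth Optional positive integer enabling the n-th most similar neighbor
#'   mode; overrides `k`.
#' @return The anchor node label, or `NA_character_` for a degree-0 node.
#' @export
select_anchor <- function(g, v, k = 1, index = "cn_closed", nth = NULL) {
  g <- as_ksim_graph(g)
  cfg <- ksim_config(k = k, index = index, nth = nth)
  vi <- node_index(g, v)
  ai <- select_anchor_int(g, vi, cfg)
  if (is.na(ai)) NA_character_ else g$nodes[ai]
}

#' Seed partition from anchor pairs
#'
#' Every non-isolated node is joined to its anchor (see [select_anchor()]);
#' the connected components of the resulting anchor graph are the seed
#' communities. Degree-0 nodes become singletons. Community labels are the
#' smallest node label in each seed community.
#'
#' @inheritParams select_anchor
#' @return A partition tibble with columns `node` and `community`.
#' @export
initial_partition <- function(g, k = 1, index = "cn_closed", nth = NULL) {
  g <- as_ksim_graph(g)
  cfg <- ksim_config(k = k, index = index, nth = nth)
  comp <- initial_membership_int(g, cfg)
  tibble::tibble(node = g$nodes, community = g$nodes[comp])
}

#' One membership-criterion sweep
#'
#' Performs a single sequential pass over the nodes in canonical order. Each
#' node is reassigned to the community holding the strict plurality of its
#' neighbors. When several communities tie for the maximum, the node keeps its
#' current community if it is among them; otherwise it joins the tied
#' community that contains its most similar neighbor (ranking of
#' [rank_neighbors()]), so that ties are resolved by the same similarity
#' signal that drives the anchoring.
#'
#' @param g A `ksim_graph` or edge table.
#' @param p A partition: tibble with `node`/`community` columns, named vector,
#'   or a `ksim_result`.
#' @param index Similarity index used to resolve plurality ties.
#' @return A list with elements `partition` (tibble) and `moves` (integer
#'   count of reassignments in the pass).
#' @export
membership_sweep <- function(g, p, index = "cn_closed") {
  g <- as_ksim_graph(g)
  pm <- partition_membership(g, p)
  ranks <- neighbor_rankings(g, index)
  sw <- membership_sweep_int(g, pm$ids, length(pm$labels), ranks)
  list(
    partition = membership_to_partition(g, sw$ids, pm$labels),
    moves = sw$moves
  )
}

#' Enforce the community criterion by merging
#'
#' A community satisfies the community criterion when it has strictly more
#' internal edges than edges to any single other community. Communities are
#' scanned in ascending (size, label) order; the first violator is merged into
#' the community it shares the most edges with (ties: smaller community, then
#' smaller label, so fragments coalesce bottom-up before a large community can
#' absorb them), counts are updated, and the scan repeats until no violator
#' remains. Singleton communities of degree-0 nodes are exempt.
#'
#' @inheritParams membership_sweep
#' @return A list with elements `partition` (tibble) and `merges` (integer).
#' @export
enforce_community_criteria <- function(g, p) {
  g <- as_ksim_graph(g)
  pm <- partition_membership(g, p)
  ec <- enforce_community_int(g, pm$ids)
  list(
    partition = membership_to_partition(g, ec$ids, pm$labels),
    merges = ec$merges
  )
}

#' Detect communities by maximal neighbor similarity (kSIM)
#'
#' Runs the full algorithm: node similarities are computed, every node is
#' anchored to one of its `k` most similar neighbors (smallest degree among
#' them), connected unions of anchor pairs form the seed communities, and the
#' partition is then refined by alternating [membership_sweep()] and
#' [enforce_community_criteria()] until a full pass changes nothing. The
#' procedure is deterministic: repeated runs on the same input give the same
#' partition.
#'
#' @param g A `ksim_graph` or an edge table (data frame / matrix), converted
#'   via [as_ksim_graph()].
#' @param k Number of most similar neighbors considered when anchoring
#'   (1 up to the maximum degree). `k = 1` anchors every node to its single
#'   most similar neighbor.
#' @param index Similarity index name, see [similarity_indexes()].
#' @param nth Optional n-th most similar neighbor mode (multi-resolution
#'   exploration); overrides `k` during anchoring.
#' @param max_iterations Safety cap on refinement passes; convergence is
#'   normally reached in a handful of passes.
#' @return A `ksim_result` with elements `partition` (tibble `node`,
#'   `community`), `iterations` (outer passes executed, including the final
#'   pass that confirms convergence), `converged`, `isolated_nodes`,
#'   `per_iteration` (tibble of moves/merges per pass), `config`, and the
#'   input `graph`. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' g <- ksim_fixture("karate")
#' res <- ksim_detect(g, k = 1)
#' res
#' glance(res)
#' @export
ksim_detect <- function(g, k = 1, index = "cn_closed", nth = NULL,
                        max_iterations = 100) {
  g <- as_ksim_graph(g)
  if (length(g$nodes) == 0L) rlang::abort("empty graph")
  cfg <- ksim_config(k = k, index = index, nth = nth,
                     max_iterations = max_iterations)

  ranks <- neighbor_rankings(g, cfg$index)
  ids <- initial_membership_int(g, cfg, ranks)
  nbins <- length(g$nodes)
  isolated <- g$deg == 0L

  per_iter <- list()
  iterations <- 0L
  converged <- FALSE
  while (iterations < cfg$max_iterations) {
    iterations <- iterations + 1L
    sw <- membership_sweep_int(g, ids, nbins, ranks)
    ids <- sw$ids
    ec <- enforce_community_int(g, ids)
    ids <- ec$ids
    per_iter[[iterations]] <- c(moves = sw$moves, merges = ec$merges)
    if (sw$moves == 0L && ec$merges == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    rlang::warn(sprintf("kSIM did not converge within %d iterations",
                        cfg$max_iterations))
  }

  # final labels: smallest node label of each community
  roots <- stats::ave(seq_along(ids), ids, FUN = min)
  partition <- tibble::tibble(node = g$nodes, community = g$nodes[roots])

  pi_mat <- do.call(rbind, per_iter)
  structure(
    list(
      partition = partition,
      iterations = iterations,
      converged = converged,
      isolated_nodes = g$nodes[isolated],
      per_iteration = tibble::tibble(
        iteration = seq_len(nrow(pi_mat)),
        moves = as.integer(pi_mat[, "moves"]),
        merges = as.integer(pi_mat[, "merges"])
      ),
      config = cfg,
      graph = g
    ),
    class = "ksim_result"
  )
}

#' @export
print.ksim_result <- function(x, ...) {
  k_comms <- length(unique(x$partition$community))
  cat(sprintf(
    "<ksim_result: %d communities on %d nodes (k = %d, index = %s)>\n",
    k_comms, nrow(x$partition), x$config$k, x$config$index
  ))
  cat(sprintf(
    "  %d iteration(s), converged: %s, isolated nodes: %d\n",
    x$iterations, x$converged, length(x$isolated_nodes)
  ))
  sizes <- sort(table(x$partition$community), decreasing = TRUE)
  cat("  community sizes:", paste(as.integer(sizes), collapse = " "), "\n")
  invisible(x)
}

# ---- internal ---------------------------------------------------------------

ksim_config <- function(k = 1, index = "cn_closed", nth = NULL,
                        max_iterations = 100) {
  k <- as.integer(k)
  max_iterations <- as.integer(max_iterations)
  if (is.na(k) || k < 1L) rlang::abort("`k` must be a positive integer")
  if (is.na(max_iterations) || max_iterations < 1L) {
    rlang::abort("`max_iterations` must be a positive integer")
  }
  if (!is.null(nth)) {
    nth <- as.integer(nth)
    if (is.na(nth) || nth < 1L) rlang::abort("`nth` must be a positive integer")
  }
  index <- match.arg(index, similarity_indexes())
  list(k = k, index = index, nth = nth, max_iterations = max_iterations)
}

select_anchor_int <- function(g, vi, cfg, r = NULL) {
  if (is.null(r)) r <- ranked_neighbors_int(g, vi, cfg$index)
  nn <- length(r$idx)
  if (nn == 0L) return(NA_integer_)
  if (!is.null(cfg$nth)) {
    return(r$idx[min(cfg$nth, nn)])
  }
  kk <- min(cfg$k, nn)
  cand <- seq_len(kk)
  # smallest degree among the k most similar; ties: higher similarity (earlier
  # tie class), then smaller node index -- the ranking order already encodes
  # the final index tie-break
  pick <- cand[order(g$deg[r$idx[cand]], r$cls[cand], cand)][1L]
  r$idx[pick]
}

initial_membership_int <- function(g, cfg, ranks = NULL) {
  n <- length(g$nodes)
  anchor_adj <- rep(list(integer()), n)
  for (vi in seq_len(n)) {
    ai <- select_anchor_int(g, vi, cfg, if (is.null(ranks)) NULL else ranks[[vi]])
    if (!is.na(ai)) {
      anchor_adj[[vi]] <- c(anchor_adj[[vi]], ai)
      anchor_adj[[ai]] <- c(anchor_adj[[ai]], vi)
    }
  }
  components_int(anchor_adj, n)
}

# neighbor rankings (best-first, with tie classes) for every node; computed
# once per detect() run and reused by anchoring and by every sweep
neighbor_rankings <- function(g, index) {
  lapply(seq_along(g$nodes), function(v) {
    ranked_neighbors_int(g, v, index)
  })
}

# one sequential pass in ascending node index order; ids are integer community
# ids whose numeric order agrees with the label order; `ranks` are the
# per-node neighbor rankings used to resolve plurality ties
membership_sweep_int <- function(g, ids, nbins, ranks) {
  moves <- 0L
  for (v in seq_along(ids)) {
    nb <- g$adj[[v]]
    if (length(nb) == 0L) next
    cnt <- tabulate(ids[nb], nbins = nbins)
    best <- max(cnt)
    if (cnt[ids[v]] != best) {
      cands <- which(cnt == best)
      if (length(cands) == 1L) {
        ids[v] <- cands
      } else {
        rk <- ranks[[v]]$idx
        ids[v] <- ids[rk[match(TRUE, ids[rk] %in% cands)]]
      }
      moves <- moves + 1L
    }
  }
  list(ids = ids, moves = moves)
}

# symmetric K x K community edge-count matrix (diagonal = internal edges)
community_edge_counts <- function(ci, cj, K) {
  a <- pmin(ci, cj)
  b <- pmax(ci, cj)
  key <- (as.numeric(a) - 1) * K + as.numeric(b)
  tt <- table(key)
  kk <- as.numeric(names(tt))
  aa <- ((kk - 1) %/% K) + 1
  bb <- ((kk - 1) %% K) + 1
  M <- matrix(0, K, K)
  M[cbind(aa, bb)] <- as.numeric(tt)
  M[cbind(bb, aa)] <- as.numeric(tt)
  M
}

# merge community-criterion violators until stable; after each merge the edge
# counts are updated (row/column addition is exact, equivalent to a recompute)
enforce_community_int <- function(g, ids) {
  merges <- 0L
  uid <- sort(unique(ids))
  K <- length(uid)
  if (K <= 1L || g$m == 0L) return(list(ids = ids, merges = 0L))
  cidx <- match(ids, uid)
  sizes <- tabulate(cidx, nbins = K)
  M <- community_edge_counts(cidx[g$edges[, 1]], cidx[g$edges[, 2]], K)
  first_member <- match(seq_len(K), cidx)
  exempt <- sizes == 1L & g$deg[first_member] == 0L

  repeat {
    if (length(uid) <= 1L) break
    internal <- diag(M)
    ord <- order(sizes, uid)
    victim <- 0L
    for (i in ord) {
      if (exempt[i]) next
      row <- M[i, ]
      row[i] <- -1
      if (max(row) >= internal[i]) {
        victim <- i
        break
      }
    }
    if (victim == 0L) break
    row <- M[victim, ]
    row[victim] <- -1
    mx <- max(row)
    cands <- which(row == mx)
    target <- cands[order(sizes[cands], uid[cands])][1L]

    ids[ids == uid[victim]] <- uid[target]
    cut_vt <- M[victim, target]
    M[target, ] <- M[target, ] + M[victim, ]
    M[, target] <- M[, target] + M[, victim]
    M[target, target] <- internal[target] + internal[victim] + cut_vt
    sizes[target] <- sizes[target] + sizes[victim]
    exempt[target] <- FALSE
    M <- M[-victim, -victim, drop = FALSE]
    uid <- uid[-victim]
    sizes <- sizes[-victim]
    exempt <- exempt[-victim]
    merges <- merges + 1L
  }
  list(ids = ids, merges = merges)
}
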