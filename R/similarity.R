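#' Available node-pair similarity indexes
#'
#' All indexes are local structural similarities driven by the common
#' neighborhood of the two nodes. `cn_closed` (the default everywhere in the
#' package) counts common members of the *closed* neighborhoods
#' \eqn{|N[u] \cap N[v]|} (each node counts itself and its neighbors), so two
#' adjacent nodes always score at least 2 and the count never degenerates to
#' zero on triangle-free regions. `cn` is the plain common-neighbor count over
#' open neighborhoods. The remaining indexes are the standard normalized
#' variants from the link-prediction literature: `jaccard`, `salton` (cosine),
#' `sorensen`, `hpi` (hub promoted), `hdi` (hub depressed), `adamic_adar`
#' and `resource_allocation`.
#'
#' @return Character vector of index names.
#' @export
similarity_indexes <- function() {
  c("cn_closed", "cn", "jaccard", "salton", "sorensen",
    "hpi", "hdi", "adamic_adar", "resource_allocation")
}

#' Structural similarity between two nodes
#'
#' @param g A `ksim_graph` or edge table.
#' @param u,v Two distinct node labels.
#' @param index Similarity index name, see [similarity_indexes()].
#' @return Non-negative similarity score. Zero whenever the two nodes share no
#'   (closed-)neighborhood overlap, e.g. in different components.
#' @examples
#' tri <- build_graph(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' pair_similarity(tri, "a", "b")            # closed neighborhoods: 3
#' pair_similarity(tri, "a", "b", "jaccard") # 1
#' @export
pair_similarity <- function(g, u, v, index = "cn_closed") {
  g <- as_ksim_graph(g)
  index <- match.arg(index, similarity_indexes())
  ui <- node_index(g, u)
  vi <- node_index(g, v)
  if (ui == vi) rlang::abort("self-similarity undefined")
  sims_to(g, vi, ui, index)
}

#' Rank the neighbors of a node by similarity
#'
#' Neighbors are sorted by the deterministic cascade used throughout the
#' algorithm: similarity descending, then degree ascending (following the rule
#' that among equally similar neighbors the one with the smallest degree is
#' preferred), then canonical node index ascending. Similarity values closer
#' than `tol` are treated as tied before the degree tie-break, so the ranking
#' does not depend on floating-point rounding.
#'
#' @inheritParams pair_similarity
#' @param v Node whose neighbors are ranked.
#' @param tol Absolute tolerance for similarity ties.
#' @return A tibble with columns `neighbor`, `similarity`, `degree`, ordered
#'   best-first; zero rows for an isolated node.
#' @export
rank_neighbors <- function(g, v, index = "cn_closed", tol = 1e-12) {
  g <- as_ksim_graph(g)
  index <- match.arg(index, similarity_indexes())
  vi <- node_index(g, v)
  r <- ranked_neighbors_int(g, vi, index, tol)
  tibble::tibble(
    neighbor = g$nodes[r$idx],
    similarity = r$sim,
    degree = as.integer(g$deg[r$idx])
  )
}

# ---- internal ---------------------------------------------------------------

# similarity of vi to each node in `targets` (vector of node indices != vi)
sims_to <- function(g, vi, targets, index) {
  adjv <- g$adj[[vi]]
  mark <- logical(length(g$nodes))
  mark[adjv] <- TRUE
  deg <- g$deg
  dv <- deg[vi]
  out <- vapply(targets, function(ui) {
    adju <- g$adj[[ui]]
    common <- adju[mark[adju]]
    cn <- length(common)
    du <- deg[ui]
    adjacent <- mark[ui]
    switch(index,
      cn_closed = cn + if (adjacent) 2 else 0,
      cn = cn,
      jaccard = if (du + dv - cn > 0) cn / (du + dv - cn) else 0,
      salton = if (du > 0 && dv > 0) cn / sqrt(du * dv) else 0,
      sorensen = if (du + dv > 0) 2 * cn / (du + dv) else 0,
      hpi = if (min(du, dv) > 0) cn / min(du, dv) else 0,
      hdi = if (max(du, dv) > 0) cn / max(du, dv) else 0,
      adamic_adar = if (cn > 0) sum(1 / log(deg[common])) else 0,
      resource_allocation = if (cn > 0) sum(1 / deg[common]) else 0
    )
  }, numeric(1))
  out
}

# collapse similarities within `tol` into tie classes (1 = most similar);
# values are grouped transitively along the sorted sequence
tie_classes <- function(sim, tol) {
  su <- sort(unique(sim), decreasing = TRUE)
  if (length(su) <= 1L) return(rep(1L, length(sim)))
  cls_of <- cumsum(c(1L, as.integer(-diff(su) > tol)))
  cls_of[match(sim, su)]
}

# neighbors of vi ordered by (tie class, degree asc, index asc)
ranked_neighbors_int <- function(g, vi, index, tol = 1e-12) {
  nbrs <- g$adj[[vi]]
  if (length(nbrs) == 0L) {
    return(list(idx = integer(), sim = numeric(), cls = integer()))
  }
  sim <- sims_to(g, vi, nbrs, index)
  cls <- tie_classes(sim, tol)
  o <- order(cls, g$deg[nbrs], nbrs)
  list(idx = nbrs[o], sim = sim[o], cls = cls[o])
}
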