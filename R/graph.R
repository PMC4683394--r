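#' Build an undirected simple graph from an edge table
#'
#' Constructs the package's graph container from a two-column table of edges
#' (one row per edge, any additional columns are ignored). The graph is
#' undirected and simple: self-loops and duplicate edges are dropped with a
#' warning. Node labels are arbitrary strings or integers; internally they are
#' mapped to contiguous indices in canonical label order (numeric order when
#' every label parses as a number, byte-wise lexicographic order otherwise),
#' which makes every downstream tie-break reproducible across runs and
#' platforms.
#'
#' @param edges A data frame, tibble or two-column matrix whose first two
#'   columns hold the endpoints of each edge. May have zero rows.
#' @param nodes Optional vector of additional node labels, used to declare
#'   isolated (degree-0) nodes that appear in no edge.
#' @return An object of class `ksim_graph`.
#' @examples
#' g <- build_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' g
#' node_degrees(g)
#' @export
build_graph <- function(edges, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character())
  }
  if (is.matrix(edges)) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(edges)) {
    rlang::abort("`edges` must be a data frame or two-column matrix")
  }
  if (nrow(edges) > 0 && ncol(edges) < 2) {
    rlang::abort("`edges` must have at least two columns (edge endpoints)")
  }
  u <- as.character(edges[[1]])
  v <- if (ncol(edges) >= 2) as.character(edges[[2]]) else character()
  if (anyNA(u) || anyNA(v)) rlang::abort("edge endpoints must not be NA")

  labels <- unique(c(u, v, as.character(nodes)))
  if (length(labels) == 0L) {
    rlang::abort("empty graph: no edges and no nodes given")
  }
  labels <- labels[order_labels(labels)]
  n <- length(labels)

  ui <- match(u, labels)
  vi <- match(v, labels)

  loops <- ui == vi
  if (any(loops)) {
    rlang::warn(sprintf("dropping %d self-loop(s)", sum(loops)))
    ui <- ui[!loops]
    vi <- vi[!loops]
  }
  lo <- pmin(ui, vi)
  hi <- pmax(ui, vi)
  key <- (as.numeric(lo) - 1) * n + as.numeric(hi)
  dup <- duplicated(key)
  if (any(dup)) {
    rlang::warn(sprintf("dropping %d duplicate edge(s)", sum(dup)))
    lo <- lo[!dup]
    hi <- hi[!dup]
    key <- key[!dup]
  }
  ord <- order(key)
  lo <- lo[ord]
  hi <- hi[ord]

  ends <- factor(c(lo, hi), levels = seq_len(n))
  adj <- lapply(split(c(hi, lo), ends), function(x) sort(as.integer(x)))
  names(adj) <- NULL

  structure(
    list(
      nodes = labels,
      adj = adj,
      edges = cbind(lo, hi, deparse.level = 0),
      m = length(lo),
      deg = lengths(adj)
    ),
    class = "ksim_graph"
  )
}

#' Coerce to a `ksim_graph`
#'
#' Data frames and matrices are interpreted as edge tables (see
#' [build_graph()]); `ksim_graph` objects pass through unchanged.
#'
#' @param x Object to coerce.
#' @param ... Passed on to methods.
#' @return A `ksim_graph`.
#' @export
as_ksim_graph <- function(x, ...) UseMethod("as_ksim_graph")

#' @export
as_ksim_graph.ksim_graph <- function(x, ...) x

#' @export
as_ksim_graph.data.frame <- function(x, ...) build_graph(x, ...)

#' @export
as_ksim_graph.matrix <- function(x, ...) build_graph(x, ...)

#' @export
as_ksim_graph.default <- function(x, ...) {
  rlang::abort("cannot interpret object as a graph; give a ksim_graph or an edge table")
}

#' @export
print.ksim_graph <- function(x, ...) {
  cat(sprintf(
    "<ksim_graph: %d nodes, %d edges, %d isolated>\n",
    length(x$nodes), x$m, sum(x$deg == 0L)
  ))
  invisible(x)
}

#' Edge table of a graph
#'
#' @param g A `ksim_graph` or edge table.
#' @return A tibble with columns `from` and `to`, one row per (undirected)
#'   edge, endpoints in canonical label order.
#' @export
graph_edges <- function(g) {
  g <- as_ksim_graph(g)
  tibble::tibble(from = g$nodes[g$edges[, 1]], to = g$nodes[g$edges[, 2]])
}

#' Node degrees
#'
#' @param g A `ksim_graph` or edge table.
#' @return A tibble with columns `node` and `degree`, one row per node in
#'   canonical order.
#' @export
node_degrees <- function(g) {
  g <- as_ksim_graph(g)
  tibble::tibble(node = g$nodes, degree = as.integer(g$deg))
}

#' Degree of a single node
#'
#' @param g A `ksim_graph` or edge table.
#' @param v A node label.
#' @return Integer degree (number of neighbors) of `v`.
#' @export
node_degree <- function(g, v) {
  g <- as_ksim_graph(g)
  vi <- node_index(g, v)
  as.integer(g$deg[vi])
}

#' Connected components of a graph
#'
#' Each maximal connected component becomes one community; the community label
#' is the smallest node label in the component (smallest in canonical label
#' order). Degree-0 nodes form singleton components.
#'
#' @param g A `ksim_graph` or edge table.
#' @return A partition tibble with columns `node` and `community`.
#' @export
connected_components <- function(g) {
  g <- as_ksim_graph(g)
  comp <- components_int(g$adj, length(g$nodes))
  tibble::tibble(node = g$nodes, community = g$nodes[comp])
}

# ---- internal helpers -------------------------------------------------------

# canonical label order: numeric when all labels parse, else C-locale radix
order_labels <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (length(x) > 0 && !anyNA(num)) {
    order(num, method = "radix")
  } else {
    order(x, method = "radix")
  }
}

node_index <- function(g, v) {
  vi <- match(as.character(v), g$nodes)
  if (anyNA(vi)) {
    rlang::abort(sprintf("unknown node(s): %s",
                         paste(as.character(v)[is.na(vi)], collapse = ", ")))
  }
  vi
}

# BFS component labels; the label of each component is its smallest node index
components_int <- function(adj, n, extra_adj = NULL) {
  comp <- integer(n)
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    comp[s] <- s
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nbrs <- adj[[v]]
      if (!is.null(extra_adj)) nbrs <- c(nbrs, extra_adj[[v]])
      for (w in nbrs) {
        if (comp[w] == 0L) {
          comp[w] <- s
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
  }
  comp
}

# Convert a partition (tibble node/community, or named vector community[node])
# into an integer membership vector aligned with g$nodes, together with the
# community label table in canonical label order (so that id order == label
# order, the order used by every "smallest label" tie-break).
partition_membership <- function(g, p) {
  if (inherits(p, "ksim_result")) p <- p$partition
  if (is.data.frame(p)) {
    if (!all(c("node", "community") %in% names(p))) {
      if (ncol(p) >= 2) {
        p <- stats::setNames(as.character(p[[2]]), as.character(p[[1]]))
      } else {
        rlang::abort("partition table needs `node` and `community` columns")
      }
    } else {
      p <- stats::setNames(as.character(p$community), as.character(p$node))
    }
  } else if (!is.null(names(p))) {
    p <- stats::setNames(as.character(p), names(p))
  } else {
    rlang::abort("partition must be a data frame or a named vector")
  }
  if (anyDuplicated(names(p))) rlang::abort("duplicate node rows in partition")
  idx <- match(g$nodes, names(p))
  if (anyNA(idx)) {
    rlang::abort("partition is not total: some graph nodes have no community")
  }
  lab <- unname(p[idx])
  levels <- unique(lab)
  levels <- levels[order_labels(levels)]
  list(ids = match(lab, levels), labels = levels)
}

membership_to_partition <- function(g, ids, labels) {
  tibble::tibble(node = g$nodes, community = labels[ids])
}
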