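#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kSIM result into the partition tibble
#'
#' @param x A `ksim_result`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `community` and `degree`.
#' @export
tidy.ksim_result <- function(x, ...) {
  dplyr::left_join(x$partition, node_degrees(x$graph), by = "node")
}

#' One-row summary of a kSIM result
#'
#' @param x A `ksim_result`.
#' @param ... Unused.
#' @return A one-row tibble: `communities`, `iterations`, `converged`,
#'   `isolated`, `modularity`, `minmaxcut`, `coverage`.
#' @export
glance.ksim_result <- function(x, ...) {
  q <- partition_quality(x$graph, x$partition)
  tibble::tibble(
    communities = q$communities,
    iterations = x$iterations,
    converged = x$converged,
    isolated = length(x$isolated_nodes),
    modularity = q$modularity,
    minmaxcut = q$minmaxcut,
    coverage = q$coverage
  )
}

#' Tidy an edge-fraction matrix into long form
#'
#' @param x An `edge_fraction_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per community pair (`i <= j`): `community_i`,
#'   `community_j`, `edges`, `fraction`.
#' @export
tidy.edge_fraction_matrix <- function(x, ...) {
  K <- length(x$labels)
  idx <- which(upper.tri(x$counts, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    community_i = x$labels[idx[, 1]],
    community_j = x$labels[idx[, 2]],
    edges = as.integer(x$counts[idx]),
    fraction = x$counts[idx] / x$m
  )
}

#' Plot the community structure of a kSIM result
#'
#' Draws the network with a force-directed layout, nodes colored by detected
#' community.
#'
#' @param object A `ksim_result`.
#' @param node_size Point size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ksim_result <- function(object, node_size = 2, ...) {
  g <- object$graph
  ig <- igraph::graph_from_edgelist(
    cbind(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]]),
    directed = FALSE
  )
  ig <- ig + igraph::vertices(setdiff(g$nodes, igraph::V(ig)$name))
  xy <- igraph::layout_with_fr(ig)
  lay <- tibble::tibble(node = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2])
  lay <- dplyr::left_join(lay, object$partition, by = "node")
  seg <- tibble::tibble(
    x = lay$x[match(g$nodes[g$edges[, 1]], lay$node)],
    y = lay$y[match(g$nodes[g$edges[, 1]], lay$node)],
    xend = lay$x[match(g$nodes[g$edges[, 2]], lay$node)],
    yend = lay$y[match(g$nodes[g$edges[, 2]], lay$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$community),
      size = node_size
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(
      color = "community",
      title = sprintf("kSIM communities (k = %d, %s)",
                      object$config$k, object$config$index)
    )
}

#' Community size distribution of a partition
#'
#' @param p A partition (tibble, named vector or `ksim_result`).
#' @return A ggplot bar chart of community sizes, largest first.
#' @export
plot_community_sizes <- function(p) {
  vec <- as_partition_vector(p)
  sizes <- sort(table(vec), decreasing = TRUE)
  df <- tibble::tibble(
    community = factor(names(sizes), levels = names(sizes)),
    size = as.integer(sizes)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$community, y = .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "community", y = "nodes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
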