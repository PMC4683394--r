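#' Community edge-fraction matrix
#'
#' Tabulates, for a partition of a graph, the symmetric K x K matrix of edge
#' counts (diagonal entries are the internal edge counts of each community,
#' off-diagonal entries the edge counts between community pairs) and the
#' corresponding fraction matrix. Fractions are normalized so the whole matrix
#' sums to one: each internal edge contributes `1/m` to its diagonal cell,
#' each cut edge contributes `1/(2m)` to each of the two symmetric
#' off-diagonal cells. Row sums of the fraction matrix are the `a_i` terms of
#' modularity.
#'
#' @param g A `ksim_graph` or edge table.
#' @param p A partition (tibble with `node`/`community`, named vector, or
#'   `ksim_result`).
#' @return An object of class `edge_fraction_matrix` with elements `counts`,
#'   `fractions`, `row_sums`, `labels` and `m`.
#' @export
edge_fraction_matrix <- function(g, p) {
  g <- as_ksim_graph(g)
  if (g$m == 0L) rlang::abort("no edges: edge fractions undefined")
  pm <- partition_membership(g, p)
  K <- length(pm$labels)
  ci <- pm$ids[g$edges[, 1]]
  cj <- pm$ids[g$edges[, 2]]
  counts <- community_edge_counts(ci, cj, K)
  fractions <- counts / g$m
  off <- row(fractions) != col(fractions)
  fractions[off] <- fractions[off] / 2
  dimnames(counts) <- dimnames(fractions) <- list(pm$labels, pm$labels)
  structure(
    list(
      counts = counts,
      fractions = fractions,
      row_sums = rowSums(fractions),
      labels = pm$labels,
      m = g$m
    ),
    class = "edge_fraction_matrix"
  )
}

#' @export
print.edge_fraction_matrix <- function(x, ...) {
  cat(sprintf("<edge_fraction_matrix: %d communities, %d edges>\n",
              length(x$labels), x$m))
  print(x$counts)
  invisible(x)
}

#' Modularity of a partition
#'
#' Newman-Girvan modularity \eqn{Q = \sum_i (e_{ii} - a_i^2)} over the edge
#' fraction matrix: the observed fraction of internal edges of each community
#' minus the fraction expected if edges were wired at random preserving
#' degrees. Higher is better; the trivial one-community partition scores 0.
#'
#' @inheritParams edge_fraction_matrix
#' @return Modularity Q (at most 1).
#' @examples
#' g <- ksim_fixture("karate")
#' partition_modularity(g, ksim_detect(g, k = 1))
#' @export
partition_modularity <- function(g, p) {
  efm <- edge_fraction_matrix(g, p)
  sum(diag(efm$fractions) - efm$row_sums^2)
}

#' MinMaxCut of a partition
#'
#' The sum over communities of external-to-internal edge-count ratios,
#' \eqn{\sum_i ext(C_i) / int(C_i)}. Smaller values mean denser,
#' better-separated communities; a partition with no cut edges scores 0.
#'
#' @inheritParams edge_fraction_matrix
#' @param permissive If `TRUE`, a community with external edges but no
#'   internal edge contributes `Inf` instead of raising an error.
#' @return Non-negative MinMaxCut value.
#' @export
partition_minmaxcut <- function(g, p, permissive = FALSE) {
  efm <- edge_fraction_matrix(g, p)
  internal <- diag(efm$counts)
  external <- rowSums(efm$counts) - internal
  bad <- internal == 0 & external > 0
  if (any(bad) && !permissive) {
    rlang::abort(paste0(
      "undefined MinMaxCut: community with no internal edge (",
      paste(efm$labels[bad], collapse = ", "),
      "); use permissive = TRUE for +Inf"
    ))
  }
  ratio <- ifelse(external == 0, 0, external / internal)
  sum(ratio)
}

#' Coverage of a partition
#'
#' Fraction of all edges that fall inside communities,
#' \eqn{\sum_i int(C_i) / m}. 1 means no cut edges.
#'
#' @inheritParams edge_fraction_matrix
#' @return Coverage in \[0, 1\].
#' @export
partition_coverage <- function(g, p) {
  efm <- edge_fraction_matrix(g, p)
  sum(diag(efm$counts)) / efm$m
}

#' All partition quality measures at once
#'
#' @inheritParams edge_fraction_matrix
#' @param measures Subset of `c("modularity", "minmaxcut", "coverage")`.
#' @return A one-row tibble with one column per requested measure plus
#'   `communities` (the number of communities).
#' @export
partition_quality <- function(g, p,
                              measures = c("modularity", "minmaxcut",
                                           "coverage")) {
  measures <- match.arg(measures, several.ok = TRUE)
  g <- as_ksim_graph(g)
  out <- tibble::tibble(communities = length(partition_membership(g, p)$labels))
  if ("modularity" %in% measures) {
    out$modularity <- partition_modularity(g, p)
  }
  if ("minmaxcut" %in% measures) {
    out$minmaxcut <- partition_minmaxcut(g, p, permissive = TRUE)
  }
  if ("coverage" %in% measures) {
    out$coverage <- partition_coverage(g, p)
  }
  out
}

#' Normalized mutual information between two partitions
#'
#' \eqn{NMI = 2 I(X;Y) / (H(X) + H(Y))} computed from the joint distribution
#' of community memberships over the (shared) node set; natural logarithms,
#' zero joint cells contribute nothing. The degenerate case where both
#' partitions are single-community (both entropies zero) scores 1. A
#' \eqn{I/\sqrt{H(X) H(Y)}} variant is selectable.
#'
#' @param x,y Partitions over the same node set (tibble with
#'   `node`/`community`, named vector, or `ksim_result`).
#' @param variant `"sum"` (default, `2I/(H(X)+H(Y))`) or `"sqrt"`
#'   (`I/sqrt(H(X)H(Y))`).
#' @return NMI in \[0, 1\]; 1 for identical partitions, 0 for independent ones.
#' @export
partition_nmi <- function(x, y, variant = c("sum", "sqrt")) {
  variant <- match.arg(variant)
  x <- as_partition_vector(x)
  y <- as_partition_vector(y)
  if (length(x) != length(y) || !setequal(names(x), names(y))) {
    rlang::abort("partitions are over different node sets")
  }
  y <- y[names(x)]
  tab <- table(unname(x), unname(y))
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  pos <- pxy > 0
  mi <- sum(pxy[pos] * log(pxy[pos] / (px %o% py)[pos]))
  if (variant == "sum") {
    if (hx + hy == 0) return(1)
    2 * mi / (hx + hy)
  } else {
    if (hx == 0 && hy == 0) return(1)
    if (hx == 0 || hy == 0) return(0)
    mi / sqrt(hx * hy)
  }
}

# partition -> named character vector community[node]
as_partition_vector <- function(p) {
  if (inherits(p, "ksim_result")) p <- p$partition
  if (is.data.frame(p)) {
    if (all(c("node", "community") %in% names(p))) {
      stats::setNames(as.character(p$community), as.character(p$node))
    } else if (ncol(p) >= 2) {
      stats::setNames(as.character(p[[2]]), as.character(p[[1]]))
    } else {
      rlang::abort("partition table needs `node` and `community` columns")
    }
  } else if (!is.null(names(p))) {
    stats::setNames(as.character(p), names(p))
  } else {
    rlang::abort("partition must be a data frame or a named vector")
  }
}
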