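#' Read a graph from a file
#'
#' Supports three formats. `edgelist`: whitespace-separated node pairs, one
#' edge per line, `#` starts a comment; a numeric third field (a weight) is
#' ignored with a warning. `gml` and `pajek` (`*Vertices` / `*Edges`) are read
#' through igraph and coerced to undirected simple graphs; edge weights and
#' directions are dropped with a warning.
#'
#' @param path Path to the file.
#' @param format One of `"edgelist"`, `"gml"`, `"pajek"`.
#' @return A `ksim_graph`.
#' @export
read_graph <- function(path, format = c("edgelist", "gml", "pajek")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "ksim_io_error")
  }
  if (format == "edgelist") {
    return(read_edgelist(path))
  }
  ig <- igraph::read_graph(path, format = format)
  if (igraph::is_directed(ig)) {
    rlang::warn("directed input coerced to undirected")
    ig <- igraph::as_undirected(ig, mode = "collapse")
  }
  if ("weight" %in% igraph::edge_attr_names(ig)) {
    rlang::warn("edge weights ignored (graphs are treated as unweighted)")
  }
  labels <- vertex_labels(ig)
  el <- igraph::as_edgelist(ig, names = FALSE)
  if (nrow(el) == 0L && igraph::vcount(ig) == 0L) {
    rlang::abort("empty graph", class = "ksim_io_error")
  }
  build_graph(
    data.frame(from = labels[el[, 1]], to = labels[el[, 2]]),
    nodes = labels
  )
}

#' Write a graph as a plain edge list
#'
#' @param g A `ksim_graph` or edge table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  g <- as_ksim_graph(g)
  edges <- graph_edges(g)
  writeLines(paste(edges$from, edges$to), path)
  invisible(path)
}

#' Read / write a partition TSV
#'
#' Partitions are stored as two tab-separated columns, `node` then
#' `community`, one row per node, no header by default. Written rows are
#' sorted by node (canonical label order); labels round-trip verbatim.
#'
#' @param path Path to the TSV file.
#' @param header Whether the file has (or should be written with) a
#'   `node`/`community` header row.
#' @return `read_partition()`: a partition tibble; `write_partition()`:
#'   `path`, invisibly.
#' @export
read_partition <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "ksim_io_error")
  }
  df <- utils::read.table(path, header = header, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    rlang::abort("empty or malformed partition file", class = "ksim_io_error")
  }
  p <- tibble::tibble(node = df[[1]], community = df[[2]])
  if (anyDuplicated(p$node)) {
    rlang::abort("duplicate node rows in partition file", class = "ksim_io_error")
  }
  p
}

#' @param p A partition (tibble with `node`/`community` columns, named vector,
#'   or `ksim_result`).
#' @rdname read_partition
#' @export
write_partition <- function(p, path, header = FALSE) {
  vec <- as_partition_vector(p)
  nodes <- names(vec)
  ord <- order_labels(nodes)
  df <- data.frame(node = nodes[ord], community = unname(vec)[ord])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

# ---- internal ---------------------------------------------------------------

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    rlang::abort(
      sprintf("malformed edge at line %d of %s", lineno[which(bad)[1]], path),
      class = "ksim_io_error"
    )
  }
  if (any(lengths(fields) > 2L)) {
    extra <- vapply(fields[lengths(fields) > 2L], `[`, "", 3L)
    if (all(!is.na(suppressWarnings(as.numeric(extra))))) {
      rlang::warn("edge weights ignored (graphs are treated as unweighted)")
    } else {
      rlang::abort(
        sprintf("malformed edge at line %d of %s: too many fields",
                lineno[which(lengths(fields) > 2L)[1]], path),
        class = "ksim_io_error"
      )
    }
  }
  build_graph(data.frame(
    from = vapply(fields, `[`, "", 1L),
    to = vapply(fields, `[`, "", 2L)
  ))
}

vertex_labels <- function(ig) {
  va <- igraph::vertex_attr_names(ig)
  if ("name" %in% va) {
    as.character(igraph::vertex_attr(ig, "name"))
  } else if ("label" %in% va) {
    as.character(igraph::vertex_attr(ig, "label"))
  } else if ("id" %in% va) {
    as.character(igraph::vertex_attr(ig, "id"))
  } else {
    as.character(seq_len(igraph::vcount(ig)))
  }
}
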