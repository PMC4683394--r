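#' Catalog of bundled classic test networks
#'
#' Five small public networks are the standard desk-scale test bed for
#' community detection. Three are bundled with the package as plain-text
#' files: Zachary's karate club (34 nodes / 78 edges), the Les Miserables
#' character co-appearance network (77 / 254) and the American college
#' football schedule (115 / 613; the original GML file carries 616 edge
#' records of which 3 are duplicate pairs, dropped when the simple graph is
#' built). The dolphin social network (62 / 159) and
#' the political-books co-purchase network (105 / 441) are listed for
#' reference but are not redistributed here; load a local copy with
#' [read_graph()] instead.
#'
#' @return A tibble with columns `name`, `nodes`, `edges`, `communities`
#'   (reference community count), `format`, `file` (path, `NA` when not
#'   bundled) and `available`.
#' @export
ksim_fixtures <- function() {
  files <- c(
    karate = "karate.edges",
    dolphins = NA_character_,
    lesmis = "lesmis.edges",
    football = "football.gml",
    polbooks = NA_character_
  )
  paths <- vapply(files, function(f) {
    if (is.na(f)) NA_character_
    else system.file("extdata", f, package = "ksim")
  }, character(1))
  tibble::tibble(
    name = names(files),
    nodes = c(34L, 62L, 77L, 115L, 105L),
    edges = c(78L, 159L, 254L, 613L, 441L),
    communities = c(2L, 2L, 6L, 11L, 3L),
    format = c("edgelist", NA, "edgelist", "gml", NA),
    file = unname(paths),
    available = !is.na(unname(paths)) & nzchar(unname(paths))
  )
}

#' Load a bundled test network
#'
#' @param name Fixture name, see [ksim_fixtures()].
#' @return A `ksim_graph`; the loaded size is checked against the catalog.
#' @examples
#' ksim_fixture("karate")
#' @export
ksim_fixture <- function(name) {
  cat_ <- ksim_fixtures()
  row <- cat_[cat_$name == name, ]
  if (nrow(row) == 0L) {
    rlang::abort(sprintf(
      "unknown fixture '%s'; available: %s",
      name, paste(cat_$name, collapse = ", ")
    ))
  }
  if (!row$available) {
    rlang::abort(sprintf(
      "fixture '%s' is not bundled with the package; load a local copy with read_graph()",
      name
    ), class = "ksim_fixture_unavailable")
  }
  g <- suppressWarnings(read_graph(row$file, format = row$format))
  if (length(g$nodes) != row$nodes || g$m != row$edges) {
    rlang::abort(sprintf(
      "fixture '%s' has unexpected size (%d nodes, %d edges; expected %d, %d)",
      name, length(g$nodes), g$m, row$nodes, row$edges
    ))
  }
  g
}
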