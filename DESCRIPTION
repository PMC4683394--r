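Package: ksim
Title: Community Detection by Maximal Neighbor Similarity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bottom-up community detection for undirected networks. Each node
    is anchored to one of its k most similar direct neighbors (structural
    similarity with a deterministic degree/index tie-break cascade), connected
    unions of anchor pairs seed the communities, and the seed partition is
    refined by a node membership criterion (plurality of neighbors) and a
    community criterion (more internal edges than edges to any single other
    community). Includes partition quality measures (modularity, MinMaxCut,
    coverage, normalized mutual information), an LFR-style benchmark generator
    with planted ground truth, readers for edge-list, GML and Pajek files,
    bundled classic test networks, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
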