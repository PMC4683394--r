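---
title: "Community detection by maximal neighbor similarity: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community detection by maximal neighbor similarity: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ksim)
```

## The model

`ksim` detects communities in undirected, unweighted, simple networks from a
bottom-up premise: a community is what you get when every node is glued to one
of its most structurally similar neighbors and the resulting clumps are then
asked to satisfy two local criteria.

1. **Anchoring.** Every node `v` with at least one neighbor selects an
   *anchor*: among its `k` most similar neighbors, the one with the smallest
   degree (degree ties fall back to higher similarity, then to the canonical
   node order). The default similarity is the closed-neighborhood
   common-neighbor count `|N[u] ∩ N[v]|`, where `N[x]` includes `x` itself;
   adjacent nodes therefore always score at least 2, which keeps the index
   informative on triangle-free stretches while ordering pairs exactly like
   the plain common-neighbor count. The connected components of the anchor
   graph are the seed communities.
2. **Membership criterion.** A node should have more neighbors inside its own
   community than inside any other single community. Refinement passes over
   the nodes in canonical order and reassigns each node to the community
   holding a strict plurality of its neighbors.
3. **Community criterion.** A community should have strictly more internal
   edges than edges to any single other community. Communities violating this
   are merged into the neighbor community they share the most edges with,
   smallest community first, until every community complies.

The outer loop alternates one membership sweep with community-criterion
enforcement until a full pass changes nothing. On all bundled networks this
takes at most three passes; the `max_iterations` cap (default 100) is a
safety net, not a tuning knob. There is no randomness anywhere in the
pipeline: every tie in every stage is broken by an explicit deterministic
cascade, so repeated runs give identical partitions by construction, not by
seeding.

## Tunable parameters

* `k` (default 1): size of the anchor candidate set, from 1 up to the maximum
  degree. `k = 1` anchors each node to its single most similar neighbor and
  recovers the coarse, consensus partitions of the classic test networks.
  Larger `k` lets low-degree neighbors win the anchor role, which splits off
  small, tightly knit satellite groups (on the karate network, `k = 3`
  separates the five-node periphery around the instructor).
* `index` (default `cn_closed`): any of nine local similarity indexes
  (`similarity_indexes()`). The normalized variants (`jaccard`, `salton`,
  `sorensen`, `hpi`, `hdi`) and the degree-weighted ones (`adamic_adar`,
  `resource_allocation`) reorder anchor choices mainly where hubs and
  near-regular regions meet; on the football schedule network the
  degree-weighted indexes reunite a conference that the raw counts leave
  split.
* `nth` (optional): multi-resolution mode. Instead of the best of the top
  `k`, every node anchors to its `nth` most similar neighbor (the least
  similar one if `nth` exceeds the degree). Increasing `nth` anchors nodes
  through progressively weaker ties, and the partitions coarsen into a
  hierarchy; the package asserts this nesting on a constructed toy (four
  triangles with strong pair bonds and one weak cross bond), not as a
  universal theorem.
* Similarity ties are declared at an absolute tolerance of `1e-12` before the
  degree tie-break, so rankings do not depend on floating-point noise across
  platforms.

## Tie-breaking: the two rules that matter

Two refinement ties have more than cosmetic consequences, and both are
resolved by the similarity signal rather than by label order:

* **Plurality ties in the membership sweep.** When several communities tie
  for the plurality of a node's neighbors and the current community is not
  among them, the node joins the tied community that contains its most
  similar neighbor. This is the same signal that drives anchoring; resolving
  the tie by smallest community label instead can send a node against its
  strongest tie (on the karate network it misplaces the node whose best
  neighbor sits across the factions, and the k = 3 partition degrades).
* **Merge-target ties in community enforcement.** When a violating community
  has equal cut to several candidates, it merges into the *smallest* of them
  (then smallest label). Fragments of a natural community thereby coalesce
  with each other before any of them can be absorbed by a large neighbor;
  preferring the candidate with more internal edges collapses satellite
  groups into hubs and loses resolution.

## Quality measures

For a partition with edge-count matrix `e` (diagonal: internal edges;
off-diagonal: cut edges):

* modularity `Q = Σ_i (e_ii − a_i²)` over edge fractions, with `a_i` the row
  sums — observed internal fraction minus the degree-preserving random
  expectation;
* MinMaxCut `Σ_i ext(C_i)/int(C_i)` on raw counts (lower is better; 0 iff no
  cut edge; a community with external but no internal edges makes it
  undefined, or `+Inf` under `permissive = TRUE`);
* coverage `Σ_i int(C_i)/m`;
* NMI `2·I(X;Y)/(H(X)+H(Y))` with natural logarithms; zero joint cells
  contribute nothing, and two single-community partitions compare as 1. The
  `I/√(H(X)H(Y))` variant is selectable; the normalization makes the
  logarithm base irrelevant.

A note on edge-count conventions: the classic college-football file carries
616 edge records of which three are duplicate pairs. This package's graph is
simple (613 edges); published tables computed on the raw record list shift
the third decimal of modularity and coverage. The fixture documentation
records both counts, and cross-checks against the raw file are done with
igraph on the source records.

## The synthetic benchmark

`generate_lfr()` emulates the standard community-detection benchmark family:
truncated power-law degrees (`gamma`, on `[kmin, kmax]`), truncated power-law
community sizes (`beta`, on `[smin, smax]`), and a mixing parameter `mu`
giving the fraction of each node's edges that leave its community. The
defaults are the study conditions used throughout the package's tests:
`n = 5000`, `kmin = 15`, `kmax = 25`, `gamma = 2`, `beta = 1`. The size
bounds `smin = 20, smax = 100` are conventional values for this benchmark
family, chosen once; they must satisfy `smin > kmin` so every node fits its
community.

The construction is a simplified configuration model, not the full original
rewiring machinery: each node splits its degree into
`round((1 − mu)·degree)` internal and the remaining external stubs (at least
one of each when `mu` is interior), nodes are assigned to communities large
enough to hold their internal degree, and stubs are matched by repeated
random pairing with rejection of self-loops, duplicates and (for external
stubs) within-community pairs. Unmatched residue is dropped and reported; at
`n ≥ 1000` it stays well under 1% of stubs. What this delivers — and all the
tests rely on — are correct (degree, size, mixing) marginals: realized mixing
tracks requested `mu` to within ±0.005 in practice. What it does not deliver:
exact degree sequences after residue dropping, degree–community-size
correlations of the original generator, or any guarantee that communities are
internally connected at high `mu`. Passing recovery tests on these graphs
therefore demonstrates robustness to stochastic mixing noise, not performance
on real-world degree–geometry coupling.

`generate_planted_partition()` is the controlled two-parameter fixture
(within-block probability `p_in`, between-block `p_out`) used where an exact
expectation is needed in tests.

## Numerical and degenerate-input choices

* Node labels sort numerically when every label parses as a number,
  byte-wise lexicographically otherwise; all "smallest label/index"
  tie-breaks refer to this one order.
* Degree-0 nodes are kept, reported as `isolated_nodes`, and emitted as
  singleton communities exempt from the community criterion.
* Self-loops, duplicate edges and edge weights are dropped with warnings;
  directed input is collapsed to undirected.
* `edge_fraction_matrix()` refuses edgeless graphs; NMI refuses partitions
  over different node sets; degree sums are forced even before stub matching.
* Iteration counts include the final pass that confirms convergence, so the
  minimum is 1.

## Problem sizes used in the checks

The bundled experiments run at the sizes the package is meant for at a desk:
the five classic networks (34–115 nodes) and 25 synthetic benchmarks of
5,000 nodes (five mixing values × five replicates), each generated and
analyzed in a few seconds. Exhaustive oracle comparisons (modularity against
the per-pair definition) are exhaustive over all labeled 4-node graphs and
all their set partitions, and sampled over 5–7-node graphs; full enumeration
of all 7-node graphs is astronomically large, so sampling is the honest
substitute.

## Known limitations

* Hard partitions only: overlapping membership is not emitted, although
  boundary nodes can be read off as nodes with external edges.
* Unweighted, undirected, static graphs only.
* The community criterion can only merge; resolution below the seed
  partition must come from the anchoring stage (via `k` or `nth`).
* On near-regular graphs (every neighborhood looks alike) the similarity
  signal carries little information and results lean on the deterministic
  tie cascade; they are reproducible but structurally shallow there.
* The benchmark generator's simplifications above.
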