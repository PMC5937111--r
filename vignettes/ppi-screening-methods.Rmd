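---
title: "Methods: hub-bottleneck screening of PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub-bottleneck screening of PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

## The screening model

`ppiscreen` implements a topological screening cascade for candidate
biomarker discovery from protein-protein interaction (PPI) networks.
The premise is the standard one in network medicine: proteins that are
both highly connected (*hubs*) and that mediate many shortest paths
(*bottlenecks*) are disproportionately likely to be functionally
central, and their intersection — refined by module membership and a
final connectivity cutoff — yields a small, testable candidate panel.

The cascade is, for each regulation direction separately:

1. **Network construction.** A list of differentially expressed
   proteins (the *seeds*) is expanded to its one-hop neighbourhood in a
   background interactome; the analysed network is the induced subgraph
   on seeds plus first neighbours. Hop count is a parameter
   (`expand_seed_neighborhood(..., hops = 1)`); one hop is the
   conventional choice and the default. Whether neighbour–neighbour
   edges belong in the network is a genuinely open design point; we
   keep them (induced subgraph), because dropping them biases degree
   estimates of neighbour nodes downward and MCODE assumes an honest
   local topology.
2. **Centrality.** Degree and betweenness centrality (BC) per node. BC
   is computed by the single-sweep accumulation algorithm (one
   breadth-first geodesic-counting pass per source, reverse dependency
   accumulation; `O(VE)` for unweighted graphs), implemented in C++ and
   cross-checked in the tests against both an adjacency-matrix-power
   geodesic-counting oracle and an independent library implementation.
   Reported BC is normalized by `2/((n-1)(n-2))` so values lie in
   `[0, 1]`, matching what network-analysis GUIs print. Disconnected
   inputs are legal: pair sums run over reachable pairs, with one
   global normalisation. Note that some published tables report BC
   values of exactly 1.0 for internal nodes of large networks, which
   cannot arise under this normalisation; such values likely reflect a
   tool-specific per-component rescaling that we deliberately do not
   imitate.
3. **Hubs, bottlenecks, and their intersection.** The top `k = 20`
   nodes by degree are hubs, the top 20 by BC are bottlenecks, and
   their literal case-sensitive intersection is the *hub-bottleneck*
   set. Ranks break ties by symbol, ascending, so every run is
   deterministic; a tie at the boundary is therefore resolved
   lexicographically (and reported via `message()`).
4. **Module detection (MCODE).** Molecular complexes are detected with
   the canonical vertex-weighting / seeded-expansion procedure (below)
   using node score cutoff 0.2, k-core 2, degree cutoff 2, max depth
   100, haircut on, fluff off. Modules with score > 3 **and** more than
   6 nodes (both strict) are retained for functional analysis.
5. **Module residency and the panel.** Hub-bottlenecks are kept only if
   they belong to a retained module; of those, the ones with degree at
   or above `degree_panel_cutoff = 1200` form the final panel. The
   cutoff is *inclusive*: in the anchoring study a protein of degree
   1208 is kept while one at 1158 is dropped, which both strict and
   inclusive readings satisfy; we fix the inclusive reading and
   document it here.

The cascade is monotone by construction
(`panel ⊆ module_resident ⊆ hub_bottlenecks ⊆ hubs ∪ bottlenecks`),
and `screen_cascade()` asserts this on every run.

## MCODE

The literature names MCODE and its parameters far more often than its
mechanics, so the implementation pins every step down:

* **Vertex weighting.** For each vertex `v` with degree ≥
  `degree_cutoff`, take the subgraph induced on the closed
  neighbourhood `N[v]`, find its highest k-core (iterated peeling), and
  set `w(v) = k_max × density` of that core (the *core-clustering
  coefficient*). Vertices under the degree cutoff get weight 0. On a
  triangle every vertex weighs `2 × 1.0 = 2.0`.
* **Expansion.** Complexes grow breadth-first from the highest-weight
  unassigned vertex; a neighbour joins iff it is unassigned and its
  weight strictly exceeds `seed_weight × (1 − node_score_cutoff)`;
  expansion depth is capped by `max_depth`. Vertices never join two
  complexes (pre-fluff), so complexes are vertex-disjoint.
* **Post-processing.** Complexes lacking a `k_core`-core are discarded;
  *haircut* iteratively trims members with fewer than 2 intra-complex
  edges (equivalently, keeps the complex's 2-core); *fluff* (off by
  default) adds boundary neighbours whose closed-neighbourhood density
  exceeds `fluff_density`, and fluffed nodes may be shared.
* **Scoring.** `score = density × n_nodes` with
  `density = 2E/(n(n−1))`. Published module tables are not always
  consistent with this definition (a 65-node, 358-edge module scored
  7.6 would have density-based score ≈ 11.2), so printed scores are
  treated as informational, never as acceptance values.
* **Determinism.** Every iteration order (seed choice, frontier order,
  output order) is tie-broken by symbol; identical inputs give
  identical output.

## Enrichment

Per retained module, every annotation term with overlap ≥ 1 is tested
with the one-sided hypergeometric over-representation test against the
catalog universe (`stats::phyper` upper tail; validated against
exhaustive combinatorial enumeration for small universes). Correction
uses the Bonferroni step-down (Holm) procedure via
`stats::p.adjust(method = "holm")`, applied *per module across its
tested terms*: the anchoring study reports modules independently and is
silent on the correction scope, so the per-module reading is fixed
here. Terms are then grouped by Cohen's kappa agreement of their
membership indicator vectors, single-linkage at κ ≥ 0.4 (connected
components of the κ-graph); group ids are positions of each component's
lexicographically smallest term, so grouping is order-invariant.
Kappa conventions for degenerate tables: identical indicator vectors
score 1 even when expected agreement is 1; non-identical vectors with
expected agreement 1 score 0. Agreement is measured over the catalog
universe; iterative group-merging heuristics of GUI tools are out of
scope. The top 3 terms by corrected p (ties by term id) are reported
per module.

## The packaged study fixtures

The package ships, as plain-text fixtures, the printed tables of a
proteomics-literature screen of laryngeal squamous cell carcinoma: 136
up- and 139 down-regulated proteins, the top-20 hub (degree) and
bottleneck (BC) blocks of the up- and down-regulated networks, and the
detected modules with their hub proteins. Identifier strings are kept
exactly as printed — including entries that are aliases of the same
protein under different naming systems — because the printed screening
counts are only reproducible under literal case-sensitive matching.
Running the cascade on these fixtures (`laryngeal_screen()`) reproduces
the published counts: 15 and 11 hub-bottlenecks, 26 total, 12
module-resident proteins, and the four-protein panel YWHAZ, PPP2R1A,
HSP90AA1, CALM3.

Two fixture-specific choices deserve a note. First, the printed module
table lists only each module's *hub* proteins, not full memberships, and
flags its hub-bottleneck members with an asterisk; the fixture cascade
therefore uses the flagged proteins as the module-membership universe —
the only printed anchor for module residency — while synthetic runs use
full module memberships. Second, the source tables are not perfectly
internally consistent about one protein (flagged as a hub-bottleneck in
the centrality tables but not in the module table); the fixture encodes
the module table exactly as printed, which is what the published
downstream counts follow. Because only the top-20 blocks of each
centrality table are printed, symbols appearing in just one block
receive 0 for the missing quantity; any value below the printed block
minimum preserves the printed ranking, so this choice is
inconsequential.

## The synthetic interactome

The interactome database behind the anchoring study is not named, so
exact network reconstruction is impossible. Instead the generator
(`synthetic_spec()`, `generate_interactome()`, `draw_seed_list()`,
`generate_annotations()`) produces instances with the statistical
structure the pipeline assumes:

* a **scale-free backbone** by linear preferential attachment
  (2000 nodes, 2 edges per arriving node by default) — the simplest
  generative model with the hub-dominated, right-skewed degree
  distribution the hub/bottleneck screen presumes;
* **planted dense modules** (3 modules of 10 nodes at internal density
  0.9 by default) standing in for molecular complexes. Memberships are
  disjoint and mutually non-adjacent in the backbone — planted
  complexes are meant to be *distinct* structures, and a single bridge
  edge between two planted cliques would let seeded expansion
  legitimately absorb one into the other, turning a generator artifact
  into an apparent detection failure;
* a **seed list** (140 proteins by default, the order of a typical
  differential-expression study) sampled uniformly, with a swap-in
  guarantee of at least one seed per planted module;
* a **planted-enrichment catalog** (50 terms of 10–50 genes, the
  typical size range of informative GO biological-process terms) in
  which each planted module has one matched term covering 80% of its
  members plus random background genes, the rest being uniform random
  sets.

All outputs are deterministic given `rng_seed` (sub-streams for
backbone, seeds, and annotations are derived by fixed offsets). Node
labels are synthetic (`G000001`, ...) to keep fixtures disjoint from
real gene namespaces.

What the generator does **not** emulate: degree-degree correlations and
clustering profiles of curated interactomes, study-bias (ascertainment)
effects, overlapping complexes, the GO term hierarchy, and
direction-specific biology. Passing recovery tests therefore shows the
algorithms are implemented correctly and behave as designed on networks
with the assumed structure — not that the biological conclusions of any
particular study are right.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline at the
study scale (2000-node interactomes, 140 seeds) and validate the
numerics on small instances where brute force is exact: betweenness
against geodesic enumeration on 200 random graphs of up to 12 nodes
(tolerance 1e-9), neighbourhood-core weights against a peeling oracle
on graphs of up to 10 nodes, hypergeometric tails against exhaustive
enumeration for universes up to 25 (tolerance 1e-12), and Holm against
its direct formula for up to 6 tests. Planted-module recovery is
asserted at ≥ 80% Jaccard per module across generator seeds 1–5.

Degenerate inputs are defined, not special-cased: empty networks give
empty tables; graphs with fewer than 3 nodes have BC 0; modules of one
node cannot survive the k-core filter; `top_k` larger than the table
returns everything with a warning; a candidate without a degree entry
is a hard error rather than a silent drop.

## Limitations

* The cascade ranks and filters; it does not model expression, effect
  sizes, or any notion of statistical significance for hub status.
* Literal string matching is a feature for reproducing printed tables
  and a caveat for real analyses: upstream identifier mapping is the
  user's responsibility.
* MCODE's published description leaves micro-decisions open; ours are
  fixed and documented above, but other implementations may differ on
  ties and on post-processing order.
* The synthetic generator supports the recovery claims only for the
  structure it plants; real interactome releases will behave
  differently in the tails.
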