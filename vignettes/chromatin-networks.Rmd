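---
title: "Methods: chromatin interaction networks, target discovery and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin interaction networks, target discovery and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chianet)
```

This vignette is the package's account of its methods: the network model,
the conventions every computation relies on, the statistical nulls, and the
design choices made where more than one reasonable convention exists. Nothing
here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The network model

Paired-anchor interaction data (ChIA-PET-style) give, per interaction, two
genomic anchor intervals and a PET count — the number of paired-end tags
supporting the contact. `chianet` models these data as an undirected simple
graph:

* **Nodes** are genomic intervals. Under *approach 1* they are the result of
  merging overlapping anchors: the minimal set of maximal intervals such that
  every anchor is contained in exactly one node. Under *approach 2* they are
  (merged) open-chromatin peaks — DNase-seq or ATAC-seq calls — that overlap
  at least one anchor. Approach 2 doubles as a filter: an interaction with an
  anchor in no peak is treated as a likely false positive and dropped from
  the edge set (but counted).
* **Edges** connect the nodes the two anchors of an interaction fall in.
  Per node pair we accumulate `interaction_count` (+1 per supporting
  interaction) and `pet_count` (+PET). An interaction whose anchors land in
  the same node is a self-loop: it is counted in the build statistics but not
  stored, because shortest-path and centrality analyses presuppose a simple
  graph.
* **Components** are labelled `0..C-1` in ascending order of each
  component's smallest node id, which makes labels — and everything
  downstream of them — deterministic.

The build statistics satisfy an exact conservation law,
`input = used + pet_filtered + self_loop + unmapped`, enforced by tests on
every constructed network.

### Coordinate and overlap conventions

All coordinates are 0-based half-open (`[start, end)`, BED-native), at every
reader and in every in-memory table; this single convention is what makes
off-by-one errors testable. *Overlap* always means at least one shared base:
bookended intervals such as `[100,200)` and `[200,300)` do **not** overlap
and are never merged (internally, interval merging runs with a zero gap
width so adjacency alone never joins intervals). A variant is the 1-bp
interval `[pos, pos+1)`, so a variant sitting exactly on a node's `end`
coordinate does not hit it. Chromosome names are compared as exact strings;
`normalize_chroms()` converts between the `chr1` and `1` styles explicitly
rather than coercing silently.

Two conventions were genuinely open and are resolved as follows, both
configurable at the call site rather than hard-coded assumptions:

* **Anchors spanning several peaks** (approach 2) fan out: the interaction
  contributes an edge for every pair of distinct nodes its two anchors
  overlap. This is the permissive reading of "anchors overlap node
  boundaries"; restricting to a best-overlap assignment would silently drop
  contacts.
* **A missing PET column** defaults to 1 with a warning, since BEDPE
  emitters differ on whether column 7 is present.

## Centralities

All four measures treat the graph as unweighted: PET counts are evidence for
an edge's existence, not a distance, and the direct/indirect target notion
is defined in hops. Per node:

* **degree** — incident edge count;
* **betweenness** — unnormalized, each unordered pair counted once, tied
  shortest paths sharing credit fractionally (Brandes' convention). Raw
  counts are reported by default because they match the verbal definition
  "number of times a node lies on shortest paths"; a `normalize_betweenness`
  flag divides by `(k-1)(k-2)/2` within components.
* **closeness** — component-scoped, `(k-1) / Σ d(v,u)` over the node's
  component of size `k`; isolated nodes get 0. Scoping to the component is
  the only way the quantity is finite on the heavily disconnected graphs
  chromatin data produce.
* **harmonic** — network-scoped, `Σ 1/d(v,u) / (N-1)` with `1/∞ = 0`; this
  is the standard motivation for harmonic centrality on disconnected graphs
  and complements component-scoped closeness.

These are computed via igraph, whose conventions were verified against this
package's definitions; the test suite additionally checks all three
path-based measures against an exhaustive all-pairs shortest-path
enumeration oracle on random graphs (20 graphs, n ≤ 12), where enumeration
is still feasible.

## Target discovery

Sources are the nodes carrying one annotation (typically non-coding
variants); targets are the nodes carrying another (typically promoters,
TSS ± `flank_bp`). `shortest_paths_between()` returns, for every
source–target pair within `max_dist` hops, the distance and *all* tied
shortest paths (capped per pair with a warning; the cap affects exported
path lists only, never distances or classifications).

A gene is classified by the **minimum** hop distance over all its
promoter-bearing nodes and all sources: `<= 1` ⇒ *direct* (the distance-0
case is a promoter in the same node as the variant), within `[2, 4]` ⇒
*indirect*, beyond ⇒ excluded. The bounds are parameters
(`direct_max`, `indirect_range`) because the indirect horizon is a
sensitivity choice, not a law; 2–4 hops is the default. Minimum-distance-per-
gene (rather than counting a gene once per node or per path) was chosen so
that classification is a function of the gene, unaffected by how many
transcript copies or promoter-bearing nodes it has; the alternative would
double-count genes with several promoters.

### Promoter window

The promoter is `[TSS - flank, TSS + flank + 1)`, clamped at 0, with
`flank = 2000` by default — "2 kb up/downstream of the TSS". The `+1` keeps
the TSS base itself inside the window on both strands (on the minus strand
the TSS is `txEnd - 1`). The window is therefore `2·flank + 1` bp wide, a
documented constant verified by test.

`nearest_tss()` implements the baseline used when no interaction data are
available: each variant maps to the gene(s) minimizing `|pos - TSS|` on its
chromosome, ties reported in full, variants on gene-free chromosomes counted
separately.

## Enrichment between annotation classes

The question: among the network's edges, are contacts between an A-node and
a B-node over-represented?

* **Observed count**: edges with one endpoint in A and one in B, each edge
  once; for A = B, edges internal to A.
* **Theoretical null**: each edge is an independent uniform draw of an
  unordered node pair. The per-edge probability of an A–B pair is the number
  of qualifying pairs over `choose(N, 2)`; with `k` doubly-labelled nodes
  the qualifying count is `n_a·n_b − k − choose(k, 2)`, which reduces to
  `choose(n_a, 2)` for A = B. The p-value is the exact binomial upper tail
  `P(X ≥ observed)`. This is deliberately the simplest null consistent with
  a "theoretical expected frequency"; it ignores the degree sequence, so
  annotations that preferentially sit on hubs will look enriched under it —
  that is a property of the null, stated here, not a bug. Degree-preserving
  nulls are out of scope.
* **Permutation null**: relabel the nodes by a uniform random permutation
  and map both annotation sets through it jointly — preserving `|A|`, `|B|`
  and `|A∩B|` — then recount. The network is never rewired, because the
  hypothesis under test concerns the placement of annotations on a fixed
  topology. The p-value uses the add-one estimator
  `(1 + #{null ≥ obs}) / (n_perms + 1)`, which can never be zero and is
  mildly conservative; with `n_perms` permutations the smallest attainable
  p is `1/(n_perms + 1)`.

The calibration test draws annotations uniformly at random on
Erdős–Rényi graphs (n = 100, edge probability 0.10, two independent 55-node
annotation sets, 500 replicates × 200 permutations) and checks the
permutation p-value distribution against uniformity by a Kolmogorov–Smirnov
test at α = 0.01. The annotation sets are deliberately large: the null count
distribution then spreads over many values, keeping the discreteness of the
estimator (ties between permuted and observed counts, plus the add-one
offset) well below what the KS test can detect. With small annotation sets
the same estimator is visibly conservative — a known property of
permutation p-values on discrete statistics, not an error.

**Gene-list enrichment** of discovered targets is Fisher's exact test,
one-tailed (greater), on the 2×2 table over a gene universe. The universe
default in pipelines is all genes annotated onto the network, and it is
always explicit, because the background choice dominates any enrichment
claim. The test suite checks the p-value against direct hypergeometric
summation over *all* 2×2 tables with margins ≤ 12.

Multiple annotation pairs tested together (`enrich_annotation_pairs()`)
gain Benjamini–Hochberg adjusted columns; this is an extension beyond the
single-pair tests.

## The synthetic fixture generator

`fixture_spec()` / `generate_fixture()` emit every file format the package
reads, at toy scale, with planted ground truth:

* random background components (default 3 components of 4–8 nodes, spanning
  tree plus extra edges at density 0.3) with anchors exactly on node
  intervals and PET counts `1 + Geometric(0.5)` — a heavy-tailed support
  distribution resembling real PET counts, where single-tag contacts
  dominate;
* **planted paths**: each requested hop distance becomes its own chain
  component with a variant in the first node and a gene TSS in the node
  exactly `hop` edges away. Realizing plants as separate chains guarantees
  the planted distance cannot be short-circuited by background edges, so
  recovery tests are exact, not probabilistic. Background variants and genes
  are placed only on background components for the same reason;
* peaks equal to the node intervals plus decoy peaks in the gaps (decoys
  must not become nodes under approach 2), which also makes approach 1 and
  approach 2 provably equivalent on fixtures — a construction identity the
  tests exploit;
* nodes are spaced with gaps exceeding twice the promoter flank, so a
  promoter can never straddle two nodes by accident.

A fixed seed makes the emitted files byte-identical across runs. What the
generator does **not** emulate: genomic sequence context, realistic
chromosome lengths, anchor-calling noise (anchors sit exactly on nodes),
overlapping gene models, trans-chromosomal contacts, and degree-dependent
annotation placement. Passing tests therefore demonstrate algorithmic
correctness on known topologies and calibrated nulls — not biological
validity on any particular cell line's data.

## Problem sizes and determinism

The oracle comparisons run at sizes where naive enumeration is exact and
fast: 500 anchors for union-find merging, 100 random graphs (n ≤ 50) for
components, 20 graphs (n ≤ 12) for path-enumeration centralities, 200×200
intervals for the quadratic overlap scan, all 2×2 tables with margins ≤ 12
for Fisher, and the 500-replicate calibration above. The acceptance script
scales the pipeline to a ~30-component study (roughly 550 interactions,
240 nodes) with six planted paths at hops 0–5, where everything reruns in
seconds. All randomness — generator, permutations, per-pair seeds — threads
from explicit seed arguments; nothing depends on hidden global state.

## Known limitations

* Interaction *calling* (deciding which raw contacts are significant) is
  upstream and out of scope; the package consumes called interactions.
* The theoretical enrichment null is degree-blind, as discussed above.
* Hi-C matrices are not binned or normalized here; Hi-C data enter only as
  already-called pairwise interactions.
* GML export serializes annotation membership per node, not the full
  feature-to-node records; reloading a network from GML restores node sets
  but uses node labels as stand-in feature ids.
* Betweenness credit for tied shortest paths is fractional; tools that count
  each tied path fully will report systematically larger hub scores.
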