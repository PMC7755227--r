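---
title: "Multi-resolution community navigation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution community navigation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commview)
```

## The model

`commview` operates on a weighted undirected protein network
$G = (V, E)$ with a symmetric weight matrix $W$, $W_{ij} \in (0, 1]$ for
edges and $W_{ij} = 0$ exactly when $(v_i, v_j) \notin E$. Self-loops are
excluded, and isolated proteins are allowed (the tuple file format cannot
express them, so they are declared through an optional node-list file).

### The divisive hierarchy

Partition quality is the weighted Newman–Girvan modularity
$$
Q = \frac{1}{2m}\sum_{ij}\Big[W_{ij} - \frac{k_i k_j}{2m}\Big]
    \delta(c_i, c_j),
$$
with $m$ the total edge weight and $k_i$ the weighted degree. Two
properties anchor the design: $Q$ of the single-community partition is
*identically zero*, and $Q \in [-1/2, 1]$. Global maximization is NP-hard,
so the Louvain heuristic is used; of its multi-level output we keep **only
the final, highest-modularity partition** per invocation. The full Louvain
dendrogram is deliberately not used: its first (vertex-moving) level tends
to produce a flood of near-singleton communities, and its aggregated
levels can leave communities of thousands of nodes — neither is a usable
resolution step for navigation.

The hierarchy is built top-down. Level 1 is the Louvain partition of the
whole network. Each community $c$ is then split further exactly when

1. $|c| \ge$ `minsplit`, and
2. the Louvain partition of the induced subgraph $G_c$ is non-trivial
   (at least two parts) and has $Q > 0$ *on $G_c$*.

Condition 2 is our reading of the requirement that "the local modularity
increases with the split": since the trivial partition scores exactly 0 on
any graph, a proposed split improves on not splitting iff its local $Q$ is
positive. $G_c$ contains only edges internal to $c$; edges leaving $c$
neither help nor hinder the decision. A disconnected $G_c$ whose Louvain
partition is its components (with $Q > 0$) splits normally — no special
case.

Isolated nodes cannot be attached by modularity (they contribute no edge
weight); the Louvain backend places each in its own community, so they
surface as singleton level-1 leaves. Entirely edgeless networks are
rejected: modularity, and hence the whole division criterion, is undefined
at $m = 0$.

### Parameters

| parameter  | default | meaning |
|------------|---------|---------|
| `minsplit` | 50      | minimum community size (nodes) eligible for further splitting; 50 suits networks of a few hundred nodes, while networks beyond $10^4$ nodes warrant values of a few hundred so leaves stay readable |
| `seed`     | 1       | drives the Louvain node-visit order; fixing it makes the entire tree, and every artifact downstream of it, bit-reproducible |

`build_hierarchy()` seeds R's RNG once and lets the sequential Louvain
calls consume the stream; the worklist is a FIFO queue and children are
ordered by smallest member id, so identical inputs give identical trees —
a hard requirement for the view layer, whose serialized outputs are
compared byte-for-byte in the test suite.

Community ids are assigned breadth-first (`C0` the root, `C1`, `C2`, …),
with `display_label()` providing the `C4-L1` form that labels each
community with its level.

## Index structures

A depth-first traversal assigns each community a `(pre, post, level)`
triple; `pre` and `post` use separate counters, each a bijection onto
$1..|V_C|$. Descent is the interval test
$\mathrm{pre}(c_2) \le \mathrm{pre}(c_1) \wedge \mathrm{post}(c_1) \le
\mathrm{post}(c_2)$; disjointness is mutual non-descent (equivalent, on a
tree, to member-set disjointness); each protein stores the labels of its
leaf community, making membership a single interval test. We define
descent **reflexively** ($c \in desc(c)$): the relation-index construction
must let a leaf community witness itself when paired with a disjoint
internal community, and strict descent would make those pairs unreachable.

The community-relation index records which disjoint community pairs are
connected by at least one network edge. Phase 1 scans $E$ once and
collects the leaf pairs joined by cross-edges. Phase 2 enumerates ordered
disjoint pairs (smaller `pre` first, skipping pairs where both are
leaves) and keeps a pair when some phase-1 leaf pair descends from it. Two
facts make phase 2 cheap: leaves below a community are contiguous in
pre-order, so each community maps to a leaf-rank interval; and a 2-D
prefix-sum table over the leaf-adjacency matrix answers "any adjacent leaf
pair inside this rank rectangle?" in O(1). The construction therefore
touches each edge once and otherwise only community pairs,
$O(|E| + |V_C|^2)$, which the tests assert through inspection counters.

## The view algebra

A view is a frontier — meta-nodes (pairwise disjoint communities) plus
atomic proteins whose member sets partition $V$ — with three edge
families: `pp` (a network edge), `cc` (some edge joins the two member
sets), `pc` (some edge joins the protein to a member). The initial view is
the root alone with no edges; `level1_view()` is the convenience that
expands it once, because an interactive first screen usually starts at the
level-1 communities while the formal starting point is the root. Both are
exposed; neither is privileged.

`zoom_in()` on a leaf substitutes its proteins and derives their edges
from the network in a single pass over the incident edges; on an internal
community it substitutes the children, reading child–child and
child–meta-node edges from the relation index (the index is authoritative
here; a brute-force reconstruction from the raw network is run against it
in the tests as a safety net) and child–protein edges from the network.
Views are immutable; each operation returns a new value, which is what
makes the inversion law `zoom_out(zoom_in(v, c), piece) == v` testable.

`zoom_out()` on a protein collapses *all* proteins of its leaf community
(leaves are atomic units — a leaf's proteins are expanded and collapsed
together, so partial expansion of a leaf cannot arise); on a meta-node it
collapses all children of the parent. If a sibling of the collapse target
is itself currently expanded, a literal collapse would leave the parent
meta-node overlapping the sibling's still-visible contents and break the
frontier partition; `zoom_out()` refuses with an instruction to collapse
the expanded sibling first. This is the one place we restrict the
operation beyond its pseudocode reading, and it is what keeps the frontier
invariant unconditional.

Edge identity is (unordered endpoints, family); `cc` edges are oriented by
pre-order label, `pp` lexicographically, `pc` protein-first, and edge rows
are sorted — so equal views are `identical()` and serialized views are
byte-stable.

## Synthetic benchmarks

`generate_hierarchical_planted_graph()` draws a balanced nested
stochastic block model: node pairs connect independently with the
probability attached to their lowest common ancestor block. The default
study conditions used throughout the tests and the acceptance script are
2 × 2 blocks of 30 nodes with $p_{leaf} = 0.5$, $p_{super} = 0.05$,
$p_{root} = 0.005$ — strong assortative separation (expected within-leaf
degree ≈ 14.5 against ≈ 1.5 to the sibling block), chosen so that recovery
failures indicate algorithmic defects rather than statistical noise.
Weights are drawn uniformly on (0, 1) independent of block structure
(structure is carried by topology; a `"unit"` option reproduces the
unweighted convention of curated interaction lists). Balanced trees only:
ground truth stays unambiguous, which is what an oracle needs.

What these fixtures do **not** emulate: degree heterogeneity (hubs),
overlapping or nested-but-unbalanced communities, and the weight–topology
correlation of real consensus networks. Passing the planted-recovery tests
therefore shows the divisive machinery is correct and well-seeded, not
that Louvain will resolve any particular real PPI network's structure —
on real data the practical depth we expect is small (below 10), and the
scale test asserts exactly that on a 10⁴-node random graph.

The Erdős–Rényi generator samples the edge count from the binomial and
decodes sampled linear pair indices, so cost is O(edges), letting tests
build a 10,000-node / 100,000-edge instance in seconds.

## Numerical and degenerate-input choices

- The split test uses $Q > 10^{-12}$ rather than $Q > 0$ to absorb
  floating-point noise in sums that are exactly zero analytically.
- Zero weights are rejected at parse time rather than dropped: $W_{ij} = 0$
  means "no edge", so an explicit 0 line is contradictory input.
- Duplicate edge records — including `(a,b)` vs `(b,a)` — are errors, not
  merges; silent de-duplication hides upstream data faults.
- Node ids are opaque case-sensitive strings; no identifier-scheme
  inference. Translation (`translate_ids()`) passes unmapped ids through
  unchanged, mirroring the convention of keeping the primary identifier
  when no cross-scheme correspondence exists.
- Ties in canonical edge orientation (both endpoints in one leaf, hence
  equal leaf `pre`) break lexicographically by node id.
- Newick labels are sanitized (structural characters replaced by `_`)
  because the format reserves them.

## Problem sizes in the shipped tests

The suite runs the exhaustive interval-label comparison on random trees of
up to ~450 communities, the relation-index and view-edge brute-force
oracles on 100+ random instances of ≤ 30 nodes, planted recovery over 10
seeds at the study conditions above, and one 10,000-node scale run. These
sizes were chosen to keep the complete suite comfortably within a few
minutes while leaving every oracle exact (enumeration, not sampling, where
the claim is exactness).

## Known limitations

- Louvain is a heuristic: the level-1 partition is a local optimum, and a
  different seed can yield a different (occasionally better) tree. The
  package guarantees reproducibility for a fixed seed, not optimality.
- Determinism is also tied to the installed igraph's Louvain
  implementation; trees built under different igraph versions may differ.
- The relation index is rebuilt, not incrementally updated; for pipelines
  that mutate networks, rebuild after each change.
- `zoom_out()` on a node whose sibling subtree is expanded requires
  collapsing that subtree first (see above) — a deliberate restriction, not
  an oversight.
- No overlapping communities, no multi-layer variants, and no use of
  intermediate Louvain dendrogram levels: one partition per split, by
  design.
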