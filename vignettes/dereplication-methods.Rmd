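---
title: "De-replicating redundant enrichment categories: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-replicating redundant enrichment categories: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gosieve)
```

## The problem

Ontological analysis of an "interesting" gene list returns the GO categories in which the list is
significantly enriched. Because genes annotated to a child category are also
counted for its ancestors, and because many sibling categories share
annotations, the significant list typically contains clusters of categories
carrying (nearly) the same genes. `gosieve` treats this as a *post-processing*
problem: given the binary category-by-gene membership matrix of the
significant categories (and optionally their per-experiment FDRs), merge the
redundant ones into groups, report one row per group, and keep the grouping
pattern visible in a separate binary matrix (the META CIM) rather than
discarding it. Upstream enrichment testing is out of scope: categories and
FDRs are consumed as input, never recomputed.

## Similarity model

For categories with gene sets $A$ and $B$ in a universe of $N$ genes, the
similarity score is the one-tail Fisher's exact p-value of the 2×2 table
partitioning the universe into $A\cap B$, $A\cap B'$, $A'\cap B$,
$A'\cap B'$. Writing $X$ for the overlap of two random sets of the observed
sizes, $p = P(X \ge |A\cap B|)$ under the hypergeometric distribution with
fixed margins.

Two modelling points deserve emphasis:

* **Tail direction.** Only the over-representation tail makes "similar"
  mean "sharing more genes than chance": with margins fixed, $p$ is
  non-increasing in the overlap, so near-duplicate categories score near 0
  and disjoint ones score exactly 1 (tested as an invariant).
* **Margin insensitivity.** Because the test conditions on the set sizes,
  two large dense categories whose overlap equals its chance expectation get
  $p \approx 0.5$, not a spuriously small value; absolute overlap size alone
  never creates similarity. A unit test pins this with two 500-gene sets
  overlapping by exactly 250 in a 1000-gene universe.

The p-value is computed by accumulating log-binomial coefficients
(`lchoose`) and summing the tail after factoring out the largest term, so it
is exact to near machine precision for any table size; the test suite
compares every margin with $N \le 60$ against direct enumeration with plain
binomial coefficients (agreement is required to a relative error of
$10^{-10}$; observed error is ~$10^{-14}$) and cross-checks random tables
against `stats::phyper` and `stats::fisher.test`. $P(X \ge 0)$ is returned
as exactly 1. No multiple-testing correction is applied to the pairwise
p-values: stringency is user-steered through the merged-pairs count below.

**Universe.** `"changed"` mode (the default) uses exactly the genes of the
membership matrix — the only self-contained choice, and the one that makes
the redundancy pattern specific to the experiment at hand. `"all"` mode
takes a total-genes list (e.g. the whole array) and widens $N$, which makes
every overlap look more surprising; it reflects static annotation overlap
instead. When one run involves several experiments, a single pooled
universe is used throughout, so that one clustering pattern is well defined
across the whole run.

## Threshold selection

The user asks for a *nominal number of merged pairs* $t$; the cutoff is the
$t$-th smallest off-diagonal p-value, and all pairs with $p \le$ cutoff
become edges. Ties at the cutoff are all admitted — the achieved count may
exceed $t$ (hence "nominal") and is reported in the fit and the manifest.
$t = 0$ produces a cutoff below the smallest p-value, hence no edges and an
identity reduction. Diagonal entries are never computed and never counted.

## The clustering step

Vertices are categories, edges the pairs at or below the cutoff. The
decomposition grows clusters to a fixed point:

* initialise one singleton cluster per category;
* repeatedly, for each cluster and each category outside it, add the
  category if it is adjacent to **every** current member (complete
  linkage); iterate until a full pass changes nothing;
* deduplicate identical clusters and drop strict subsets.

At the fixed point no cluster can absorb another vertex, which is exactly
maximality of a clique, and every vertex seeded its own cluster, so the
groups cover all categories. A category adjacent to two groups that are not
mutually adjacent remains in both — multi-membership is the informative
case, surfaced by the META CIM.

Three details are underdetermined by the complete-linkage rule itself and
were fixed as package design choices:

* **Initialisation** is one singleton per vertex: it guarantees coverage
  and lets every vertex seed its own clique.
* **Visit order** is always lexicographic in category names, for both
  clusters and candidate vertices. Within one cluster the growth result is
  order-independent (complete linkage), but the *set* of cliques discovered
  by any greedy scheme is not; pinning the order makes output bit-exactly
  reproducible and invariant under permutation of the input rows (a tested
  invariant). Other implementations of the same scheme may discover a
  different — equally valid — maximal-clique cover on graphs where several
  covers exist, so exact group counts are comparable only within one
  implementation.
* **Subset pruning** after deduplication: a strict-subset cluster is an
  artifact of the growth schedule, not a maximal clique (vacuous at the
  fixed point, kept as a hard guarantee).

Correctness is checked two ways: `verify_decomposition()` asserts
clique-ness, maximality, coverage and subset-freeness from first
principles, and the test suite requires every cluster to appear in an
independent Bron–Kerbosch enumeration (`igraph::max_cliques`) on 200 random
graphs with up to 12 vertices across edge densities 0.1–0.85. Exhaustive
enumeration of *all* maximal cliques is deliberately not the production
path — it serves only as the oracle.

## Collapse rules and naming

Membership matrices collapse by the cell-wise **mean** of member rows (a
cell becomes the fraction of group members containing the gene); FDR
matrices collapse by the cell-wise **minimum** (a group is as significant
as its best member, per experiment). Both rules are idempotent on identical
rows and bounded by the member rows cell-wise (tested invariants). The FDR
matrix is collapsed over categories per experiment — the only reading
consistent with an experiments-by-category FDR input.

Groups are numbered 1..K with merged (multi-member) groups first, in
canonical lexicographic member order, singletons after. This keeps the
META CIM columns contiguous (`group_1..group_K`) and identical to the
numbers in the `":N"` row labels. A merged group is displayed as
`representative:N`; the representative is the member with the smallest
minimum FDR across experiments when an FDR matrix is available (the most
significant member is the most informative label), otherwise the
lexicographically first member, ties lexicographic. Concatenating all
member names, while faithful, is unreadable as a heatmap label for 5+
categories, so the full membership lives in the `groups.tsv` sidecar and in
the META CIM instead. The META CIM contains only merged groups — singletons
carry no grouping information — and a run with no merged groups produces an
empty META CIM and no file.

When one grouping pattern is applied to a *different* matrix (default mode:
the pattern derived from the integrative matrix collapses each individual
matrix), members absent from that matrix are dropped from their group for
that matrix only, groups emptied thereby are omitted, and the original
group numbers and labels are retained so rows remain comparable across the
whole output set. Applying a pattern to the matrix it came from equals the
direct collapse (tested). Similarity in default mode is always computed
from the membership matrix (gene overlap), never from FDR values — the
metric is defined on gene sets.

## Display

Rows and columns are ordered by average-linkage (UPGMA) hierarchical
clustering of Euclidean distances, via `stats::hclust`; linkage heights are
checked against a brute-force UPGMA recomputation for up to 8 leaves. Leaf
order within a dendrogram is underdetermined, so the canonical
smaller-index-subtree-first layout is applied, making images byte-stable
across runs. Membership-type matrices use the yellow (0, absent) → red
(1, present) convention; FDR matrices a red (significant) → pale scale.
Very large generic categories (e.g. top-level processes) can optionally be
removed before analysis with `filter_large_categories()`; the filter is off
by default and refuses to empty the matrix.

## Synthetic data and what the tests do (and do not) show

`generate_planted()` emulates the redundancy structure of a real
significant-category list: planted groups of near-identical categories
share a core gene set, with cores pairwise disjoint across groups so the
ground truth is unambiguous; per-category jitter switches non-core genes on
with a given probability; independent background categories emulate the
non-redundant remainder. Defaults (150 genes, 4 groups × 3 categories,
8-gene cores, jitter 0.02, 6 background categories at density 0.05, FDRs
uniform on [0, 0.1]) match the scale of a typical post-enrichment CIM —
tens of categories over a hundred-odd changed genes. FDR values are
decorative by design: the pipeline only min-pools them.

With zero jitter, no background and the threshold set to the number of
within-group pairs, the pipeline must recover every planted group exactly;
the suite requires 100% recovery over 50 seeds, and mean recovery over a
jitter grid (0, 0.02, 0.05, 0.1; 25 seeds each) must be non-increasing
within one seed's worth of sampling noise. These tests validate the
machinery, not the biology: real GO categories overlap *between* "groups",
are nested by the ontology, and have heavy-tailed sizes, none of which the
generator reproduces (cross-group overlap is exercised separately through
hand-built graphs). Passing therefore shows the algorithm does what it
claims on data with known truth — not that any particular threshold is
right for a given real dataset, which remains the user's scientific choice,
typically made by inspecting META CIMs at a few stringency levels.

Problem sizes used throughout the suite — universes to 60 for the
exhaustive Fisher comparison, 200 random 12-vertex graphs, 8-leaf UPGMA
oracles, 13–18-category pipeline runs — were chosen so each check exercises
the full code path while the complete suite stays fast enough to run on
every change.

## Numerical and degenerate-input choices

* Matrix files are tab-separated with a `category` label column; binary
  matrices round-trip bit-exactly, real-valued ones are written with six
  decimals. Tabs and decimal points only — no locale handling.
* Empty categories (no genes) are rejected at load; duplicate labels and
  out-of-range cells are errors naming the offending coordinate; duplicate
  gene-list entries are dropped with a warning each.
* A single-row or single-column matrix gets the identity ordering; a
  similarity computation needs at least two categories.
* `p_threshold = 1` merges everything into one group; `merged_pairs = 0`
  reduces nothing.
* Manifests record every parameter of a run; `rerun_from_manifest()`
  reproduces the TSV outputs exactly.

## Known limitations

* The discovered clique cover, while always valid and deterministic here,
  is one of possibly several; group counts from other implementations of
  the same scheme need not match exactly (see the visit-order note above).
* The clustering fixed-point loop is quadratic-ish in category count per
  pass; it is intended for the tens-to-hundreds of categories a significant
  list contains, not for thousands.
* Input dialects of specific upstream tools are not parsed; the canonical
  TSV layouts documented here are the interface.
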