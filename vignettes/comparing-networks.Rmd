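---
title: "Methods: comparing multiple biological association networks"
author: "NetCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing multiple biological association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetCompare)
```

## Scope and data model

NetCompare compares 2–8 undirected networks drawn from one shared node
namespace — gene, protein or taxon identifiers compared as exact,
case-sensitive strings. The cap of eight simultaneous networks is a design
constraint of the comparison semantics (exclusive-region analysis over
`2^k − 1` subsets, pairwise transition scoring), not an implementation
limit.

All networks are treated as **undirected**. The backend algorithms —
greedy modularity maximisation, maximal-clique enumeration, Jaccard
similarity over edge sets — are defined on undirected graphs, so the
source/target columns of an input edge list are purely a parsing
convention. Every edge is stored canonically with endpoints in C-locale
lexicographic order; two networks with equal node and edge sets are
therefore slot-identical regardless of input file ordering, which is what
makes the set algebra exact and reproducible across platforms and locales.

Parsing decisions where edge-list dialects differ:

* duplicate edges collapse to one; if their weights conflict, the **last
  occurrence wins** and a warning is raised;
* self-loops are dropped with a warning by default (they have no coherent
  meaning for cliques or modularity), retained behind
  `allowSelfLoops = TRUE`;
* blank lines and `#`-prefixed lines are skipped; surrounding whitespace is
  trimmed from identifiers;
* edge identity in **all set operations ignores weights** — intersection,
  exclusivity and Jaccard similarity are presence/absence statements.

## Set comparison (Venn/UpSet regions)

`computeRegions()` assigns every element of the union to the unique subset
of networks containing it. These are **exclusive** regions — the standard
UpSet semantics, where region counts are pairwise disjoint and sum to the
union size. The alternative "shared by at least these networks" reading is
a derived quantity exposed as `inclusiveCounts()`; we kept the exclusive
convention primary because it is the only one in which the displayed
numbers partition the union and can be summed meaningfully. Row orderings
(`upsetRows()`) are deterministic: descending count or subset size, ties
broken lexicographically by the label subset.

## Network similarity and the selection dendrogram

Pairwise similarity is the edge Jaccard index
`s = |E_i ∩ E_j| / |E_i ∪ E_j|`. Degenerate cases are defined, not
errored: two empty edge sets are identical (`s = 1`), one empty set
against a non-empty one is fully dissimilar (`s = 0`).

Networks are clustered on the distance `d = 1 − s` by agglomerative
hierarchical clustering with **average linkage (UPGMA)**, the common
default for similarity dendrograms; the linkage is a `method` argument for
users who prefer complete or single linkage. Labels are sorted
lexicographically before clustering so that equal-distance merges resolve
identically regardless of input order. The newick export rescales the
tree so leaf-to-root depths equal the merge heights (the underlying
`hclust`-to-`phylo` conversion halves them).

The radar view reports the **distance** of each network from the global
union, `1 − |S_k|/|S_union|` for node and edge sets. Index and distance
are easily conflated here; we report distance so that a network equal to
the union sits at 0, which matches the intuition "further from the centre
= more divergent".

## Graph properties

The preview statistic called *cluster coefficient* is the **average local
clustering coefficient** with nodes of degree < 2 contributing zero — the
common global preview statistic. The triangle-ratio alternative
(transitivity) is a genuinely different quantity and is exposed separately
as `globalTransitivity()` rather than silently substituted.

Centrality conventions:

* **betweenness** uses raw unordered-pair counts (each source–target pair
  contributes its fractional path counts once); the normalized variant is
  behind a flag, since cross-network comparisons are relative;
* **eccentricity** and **closeness** are computed within each node's
  connected component instead of erroring or returning infinity on
  disconnected inputs — every node gets a value;
* **eigenvector / HITS**: on an undirected graph the hub and authority
  vectors coincide with the principal adjacency eigenvector, so all three
  are computed by one deterministic power iteration. The iteration runs on
  `A + I` rather than `A`: the shift preserves the principal eigenvector
  while guaranteeing convergence on bipartite graphs, where iteration on
  `A` alone oscillates between the two sides. Parameters: uniform start
  vector, sup-norm tolerance `1e-8`, at most 1000 iterations (exceeding
  them is an error naming the tolerance), result scaled to unit maximum.
  No randomness is involved anywhere in the package's centralities.

Cross-network tables (`deltaCentrality()`) record a node missing from a
network as `NA` — an explicit ABSENT marker, written as the string
`ABSENT` in TSV export — never as 0, which would be a legitimate value.

## Shortest paths

The unit of analysis is the set of **all co-optimal shortest paths**
between one source/target pair, per network. Single-path Dijkstra cannot
produce this set; enumeration works from the shortest-path predecessor
structure (igraph's all-shortest-paths), which is equivalent for unit
weights and for positive weighted costs. Defaults are unweighted hop
counts — path-length reasoning in comparative analyses is typically in
hops — with weighted mode behind a flag that requires strictly positive
weights.

Order numbers start at 0 on the source, so in hop mode the target's number
equals the path length. The preferred-intermediate tally counts a node
**once per network** (not once per co-optimal path) and excludes source
and target, which trivially appear in every path. A disconnected pair is a
result (empty path set, with a notice), not an error; a pair co-occurring
in no selected network is an error.

## Communities and transitions

Community detection is Clauset–Newman–Moore greedy modularity
maximisation: agglomerate from singletons by the best modularity gain and
cut the merge dendrogram at maximum modularity. One numerical subtlety is
handled explicitly: the cut maximises the modularity trace after rounding
to 12 decimals, because float noise in the trace can otherwise park the
cut one merge early on graphs whose true optimum is a tie (e.g. a single
clique, where the correct answer is one community at `Q = 0`). Isolated
nodes become singleton communities; an edgeless network yields all
singletons with `Q = 0` and a warning. Reported modularity is always the
direct Newman–Girvan `Q` of the returned partition.

Transition scoring between partitions A and B computes intersection count
and Jaccard for **all |A| × |B| community pairs**; `sumJaccard` is their
cumulative sum and `weightedSumJaccard = sumJaccard / comparisons × 100`.
The denominator "comparisons made" is genuinely open — counting all cross
pairs is the literal reading and keeps the weighted score small for
many-community partitions; the variant that divides by only the pairs with
non-zero overlap is computed alongside
(`weightedSumJaccardNonzero`) rather than hidden. Nodes present in only
one of the two networks count against the pair unions: a departed node is
a genuine community change, not missing data.

The rank embedding pools the (network, node) observations of **both**
compared networks per measure (degree, hub, betweenness), ranks them
ascending with average ranks on ties, and divides by the pooled count.
Pooled ranking was chosen over per-network min–max scaling because it
makes the two columns of the comparison directly comparable: a value of
1.0 means the single strongest observation across the pair.

## Cliques

"Cliques of size ≥ k" means **maximal** cliques — complete subgraphs not
contained in a larger one — enumerated by Bron–Kerbosch with pivoting.
Reporting all complete subgraphs would bury every K5 under its 10
triangles. The default `k = 3` starts at triads (dyads are just edges);
`k = 2` is allowed. Output order is deterministic: descending size, then
lexicographic member lists. Tracking a clique in another network reports
present/absent members and the retained internal edge count (an intact
clique of size s retains `choose(s, 2)`).

## Synthetic study conditions

The generator produces the conditions used throughout testing and the
acceptance script:

* `generateRandom()`: **uniform G(n, m)** graphs — exact edge counts,
  matching the benchmark design of size categories with n nodes and
  2n–5n edges (500–5000 nodes, 1000–25000 edges, three replicates per
  category) rather than a binomial G(n, p) approximation;
* `generatePlantedPartition()`: stochastic block model, default two blocks
  of 20 nodes with `pIn = 0.9`, `pOut = 0.02` — well-separated structure
  whose recovery is a meaningful yes/no check;
* `generateFamily()`: a base G(n, m) network plus derivatives that keep a
  fraction `overlap` of base edges and rewire the rest into the base's
  complement — emulating condition-to-condition rewiring over a fixed
  namespace. The measured edge Jaccard against the base is a monotone
  function of `overlap` (≈ `keep/(2m − keep)` in expectation).

Node labels are `N000001…`, lexicographically ordered, so downstream
tie-breaks are reproducible. Every generator call takes one explicit seed
and restores the session RNG state afterwards.

What the synthetic conditions do **not** emulate: degree heterogeneity
(real association networks are heavy-tailed), weighted association
strengths, correlated rewiring (biological rewiring is concentrated around
affected pathways, not uniform), or namespace drift between conditions.
Passing tests on these fixtures therefore establishes algorithmic
correctness of the comparisons, not robustness of biological conclusions
drawn from inferred networks — the inference step (correlation networks,
STRING overlays) is out of scope entirely.

## Verification strategy and problem sizes

All exact claims are tested against independent brute-force oracles at
sizes where exhaustive enumeration is tractable: all-shortest-path
enumeration against depth-first search over all simple paths (200 random
graphs, ≤ 12 nodes), betweenness against fractional path counting,
maximal cliques against exhaustive clique growth (200 random graphs, ≤ 15
nodes), greedy modularity against the maximum over all set partitions
(≤ 8 nodes, Bell-number enumeration), and the transition scores against a
fully hand-enumerated two-partition example (`sumJaccard = 19/12 ≈
1.5833`, `weightedSumJaccard ≈ 39.58`). Set-algebra invariants (disjoint
cover, per-network reconstruction, subset relations) run over 100 random
collections of 3–5 networks. Planted-partition recovery is measured over
100 seeds. The full pipeline additionally runs once at the largest
benchmark size, 5000 nodes / 25000 edges.

## Known limitations

* Weighted modularity and weighted set operations are out of scope; the
  weight column only affects weighted shortest paths.
* Greedy modularity inherits the resolution limit of modularity
  maximisation and the known tendency of the fast-greedy agglomeration to
  absorb small communities; partitions on weakly structured graphs should
  be read as summaries, not ground truth.
* Edge identity strings use the separator `--`; node identifiers
  containing that substring would collide (not observed in gene/taxon/
  protein namespaces).
* Venn-style region output is exact for any k ≤ 8, but drawing more than
  5 sets as ellipses is a rendering problem this package deliberately does
  not have.
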