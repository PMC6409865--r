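---
title: "Network location of disease genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network location of disease genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netloci)
```

## The question and the model

Disease genes are hypothesized to occupy distinctive *locations* in the
interactome — the undirected graph of gene–gene functional interactions —
rather than simply having many partners. `netloci` operationalizes
location through four node-level parameters: degree, average shortest
path length (ASPL), local clustering coefficient (CC), and betweenness
centrality (BC). The package's central comparison asks, for a designated
gene set, whether each parameter's distribution differs from that of
random same-size gene sets drawn from the same network, and separately
from that of the set's own first-order neighbors.

The model of the interactome is deliberately minimal: an unweighted,
undirected simple graph over gene symbols. Symbols are case-sensitive and
taken verbatim; no identifier mapping is attempted. Edge-list columns
beyond the first two (confidence scores, interaction types) are ignored,
because all four parameters are defined on the unweighted topology.
Self-loops are dropped (with a counted warning) and duplicate or reversed
duplicate lines collapse to one edge, so every input becomes a simple
graph by construction.

## Connectivity: why the largest component

Per-gene ASPL is undefined for unreachable pairs. Real integrated
interactomes are dominated by one giant component, but small satellite
components do occur, and a published analysis rarely states how
unreachable pairs were treated. We therefore default to restricting the
whole analysis to the largest connected component (ties broken toward the
component containing the byte-wise smallest symbol, for determinism), and
expose a whole-graph mode in which unreachable pairs are simply excluded
from averages. Results in the two modes coincide exactly on connected
inputs.

`network_apl()` exposes two denominators for the network-level average:
the conventional mean over the $N(N-1)/2$ unordered distinct pairs, and a
self-inclusive variant dividing the same total by $N(N+1)/2$, i.e.
counting each node's zero-distance self-pair. Some texts print the
formula the second way; on the path graph $P_4$ the two give $5/3$ and
$1$ respectively. The conventional form is the default; per-gene values
are unaffected.

## The four parameters: conventions and edge cases

**Degree** is the adjacency-list length; no convention is needed.

**ASPL** of gene $v$ is the mean BFS distance to all other reachable
genes, with $d(v,v) = 0$ excluded from the numerator as a self-pair. Any
gene with at least one neighbor in a connected graph has ASPL $\ge 1$.

**CC** is $2n/(k(k-1))$ with $k$ the degree and $n$ the number of edges
among the neighbors; the neighbor-edge count is obtained from the
symmetric adjacency structure and halved, since each edge is seen from
both endpoints. For $k < 2$ there is no neighbor pair and we define
CC $= 0$ — the common convention, which keeps CC totally ordered across
all genes rather than leaving hubs' leaves undefined.

**BC** sums, over unordered pairs $\{i, j\}$ with $i \ne v \ne j$, the
fraction of shortest $i$–$j$ paths through $v$. We accumulate with
Brandes' single-source dependency scheme, which visits each unordered
pair from both endpoints in an undirected graph; the raw total is
therefore halved. The default output is normalized by $(N-1)(N-2)/2$,
the number of pairs eligible for a given $v$, giving values in $[0, 1]$;
a flag exposes the raw sum. Normalized reporting is the default because
per-gene betweenness values quoted for interactomes of several thousand
genes are typically of magnitude $10^{-3}$–$10^{-1}$, which is only
consistent with the normalized scale. Unreachable pairs contribute
nothing. The test suite verifies the accumulation against a brute-force
oracle that evaluates the defining sum from a Floyd–Warshall distance
matrix and explicit path counts (tolerance $10^{-9}$ on 100 seeded random
graphs with $n \le 30$), against `igraph`, and against exact pair counts
on random trees, where the unique-path structure makes the definition
enumerable.

All iteration is in byte order of the gene symbols (radix sort, so the
ordering is locale-independent), making every output byte-stable under a
fixed seed.

## Null models and testing

Random gene sets are drawn uniformly without replacement from the
analyzed component minus the disease genes (no-overlap sampling); the
replicates themselves are independent and may overlap one another.
Sampling from the same network — rather than from a genome-wide list —
keeps the metric distributions comparable; this is the one place where a
published comparison of disease genes to "randomly selected normal genes"
is ambiguous, and we chose the network-restricted pool.

Significance per parameter is a **two-sided** Mann–Whitney U test between
the disease values and the pooled null values. Two-sided is conservative
and direction is reported separately as the sign of the median
difference, so no claim rests on a directional test. Pooling the
replicates into a single null sample gives one p-value per parameter (the
quantity a comparative figure reports); per-replicate p-values are also
emitted for transparency. The U statistic and p-value come from
`stats::wilcox.test`: exact enumeration when both samples are small and
tie-free, otherwise the Gaussian approximation with tie-corrected
variance and continuity correction. Two degenerate cases are resolved by
symmetry before testing: a constant pooled sample, and identical
multisets, both return $p = 1$ exactly. The exact path is validated
against a full-enumeration oracle over all $\binom{m+n}{m}$ label
assignments (200 seeded draws, $m, n \le 8$), and exact and normal
p-values agree within 0.02 for tie-free samples of sizes 10 vs 100.

Larger gene sets are partitioned for the grouped analysis by a seeded
shuffle followed by chunking into groups whose sizes differ by at most
one — 171 genes cannot be divided into 10 truly equal groups, so
"near-equal" is the honest implementable contract.

The neighbor comparison contrasts the disease genes with the union of
their first-order neighbors, *excluding* the seed genes themselves:
including them would compare the set partly against itself. Whether the
neighbors "look like random genes" is summarized by an aggregate
affinity score (`neighbor_affinity()`): for each parameter, the absolute
difference between the neighbor median and the null (resp. disease)
median, standardized by the pooled-null standard deviation, summed over
the four parameters. The aggregate — not a per-parameter vote — is used
because direct adjacency transfers part of a bridge gene's distance
advantage to its neighbors in any strongly modular network (a neighbor of
an inter-community connector is two hops from the far community), so the
ASPL coordinate alone is genuinely intermediate while the overall profile
is null-like.

## Spearman correlations with ties

The inter-parameter correlation matrix uses Spearman's rank correlation
implemented as the Pearson correlation of tie-averaged ranks. This is the
module's central numerical decision: published metric tables are rounded
(two-decimal CC values contain many ties), and the popular tie-free
shortcut $1 - 6\sum d^2 / (n(n^2-1))$ is biased under ties. On the
packaged ten-gene reference table the tie-correct form gives
aspl~cc $= -0.994$ while the shortcut gives $-0.982$; the test suite
pins both, and checks invariance under strictly increasing transforms
and agreement with a brute-force oracle that constructs average ranks
explicitly. Correlations involving a constant parameter are undefined
and are reported as `NA` with a warning, never silently zeroed. No
p-values are attached to coefficients.

## The synthetic interactome generator

The generator provides the study conditions for every statistical claim
the package tests about itself.

`generate_scale_free()` grows a preferential-attachment graph: a seed
clique on $m$ nodes, then each new node attaches $m$ distinct edges with
probability proportional to current degree. The edge count is exactly
$\binom{m}{2} + m(n - m)$ and the degree distribution is heavy-tailed,
emulating the degree structure of real biomolecular networks (checked
coarsely against an equal-edge-count uniform random graph at
$n = 5000$).

`plant_disease_genes()` builds the full study system: `n_communities`
independent preferential-attachment communities (default 2 communities of
`n_nodes` = 200 genes, $m = 4$), plus `planted_count` = 10 connector
genes, each linked to `connector_links_per_community` = 3 uniformly
chosen **low-degree** genes in every community (the pool is the smallest
degree values present, widened only until it can supply the links).
Connectors are then the only bridges between communities, so by
construction they acquire:

- high betweenness (every inter-community shortest path crosses one),
- low ASPL (they are central to both communities),
- near-zero clustering (their neighbors live in different communities
  and are mutually unconnected),
- a fixed, deliberately unremarkable degree of
  `n_communities × connector_links_per_community` $= 6$.

The attachment parameter $m = 4$ was chosen so that this connector degree
sits at the community median: for preferential attachment the median
degree $k$ satisfies $k(k+1) \approx 2m(m+1)$, giving $k \approx 5.8$ at
$m = 4$. With that placement the planted set is *not* degree-prominent —
the dissociation between betweenness prominence and degree prominence
that motivates the whole analysis — and community clustering is lifted
far enough off zero that the null CC median is positive. Low-degree
attachment serves the same goal from the other side: linking connectors
to hubs would both inflate their neighborhood quality and shortcut
nothing.

What the generator does **not** emulate: the scale (hundreds vs thousands
of genes), edge density and multi-source heterogeneity of a real
integrated interactome; overlapping pathway communities; noisy or
false-positive edges; and any biological identity of the symbols. Passing
the planted-signature tests therefore shows that the pipeline detects the
location signature *when it is present by construction* and does not
hallucinate it under the null — not that any particular real disease list
will show it.

All randomness flows through one seeded RNG scope per call
(`with_seed`), restoring any pre-existing RNG state; no global state
leaks, and equal seeds give byte-identical results end to end.

## Problem sizes and runtime choices

The validation suite runs on sizes chosen to keep the brute-force oracles
exact and the whole suite quick: oracle equivalence on random graphs with
$n \le 30$ (where $O(n^3)$ Floyd–Warshall and explicit path enumeration
are trivial), the planted-signature study on the default 410-gene
networks across 10 seeds, the type-I calibration as 2000 simulated
null-vs-null tests on one fixed 410-gene network (rejection at
$\alpha = 0.05$ expected in $5\% \pm 2\%$ of simulations), and the
heavy-tail check at $n = 5000$. The implementation is pure R; a single
betweenness pass on a 410-gene network takes well under a second, and
nothing in the pipeline needs compiled code at these scales. For
interactomes of several thousand genes the same code applies unchanged;
betweenness is the dominant cost, at one BFS plus accumulation per node.

## Known limitations

- The null model is uniform sampling; degree-preserving
  (configuration-model) nulls are out of scope, so a gene set's parameter
  differences are statements relative to *random genes*, not relative to
  random genes of equal degree.
- No multiple-testing correction across parameters or across gene sets is
  applied; the four parameters are reported individually, and their
  mutual correlations are quantified instead.
- Weighted or directed interactions, identifier normalization, and
  approximate betweenness for very large graphs are not implemented.
- The packaged ten-gene reference table is loaded at its printed
  precision, not recomputed: the interactome it was measured on is not
  redistributable, so only desk-recomputable quantities derived from the
  table (such as its rank correlations) are asserted anywhere.
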