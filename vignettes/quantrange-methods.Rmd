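---
title: "Ranges of co-optimal transcript abundances: models and methods"
author: "quantrange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranges of co-optimal transcript abundances: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantrange)
```

## The problem

RNA-seq expression quantifiers report one abundance per transcript, but the
likelihood they maximise often has many maximisers: exons are shared between
isoforms, short fragments map ambiguously, and entire families of abundance
assignments predict exactly the same read distribution. This
*nonidentifiability* is not sampling noise — it does not shrink with
sequencing depth — and a point estimate silently hides it. quantrange makes
it visible by computing, for every transcript or splicing pattern, the closed
interval `[lo, hi]` of abundances attainable across all equally optimal
solutions. A width of zero certifies the estimate; a wide interval warns that
downstream conclusions (isoform ranking, differential expression) may rest on
an arbitrary choice among co-optimal solutions.

Three model assumptions are covered:

1. **Complete reference** — every expressed transcript is annotated.
2. **Incomplete reference** — only the splice graph is trusted; any
   source-to-sink path may be expressed.
3. **Hybrid** — a fraction $\lambda$ of expression comes from unannotated
   paths; ranges interpolate affinely between the extremes.

## Splice graphs, flows and decompositions

A gene is represented as a splice graph: a DAG with a virtual source $S$, a
virtual sink $T$, one vertex per (partial) exon and one edge per junction
(including the virtual transcript-start and -end edges). A transcript is an
$S$–$T$ path. A *flow* assigns each edge a non-negative weight, balanced at
every internal vertex; its total $U$ is the outflow of $S$. A *decomposition*
writes a flow as weighted $S$–$T$ paths whose per-edge sums reproduce the
flow; every finite flow admits one, and the decomposition is exactly as
non-unique as the quantification is nonidentifiable.

```{r}
w <- wGraphFixture()
w$graph
totalFlow(w$graph, w$flow)
```

This "W" example is the minimal interesting case: 4 units enter through A, 6
through B; after merging, 3 leave through C and 7 through D. Any split
$w \in [0, 3]$ of the A-inflow between the C- and D-exits is co-optimal.

## Complete reference: linear programming over sufficient statistics

Under the complete-reference assumption, two quantifications are
indistinguishable exactly when, for every *phasing path* (the ordered
junctions covered by one fragment class), the total abundance of transcripts
containing it in full is equal. Given an optimal solution $\{c_j\}$ from any
quantifier, the co-optimal set is therefore the polytope

$$\sum_{j:\,i \subseteq T_j} c'_j = g_i \quad \text{for every phasing path } i,
\qquad c'_j \ge 0,$$

with $g_i$ evaluated at the input optimum. `transcriptRangeLP()` minimises
and maximises one coordinate of this polytope; because the feasible set is
convex and the objective linear, every value between the extremes is attained
(`probeAbundance()` verifies this directly). By default the phasing paths are
all single junctions, i.e. all edges of each transcript's path including the
virtual start/end edges — the junction totals of the base model; longer
phasing paths can be supplied and only ever narrow ranges.

```{r}
tr <- list(TranscriptModel("T1", "g", c("SA", "AM", "MC", "CT")),
           TranscriptModel("T2", "g", c("SA", "AM", "MD", "DT")),
           TranscriptModel("T3", "g", c("SB", "BM", "MC", "CT")),
           TranscriptModel("T4", "g", c("SB", "BM", "MD", "DT")))
allRangesLP(tr, c(3, 1, 0, 6))
```

The LPs are solved by a dense two-phase primal simplex implemented in the
package (Bland's rule, equality form, non-negative variables). Gene-level
systems have tens of variables and constraints, where the full-tableau method
is simple, exact to solver tolerance ($10^{-6}$ absolute on endpoints) and
fast. Transcripts without junctions (single-exon) are not constrained by
junction evidence at all; rather than guess, they are flagged with the range
`[0, total gene abundance]`.

## Incomplete reference: OR-Quant and AND-Quant

Under graph quantification the data determine an edge flow, and each
transcript's abundance is its path weight in some decomposition. Two query
semantics cover transcripts and splicing patterns:

* **OR-Quant**: given an edge set $E'$, a path is *good* if it touches any
  edge of $E'$; asked is the range of total good flow over all
  decompositions.
* **AND-Quant**: given an ordered list of pairwise-disjoint edge sets
  $E_1 \ldots E_m$ with the *well-ordering property* (no path meets a
  later-indexed set before an earlier one), a path is good if it touches
  every set. A full transcript is the special case of singleton sets along
  its path.

OR-Quant reduces to two max-flow calls with the edge flows as capacities:
deleting $E'$ and maximising flow finds how much can avoid $E'$ entirely, so
the minimum good flow is $U - \mathrm{MaxFlow}(G^-)$; redirecting every
$E'$ edge into an auxiliary sink (`"T_prime"`, original destinations kept as
edge labels) and maximising flow finds how much can be forced through $E'$,
the maximum good flow. Max-flow itself is delegated to igraph, which handles
real-valued capacities; abundances are continuous and no integrality is
assumed anywhere.

AND-Quant complements into OR-Quant through the *block graph* $G_B$: the
filtered query edges plus all edges lying between consecutive query levels.
Good paths are exactly the $S$–$T$ paths inside $G_B$, so with
$[l, r] = \mathrm{ORQuant}(G, E \setminus G_B)$ the answer is
$[U - r,\, U - l]$. $G_B$ is built in linear time from two reachability
labels per vertex ($s(v)$: the deepest query level completed on some path
from $S$ to $v$; $t(v)$: symmetric from $v$ to $T$), computed by forward and
backward dynamic programming over the topological order after pruning
vertices that lie on no $S$–$T$ path. A query edge of $E_i$ survives
filtering iff $s(u) = i-1$ and $t(v) = i+1$; a non-query edge is a block
edge iff $s(u) + 1 = t(v)$. An emptied set proves no good path exists and
the range is `[0, 0]`.

```{r}
andQuant(w$graph, w$flow, EdgeSetQuery(list("S->A", "M->C")))
orQuant(w$graph, w$flow, c("S->A", "M->C"))
```

**Why query sets must be disjoint.** If one edge belonged to two levels,
"touches every set" and "crosses every level via an ordered chain of
distinct edges" would stop being the same predicate, and the label DP
computes only the latter. All constructions the package targets —
full-transcript singletons, junction cuts for splicing patterns — are
naturally disjoint, so `EdgeSetQuery` enforces disjointness at construction
rather than silently answering a different question.

**Witnesses.** `witnessDecomposition()` turns the endpoint values into
explicit decompositions. The minimum witness decomposes a maximum flow of
$G^-$ (all bad paths) and the residual flow (necessarily all good). The
maximum witness decomposes the auxiliary max-flow into truncated
$S$–`T_prime` paths and completes them one at a time — always the path whose
second-to-last vertex is topologically latest, ties broken by ascending path
index — routing each weight onward with a max-flow on the remaining
capacity; the final residual decomposes into bad paths. Every witness is
re-validated (edge sums reproduce the flow; good flow equals the endpoint)
and a mismatch aborts loudly, so the construction doubles as an internal
consistency check of the endpoint computation.

## Hybrid assumption and reliability audits

With $[l^0, u^0]$ the LP range and $[l^1, u^1]$ the graph range,
the hybrid range at $\lambda \in [0,1]$ is
$[\lambda l^1 + (1-\lambda) l^0,\; \lambda u^1 + (1-\lambda) u^0]$. Both
interpolation and replicate averaging are affine, so their order is
irrelevant (asserted in the tests to $10^{-12}$).

Two audits consume these ranges:

* **Sibling ranking** (`siblingRankingInconclusive()`): within a gene, a
  transcript's expression ranking against a sibling isoform is inconclusive
  when their closed ranges intersect.
* **DE reliability** (`classifyDECall()`): for a transcript already detected
  as differentially expressed by an external pipeline, the per-replicate
  hybrid ranges are averaged within each condition at every $\lambda$ on a
  grid (default $0, 0.1, \ldots, 1$); the call is *questionable* at
  $\lambda$ when the overlap fraction — intersection length over the length
  of the smaller range — strictly exceeds a threshold (default 25%).
  Reported are the per-$\lambda$ table, the smallest flagged $\lambda$, and
  the smallest $\lambda$ at which the mean ranges touch at all. An
  alternative gap rule (mean lower bound of the over-expressed group must
  exceed the other group's mean upper bound by a margin) is available; the
  margin has no canonical value and defaults to 0.

Degenerate overlaps need a convention, since the ratio is undefined when the
smaller range is a point: a point inside the other closed range counts as
full overlap, outside as none, and two points overlap iff equal. This is the
conservative choice — an identifiable transcript equal in both conditions is
flagged, not excused. Before cross-sample comparison, ranges are normalised
to a per-million scale (LP ranges by the sample's total abundance, graph
ranges by the sample's total flow), since raw abundances are not comparable
across libraries.

DE detection itself (fold changes, FDR) is deliberately out of scope: the
audit takes direction-known calls from an external pipeline and only asks
whether nonidentifiability undermines them.

## What the synthetic data emulate — and what they do not

`syntheticTranscriptome()` builds genes from the standard splicing
repertoire: one or two alternative first exons (start choice), two to four
internal cassette exons, one or two alternative last exons, with isoform
diversity dominated by end choice (half the isoforms keep the full internal
structure). This is deliberate: nonidentifiability under junction evidence
arises from end-sharing structures — two start choices and two end choices
sharing internals, as in the W example — and not from cassette chains, where
almost every isoform owns a private junction. Defaults are 10 genes and 4
isoforms per gene (around the human average); ground-truth abundances are
log-uniform over $[0.1, 1000]$, spanning the dynamic range a quantifier
typically reports; about a third of genes are placed on the minus strand to
exercise transcription-order handling. Junction totals are computed from
the truth by construction, so the fixtures are exactly self-consistent.

`randomFlowDAG()` builds flows as sums of sampled path weights, which
guarantees decomposability and a known witness; adversarially balanced but
non-path-generated flows cannot arise for valid inputs.

What the fixtures do *not* model: read-level noise, fragment-length and
positional bias, mapping ambiguity between genes, and annotation errors.
Passing tests therefore certify the algorithmic claims (range endpoints,
witnesses, block graphs, interval properties) on exactly solvable instances;
they say nothing about how well an upstream quantifier estimates the flow on
real libraries, which is the quantifier's problem, not this package's.

## Verification strategy and problem sizes

Every algorithmic claim has an independent oracle. `oracleFlowRange()`
enumerates all $S$–$T$ paths (guarded at $10^5$) and solves the range LP
over the path polytope — a different algorithm, on a different
parameterisation, sharing no code path with the max-flow route. The standard
batteries are 200 seeded random DAGs (at most 10 vertices / 20 edges) with
random edge subsets and random well-ordered queries (disjoint topological
cuts along a sampled path), plus 100 synthetic genes for the LP interval
property with 20 interior probes per nonidentifiable transcript and
just-outside probes at $10^{-3}(u - l + 1)$ beyond each endpoint. These
sizes keep the full suite under a minute per battery while exercising every
code path; they are stated here so results are reproducible, and
`scripts/acceptance.R` recomputes them from scratch for any seed.

Numerical choices: flow balance is checked to $10^{-9}$ relative to $U$;
LP and max-flow endpoint comparisons use $10^{-6}$ absolute; endpoints are
clamped into $[0, U]$ after complementation to absorb solver noise;
topological order and path stripping break ties by ascending identifier so
all outputs are deterministic given a seed.

## Known limitations

* Genes are processed independently; multi-gene read sharing is not
  modelled (consistent with the per-gene linear system).
* Single-exon transcripts are flagged, not ranged, under the LP route.
* The per-transcript ranges are marginals: picking extremes for two
  transcripts simultaneously need not be jointly co-optimal, so counts of
  overlapping ranges are upper bounds on truly inconclusive pairs.
* The supergraph construction that folds multi-junction phasing reads into
  graph quantification is upstream of this package; flows are taken as
  given on whatever DAG the caller supplies.
* $\lambda$ is an assumption, not an estimate; audits therefore sweep a
  grid rather than commit to a value.
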