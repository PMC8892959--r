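# quantrange

Ranges of co-optimal transcript abundance estimates under
nonidentifiability.

## The problem

RNA-seq quantifiers (Salmon, kallisto, RSEM, ...) report a single abundance
per transcript, but the likelihood they maximise frequently has many
maximisers: because exons are shared between isoforms and fragments are
short, whole families of abundance assignments explain the observed reads
*equally well*. This nonidentifiability is structural — it does not go away
with deeper sequencing — and a point estimate hides it completely.

quantrange computes, for each transcript (or splicing pattern), the closed
interval $[l, u]$ of abundances attainable across **all** equally optimal
solutions, under three assumptions:

* **Complete reference** (every expressed transcript is annotated): the
  co-optimal set is the polytope
  $\{c' \ge 0 : \sum_{j: i \subseteq T_j} c'_j = g_i \text{ for every
  phasing path } i\}$, where $g_i$ is the junction/phasing-path total at
  the quantifier's optimum; per-transcript min/max linear programs give
  $[l^0, u^0]$.
* **Incomplete reference** (only the splice graph is trusted): co-optimal
  solutions are the decompositions of the inferred edge flow into weighted
  source-to-sink paths. For an edge set $E'$,
  $\mathrm{ORQuant}(G, E') = [\,U - \mathrm{MaxFlow}(G^-),\,
  \mathrm{MaxFlow}(G^+)\,]$ (delete $E'$ / redirect $E'$ into an auxiliary
  sink, edge flows as capacities); for an ordered list of disjoint edge
  sets $\{E_k\}$ with the well-ordering property,
  $\mathrm{ANDQuant}(G, \{E_k\}) = [\,U - r,\, U - l\,]$ where
  $[l, r] = \mathrm{ORQuant}(G, E \setminus G_B)$ and $G_B$ is the block
  graph containing exactly the good paths. A transcript's range $[l^1, u^1]$
  is AND-Quant over the singleton sets of its path.
* **Hybrid**: with $\lambda$ the assumed fraction of expression from
  unannotated paths,
  $[l^\lambda, u^\lambda] = [\lambda l^1 + (1{-}\lambda) l^0,\;
  \lambda u^1 + (1{-}\lambda) u^0]$.

The intervals drive two audits: flagging transcripts whose expression
ranking against sibling isoforms is inconclusive (overlapping ranges), and
flagging differential-expression calls whose between-group mean ranges
overlap beyond a threshold fraction (default 25%) at some $\lambda$.

## Worked example

The minimal interesting splice graph has two alternative starts (A, B) and
two alternative ends (C, D) around a shared exon M, with edge flows
S→A = 4, S→B = 6, A→M = 4, B→M = 6, M→C = 3, M→D = 7, C→T = 3, D→T = 7
(total flow U = 10):

```r
library(quantrange)
w <- wGraphFixture()
transcriptRangeGraph(w$graph, w$flow, w$paths$SAMCT)
#> AbundanceRange [0, 3] (width 3)
```

Any decomposition may route between 0 and 3 units through the path
S-A-M-C-T, so its abundance is completely undetermined beyond that
interval. The same structure through the complete-reference LP, with the
four annotated transcripts at an optimum (3, 1, 0, 6):

```r
tr <- list(TranscriptModel("T1", "g", c("SA", "AM", "MC", "CT")),
           TranscriptModel("T2", "g", c("SA", "AM", "MD", "DT")),
           TranscriptModel("T3", "g", c("SB", "BM", "MC", "CT")),
           TranscriptModel("T4", "g", c("SB", "BM", "MD", "DT")))
allRangesLP(tr, c(3, 1, 0, 6))
#>   transcript_id gene_id abundance lo hi identifiable
#> 1            T1       g         3  0  3            0
#> 2            T2       g         1  1  4            0
#> 3            T3       g         0  0  3            0
#> 4            T4       g         6  3  6            0
```

Every co-optimal solution is (3−w, 1+w, w, 6−w) for some w in [0, 3]; the
reported optimum is just one point of each interval, and transcript T3 —
reported as zero — may carry up to 3 units. Auditing a DE call whose
condition-A range is [10, 10] / [4, 16] (LP / graph) against condition-B
[4, 5] / [2, 8]:

```r
repA <- list(list(range0 = AbundanceRange(10, 10),
                  range1 = AbundanceRange(4, 16)))
repB <- list(list(range0 = AbundanceRange(4, 5),
                  range1 = AbundanceRange(2, 8)))
classifyDECall(repA, repB)$lambda_star
#> [1] 0.7
```

The call is solid while the reference explains most expression, but becomes
questionable (mean-range overlap > 25%) once at least 70% of expression is
allowed to come from unannotated paths.

## Command line

A thin wrapper (`inst/scripts/quantrange`) exposes the pipeline:

```sh
quantrange simulate    --kind transcriptome --seed 3 --out sim/
quantrange lp-range    --gtf sim/annotation.gtf --quant sim/quant.sf --out lp.tsv
quantrange graph-range --graph sim/graph_G001.tsv --query sim/query_G001.json --out gr.tsv
quantrange interpolate --lp lp.tsv --graph-ranges gr.tsv --lambda 0.5 --out merged.tsv
quantrange de-audit    --groupA a1.tsv,a2.tsv --groupB b1.tsv,b2.tsv --threshold 0.25 --out audit.tsv
quantrange sibling-rank --ranges lp.tsv --out sibling.tsv
```

Graphs travel as a plain edge-list TSV (`edge_id  u  v  flow` with
`#source`/`#sink` headers), queries as JSON (a transcript `path` or an
ordered list of edge `sets`), and quantifications in the usual quantifier
dialect (`Name Length EffectiveLength TPM NumReads`).

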