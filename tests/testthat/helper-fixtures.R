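## Shared fixtures for the test suite.

## the diamond: two parallel 2-edge paths
diamond_graph <- function(wA = 3, wB = 7) {
  g <- SpliceGraph(data.frame(
    id   = c("S->A", "A->T", "S->B", "B->T"),
    from = c("S", "A", "S", "B"),
    to   = c("A", "T", "B", "T"), stringsAsFactors = FALSE))
  list(graph = g,
       flow = Flow(c("S->A" = wA, "A->T" = wA, "S->B" = wB, "B->T" = wB)))
}

## the 4-transcript system over the W-graph junctions
w_transcripts <- function() {
  list(TranscriptModel("T1", "g1", c("SA", "AM", "MC", "CT")),
       TranscriptModel("T2", "g1", c("SA", "AM", "MD", "DT")),
       TranscriptModel("T3", "g1", c("SB", "BM", "MC", "CT")),
       TranscriptModel("T4", "g1", c("SB", "BM", "MD", "DT")))
}

## AND-sense / OR-sense predicates for the oracle
or_pred <- function(eprime) function(p) any(p %in% eprime)
and_pred <- function(query) {
  sets <- querySets(query)
  function(p) all(vapply(sets, function(s) any(p %in% s), logical(1)))
}

expect_range_equal <- function(range, lo, hi, tol = 1e-6) {
  expect_lt(abs(rangeLo(range) - lo), tol)
  expect_lt(abs(rangeHi(range) - hi), tol)
}
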