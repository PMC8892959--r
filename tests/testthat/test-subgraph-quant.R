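test_that("well-ordering check accepts path queries and finds violations", {
  w <- wGraphFixture()
  q <- pathToQuery(w$graph, w$paths$SAMCT)
  expect_true(checkWellOrdering(w$graph, q)$ok)

  ## E_1 after E_2 on the same path
  bad <- EdgeSetQuery(list("M->C", "S->A"))
  res <- checkWellOrdering(w$graph, bad)
  expect_false(res$ok)
  expect_true(res$i >= res$j)
  ## the witness is an S-T path exhibiting the violation
  expect_equal(graphEdges(w$graph)$from[match(res$witness[1],
                                              graphEdges(w$graph)$id)], "S")
  expect_true(all(res$witness %in% graphEdges(w$graph)$id))

  ## two edges of one set on a single path
  same <- EdgeSetQuery(list(c("S->A", "A->M")))
  expect_false(checkWellOrdering(w$graph, same)$ok)
  ## ... but parallel edges in one set are fine
  par <- EdgeSetQuery(list(c("M->C", "M->D")))
  expect_true(checkWellOrdering(w$graph, par)$ok)
})

test_that("auxiliary graphs implement the two max-flow reductions", {
  w <- wGraphFixture()
  gm <- buildGMinus(w$graph, c("S->A", "M->C"))
  expect_setequal(graphEdges(gm)$id,
                  setdiff(graphEdges(w$graph)$id, c("S->A", "M->C")))
  expect_equal(maxFlow(gm, w$flow)$value, 6)

  expect_identical(graphEdges(buildGMinus(w$graph, character(0)))$id,
                   graphEdges(w$graph)$id)
  no_out <- buildGMinus(w$graph, c("S->A", "S->B"))
  expect_equal(maxFlow(no_out, w$flow)$value, 0)

  gp <- buildGPlus(w$graph, c("S->A", "M->C"))
  e <- graphEdges(gp)
  expect_equal(graphSink(gp), "T_prime")
  expect_equal(sort(e$label[e$to == "T_prime"]), c("A", "C"))  # origin labels
  expect_equal(maxFlow(gp, w$flow, sink = "T_prime")$value, 7)

  ## redirecting the only sink edge captures everything
  single <- SpliceGraph(data.frame(id = c("a", "b"), from = c("S", "A"),
                                   to = c("A", "T")))
  gp2 <- buildGPlus(single, "b")
  expect_equal(maxFlow(gp2, Flow(c(a = 5, b = 5)), sink = "T_prime")$value, 5)
  ## empty E-prime leaves the auxiliary sink unreachable
  gp3 <- buildGPlus(w$graph, character(0))
  expect_equal(maxFlow(gp3, w$flow, sink = "T_prime")$value, 0)
})

test_that("maxFlow handles parallel paths and unreachable sinks", {
  d <- diamond_graph(3, 7)
  expect_equal(maxFlow(d$graph, d$flow)$value, 10)
  mf <- maxFlow(d$graph, d$flow)
  expect_equal(unname(mf$flow[c("S->A", "S->B")]), c(3, 7))
  iso <- SpliceGraph(data.frame(id = "a", from = "S", to = "A"),
                     vertices = c("S", "A", "T"))
  expect_equal(maxFlow(iso, Flow(c(a = 2)))$value, 0)
})

test_that("orQuant matches the worked example and its trivial bounds", {
  w <- wGraphFixture()
  expect_range_equal(orQuant(w$graph, w$flow, "M->C"), 3, 3)
  expect_range_equal(orQuant(w$graph, w$flow, c("S->A", "M->C")), 4, 7)
  expect_range_equal(orQuant(w$graph, w$flow, character(0)), 0, 0)
  expect_range_equal(orQuant(w$graph, w$flow, graphEdges(w$graph)$id),
                     10, 10)
  ## single-edge conservation: good flow through one edge is exactly f_e
  for (e in graphEdges(w$graph)$id) {
    f <- flowValues(w$flow)[[e]]
    expect_range_equal(orQuant(w$graph, w$flow, e), f, f)
  }
})

test_that("reachability labels reproduce the hand-computed DP", {
  w <- wGraphFixture()
  q <- EdgeSetQuery(list("S->A", "M->C"))
  lab <- computeReachLabels(w$graph, q)
  expect_equal(lab$s[c("S", "A", "B", "M", "C", "D", "T")],
               c(S = 0L, A = 1L, B = 0L, M = 1L, C = 2L, D = 1L, T = 2L))
  expect_equal(lab$t[c("T", "D", "C", "M", "A", "B", "S")],
               c(T = 3L, D = 3L, C = 3L, M = 2L, A = 2L, B = 2L, S = 1L))

  ## empty query: everything level 0 / 1
  lab0 <- computeReachLabels(w$graph, EdgeSetQuery(list()))
  expect_true(all(lab0$s == 0L))
  expect_true(all(lab0$t == 1L))

  expect_error(computeReachLabels(w$graph,
                                  EdgeSetQuery(list("M->C", "S->A"))),
               "well-ordering")
})

test_that("edge filtering keeps exactly the edges on good paths", {
  w <- wGraphFixture()
  q <- EdgeSetQuery(list("S->A", "M->C"))
  fq <- filterEdgeSets(w$graph, q)
  expect_equal(querySets(fq), list("S->A", "M->C"))

  ## an edge on no good path is dropped: D->T is only reachable while
  ## avoiding E_1, so its tail has label s = 0, not 1
  g2 <- SpliceGraph(data.frame(
    id   = c("S->A", "S->B", "A->C", "B->C", "B->D", "C->T", "D->T"),
    from = c("S", "S", "A", "B", "B", "C", "D"),
    to   = c("A", "B", "C", "C", "D", "T", "T"), stringsAsFactors = FALSE))
  q2 <- EdgeSetQuery(list("S->A", c("C->T", "D->T")))
  expect_true(checkWellOrdering(g2, q2)$ok)
  fq2 <- filterEdgeSets(g2, q2)
  expect_equal(querySets(fq2)[[2]], "C->T")
  ## the dropped edge does not change the answer: S->A's 2 units must
  ## continue through A->C and C->T in every decomposition
  f2 <- Flow(c("S->A" = 2, "S->B" = 8, "A->C" = 2, "B->C" = 3, "B->D" = 5,
               "C->T" = 5, "D->T" = 5))
  expect_range_equal(andQuant(g2, f2, q2), 2, 2)

  ## incompatible levels: no good path exists, so every set empties out
  ## (M->D is itself on no good path once C->T can never follow it)
  q3 <- EdgeSetQuery(list("M->D", "C->T"))
  fq3 <- filterEdgeSets(w$graph, q3)
  expect_equal(lengths(querySets(fq3)), c(0L, 0L))
  expect_range_equal(andQuant(w$graph, w$flow, q3), 0, 0)
})

test_that("block graph matches the worked example and trivial cases", {
  w <- wGraphFixture()
  q <- EdgeSetQuery(list("S->A", "M->C"))
  gb <- buildBlockGraph(w$graph, q)
  expect_setequal(graphEdges(gb)$id, c("S->A", "A->M", "M->C", "C->T"))

  ## single-path graph, full singleton query: block graph is the path
  single <- SpliceGraph(data.frame(id = c("a", "b"), from = c("S", "A"),
                                   to = c("A", "T")))
  gb2 <- buildBlockGraph(single, EdgeSetQuery(list("a", "b")))
  expect_setequal(graphEdges(gb2)$id, c("a", "b"))
})

test_that("andQuant matches worked examples and complementarity", {
  w <- wGraphFixture()
  expect_range_equal(andQuant(w$graph, w$flow,
                              EdgeSetQuery(list("S->A", "M->C"))), 0, 3)
  expect_range_equal(andQuant(w$graph, w$flow, EdgeSetQuery(list("S->A"))),
                     4, 4)
  expect_range_equal(transcriptRangeGraph(w$graph, w$flow, w$paths$SAMCT),
                     0, 3)
  expect_range_equal(transcriptRangeGraph(w$graph, w$flow, w$paths$SBMDT),
                     3, 6)

  ## unique decomposition: point range at the path weight
  d <- diamond_graph(3, 7)
  expect_range_equal(transcriptRangeGraph(d$graph, d$flow,
                                          c("S->A", "A->T")), 3, 3)
  ## empty query: every path good
  expect_range_equal(andQuant(w$graph, w$flow, EdgeSetQuery(list())),
                     10, 10)
  ## zero flow short-circuits
  z <- Flow(setNames(numeric(8), graphEdges(w$graph)$id))
  expect_range_equal(andQuant(w$graph, z, EdgeSetQuery(list("S->A"))), 0, 0)
})

test_that("or/and endpoints match the path-enumeration oracle on batteries", {
  for (seed in 1:40) {
    fx <- randomFlowDAG(nVertices = 5 + seed %% 5,
                        edgeDensity = 0.3 + 0.05 * (seed %% 5),
                        nPaths = 1 + seed %% 5, seed = seed)
    edges <- graphEdges(fx$graph)$id
    ep <- edges[seq_along(edges) %% 3 == 0]
    o <- orQuant(fx$graph, fx$flow, ep)
    oo <- oracleFlowRange(fx$graph, fx$flow, or_pred(ep))
    expect_lt(abs(rangeLo(o) - rangeLo(oo)), 1e-6)
    expect_lt(abs(rangeHi(o) - rangeHi(oo)), 1e-6)

    q <- randomWellOrderedQuery(fx$graph)
    a <- andQuant(fx$graph, fx$flow, q)
    ao <- oracleFlowRange(fx$graph, fx$flow, and_pred(q))
    expect_lt(abs(rangeLo(a) - rangeLo(ao)), 1e-6)
    expect_lt(abs(rangeHi(a) - rangeHi(ao)), 1e-6)
    expect_lte(rangeHi(a), totalFlow(fx$graph, fx$flow) + 1e-9)
    expect_gte(rangeLo(a), -1e-9)
  }
})

test_that("witness decompositions achieve both endpoints", {
  w <- wGraphFixture()
  ep <- c("S->A", "M->C")
  dmax <- witnessDecomposition(w$graph, w$flow, ep, "max")
  expect_equal(goodFlow(dmax, eprime = ep), 7, tolerance = 1e-9)
  dmin <- witnessDecomposition(w$graph, w$flow, ep, "min")
  expect_equal(goodFlow(dmin, eprime = ep), 4, tolerance = 1e-9)
  ## both are full decompositions
  for (d in list(dmax, dmin)) {
    sums <- setNames(numeric(8), graphEdges(w$graph)$id)
    for (k in seq_along(decompPaths(d))) {
      p <- decompPaths(d)[[k]]
      sums[p] <- sums[p] + decompWeights(d)[k]
    }
    expect_equal(sums, flowValues(w$flow)[names(sums)], tolerance = 1e-9)
  }
  ## empty E-prime: any full decomposition, zero good flow
  d0 <- witnessDecomposition(w$graph, w$flow, character(0), "max")
  expect_equal(goodFlow(d0, eprime = character(0)), 0)
  expect_equal(sum(decompWeights(d0)), 10, tolerance = 1e-9)
})

test_that("block graph equals the brute-force reachability construction", {
  for (seed in 1:40) {
    fx <- randomFlowDAG(nVertices = 5 + seed %% 6, seed = seed + 1000)
    q <- randomWellOrderedQuery(fx$graph)
    labels <- computeReachLabels(fx$graph, q)
    fq <- filterEdgeSets(fx$graph, q, labels)
    ids <- if (any(lengths(querySets(fq)) == 0L)) character(0) else
      sort(graphEdges(buildBlockGraph(fx$graph, q, labels, fq))$id)
    expect_identical(ids, bruteForceBlockGraph(fx$graph, q))
  }
})
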