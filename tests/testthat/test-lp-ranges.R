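test_that("linear system collects the junction totals g_i", {
  ## two single-junction transcripts sharing one junction
  tr <- list(TranscriptModel("T1", "g", "e1"), TranscriptModel("T2", "g", "e1"))
  sys <- buildLinearSystem(tr, c(2, 3))
  expect_equal(unname(sys@g), 5)
  expect_equal(unname(sys@membership[1, ]), c(1, 1))

  tr4 <- w_transcripts()
  sys4 <- buildLinearSystem(tr4, c(3, 1, 0, 6))
  g <- setNames(sys4@g, rownames(sys4@membership))
  expect_equal(g[c("SA", "SB", "AM", "BM", "MC", "MD", "CT", "DT")],
               c(SA = 4, SB = 6, AM = 4, BM = 6, MC = 3, MD = 7,
                 CT = 3, DT = 7))

  ## a 3-junction phasing path is contained in T1 only
  sys5 <- buildLinearSystem(tr4, c(3, 1, 0, 6),
                            phasingPaths = list("SA", "SB", "AM", "BM",
                                                "MC", "MD", "CT", "DT",
                                                c("SA", "AM", "MC")))
  row <- sys5@membership["SA,AM,MC", ]
  expect_equal(unname(row), c(1, 0, 0, 0))
  expect_equal(sys5@g[[9]], 3)

  expect_error(buildLinearSystem(tr4, c(3, 1, 0, 6),
                                 phasingPaths = list(c("MC", "MD"))),
               "contained in no transcript")
})

test_that("per-transcript LP ranges match hand-parameterized solutions", {
  tr4 <- w_transcripts()
  sys <- buildLinearSystem(tr4, c(3, 1, 0, 6))
  expect_range_equal(transcriptRangeLP(sys, "T1"), 0, 3)

  ## co-optimal set is (3-w, 1+w, w, 6-w), w in [0, 3]
  tab <- allRangesLP(tr4, c(3, 1, 0, 6))
  expect_equal(tab$lo, c(0, 1, 0, 3), tolerance = 1e-6)
  expect_equal(tab$hi, c(3, 4, 3, 6), tolerance = 1e-6)
  expect_equal(tab$identifiable, rep(0L, 4))

  ## a longer phasing path pins T1 (and with it every transcript)
  sys5 <- buildLinearSystem(tr4, c(3, 1, 0, 6),
                            phasingPaths = list("SA", "SB", "AM", "BM",
                                                "MC", "MD", "CT", "DT",
                                                c("SA", "AM", "MC")))
  expect_range_equal(transcriptRangeLP(sys5, "T1"), 3, 3)

  ## fully determined single-transcript gene
  solo <- list(TranscriptModel("T1", "g", "j1"))
  expect_range_equal(transcriptRangeLP(buildLinearSystem(solo, 7), "T1"),
                     7, 7)
})

test_that("ranges contain the input optimum and shrink under constraints", {
  fx <- syntheticTranscriptome(nGenes = 6, isoformsPerGene = 3, seed = 5)
  for (g in fx$genes) {
    tab <- allRangesLP(g$transcripts, g$abundances)
    expect_true(all(tab$lo <= tab$abundance + 1e-6))
    expect_true(all(tab$hi >= tab$abundance - 1e-6))
    ## monotonicity: adding a phasing-path constraint never widens a range
    tr <- g$transcripts
    long <- tr[[1]]@junctions[1:2]
    singles <- as.list(unique(unlist(lapply(tr, function(t) t@junctions))))
    tab2 <- allRangesLP(tr, g$abundances,
                        phasingPaths = c(singles, list(long)))
    expect_true(all(tab2$lo >= tab$lo - 1e-6))
    expect_true(all(tab2$hi <= tab$hi + 1e-6))
  }
})

test_that("probe values inside the range are feasible, outside not", {
  tr4 <- w_transcripts()
  sys <- buildLinearSystem(tr4, c(3, 1, 0, 6))
  for (p in seq(0, 3, by = 0.5)) {
    expect_true(probeAbundance(sys, "T1", p))
  }
  expect_false(probeAbundance(sys, "T1", 3.01))
  expect_false(probeAbundance(sys, "T1", -0.01))
  expect_true(probeAbundance(sys, "T4", 4.2))
  expect_false(probeAbundance(sys, "T4", 2.9))
})

test_that("LP endpoints agree with a vertex-style oracle on random systems", {
  ## independent route: oracleFlowRange over the gene's splice graph --
  ## the LP over junction sufficient statistics and the LP over the path
  ## polytope describe the same co-optimal set when every S-T path of the
  ## graph is an annotated transcript
  set.seed(31)
  fx <- syntheticTranscriptome(nGenes = 8, isoformsPerGene = 4, seed = 31)
  checked <- 0L
  for (g in fx$genes) {
    all_paths <- enumerateSTPaths(g$graph)
    if (length(all_paths) != length(g$transcripts)) next  # graph has novel paths
    tab <- allRangesLP(g$transcripts, g$abundances)
    for (k in seq_along(g$transcripts)) {
      tx <- g$transcripts[[k]]
      rng <- oracleFlowRange(g$graph, g$flow, function(p)
        identical(p, g$paths[[tx@id]]))
      expect_lt(abs(tab$lo[k] - rangeLo(rng)), 1e-6)
      expect_lt(abs(tab$hi[k] - rangeHi(rng)), 1e-6)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("degenerate inputs: empty list, point ranges, junction-free", {
  empty <- allRangesLP(list(), numeric(0))
  expect_equal(nrow(empty), 0L)

  ## two independent single-isoform genes: point ranges
  tr <- list(TranscriptModel("A1", "gA", c("a1", "a2")),
             TranscriptModel("B1", "gB", "b1"))
  tab <- allRangesLP(tr, c(4, 9))
  expect_equal(tab$lo, tab$hi)
  expect_equal(tab$identifiable, c(1L, 1L))

  ## junction-free transcript is flagged, not guessed
  tr2 <- list(TranscriptModel("X1", "gX", character()),
              TranscriptModel("X2", "gX", "j1"))
  expect_warning(tab2 <- allRangesLP(tr2, c(2, 5)), "without junctions")
  expect_equal(tab2$lo[1], 0)
  expect_equal(tab2$hi[1], 7)
  expect_equal(tab2$identifiable[1], 0L)
})
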