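test_that("interpolation obeys the affine formula and its identities", {
  r0 <- AbundanceRange(1, 2)
  r1 <- AbundanceRange(0, 3)
  expect_range_equal(interpolateRange(r0, r1, 0.5), 0.5, 2.5, tol = 1e-12)
  expect_identical(rangeLo(interpolateRange(r0, r1, 0)), rangeLo(r0))
  expect_identical(rangeHi(interpolateRange(r0, r1, 0)), rangeHi(r0))
  expect_identical(rangeLo(interpolateRange(r0, r1, 1)), rangeLo(r1))
  expect_identical(rangeHi(interpolateRange(r0, r1, 1)), rangeHi(r1))
  p <- AbundanceRange(2, 2)
  expect_range_equal(interpolateRange(p, p, 0.37), 2, 2, tol = 1e-15)
  expect_error(interpolateRange(r0, r1, 1.2), "lambda")
  expect_error(interpolateRange(r0, r1, -0.1), "lambda")
})

test_that("interpolate-then-average commutes with average-then-interpolate", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    r0s <- lapply(1:n, function(i) {
      lo <- runif(1, 0, 10); AbundanceRange(lo, lo + runif(1, 0, 5))
    })
    r1s <- lapply(1:n, function(i) {
      lo <- runif(1, 0, 10); AbundanceRange(lo, lo + runif(1, 0, 5))
    })
    lam <- runif(1)
    a <- meanRange(Map(function(a0, a1) interpolateRange(a0, a1, lam),
                       r0s, r1s))
    b <- interpolateRange(meanRange(r0s), meanRange(r1s), lam)
    expect_lt(abs(rangeLo(a) - rangeLo(b)), 1e-12)
    expect_lt(abs(rangeHi(a) - rangeHi(b)), 1e-12)
  }
})

test_that("overlap fraction follows the smaller-range convention", {
  expect_equal(overlapFraction(AbundanceRange(0, 4), AbundanceRange(2, 10)),
               0.5)
  ## symmetry
  expect_equal(overlapFraction(AbundanceRange(2, 10), AbundanceRange(0, 4)),
               0.5)
  ## disjoint and nested
  expect_equal(overlapFraction(AbundanceRange(0, 1), AbundanceRange(2, 3)), 0)
  expect_equal(overlapFraction(AbundanceRange(2, 3), AbundanceRange(0, 10)), 1)
  ## point-range conventions
  expect_equal(overlapFraction(AbundanceRange(3, 3), AbundanceRange(2, 5)), 1)
  expect_equal(overlapFraction(AbundanceRange(3, 3), AbundanceRange(4, 5)), 0)
  expect_equal(overlapFraction(AbundanceRange(3, 3), AbundanceRange(3, 3)), 1)
  expect_equal(overlapFraction(AbundanceRange(3, 3), AbundanceRange(4, 4)), 0)
  ## invariance under joint affine rescaling
  a <- AbundanceRange(1, 5); b <- AbundanceRange(4, 12)
  for (k in c(0.5, 3, 100)) {
    expect_equal(overlapFraction(AbundanceRange(1 * k, 5 * k),
                                 AbundanceRange(4 * k, 12 * k)),
                 overlapFraction(a, b))
  }
})

test_that("meanRange averages endpoints", {
  expect_range_equal(meanRange(list(AbundanceRange(0, 2),
                                    AbundanceRange(2, 4))), 1, 3,
                     tol = 1e-12)
  expect_range_equal(meanRange(list(AbundanceRange(1, 1),
                                    AbundanceRange(3, 3))), 2, 2,
                     tol = 1e-12)
  one <- AbundanceRange(0.5, 0.7)
  expect_range_equal(meanRange(list(one)), 0.5, 0.7, tol = 1e-12)
  expect_error(meanRange(list()), "at least one")
})

test_that("DE classification flags overlap and reports critical lambda", {
  point <- function(x) AbundanceRange(x, x)
  repsA <- lapply(1:3, function(i) list(range0 = point(10), range1 = point(10)))
  repsB <- lapply(1:3, function(i) list(range0 = point(2), range1 = point(2)))
  res <- classifyDECall(repsA, repsB)
  expect_false(any(res$table$questionable))
  expect_true(is.na(res$lambda_star))
  expect_true(is.na(res$lambda_touch))

  ## nesting at lambda = 1 only: graph ranges widen with lambda
  repsA2 <- list(list(range0 = AbundanceRange(10, 10),
                      range1 = AbundanceRange(0, 20)))
  repsB2 <- list(list(range0 = AbundanceRange(5, 6),
                      range1 = AbundanceRange(5, 6)))
  res2 <- classifyDECall(repsA2, repsB2)
  expect_true(res2$table$questionable[res2$table$lambda == 1])
  expect_false(res2$table$questionable[res2$table$lambda == 0])

  ## ranges linear in lambda crossing the threshold between grid points:
  ## A = [10,10] fixed; B0 = [4, 5], B1 = [4, 15], so hi_B(lam) =
  ## 5 + 10*lam reaches 10 exactly at lam = 0.5; the first flagged grid
  ## value must be 0.5
  repsA3 <- list(list(range0 = point(10), range1 = point(10)))
  repsB3 <- list(list(range0 = AbundanceRange(4, 5),
                      range1 = AbundanceRange(4, 15)))
  res3 <- classifyDECall(repsA3, repsB3)
  expect_equal(res3$lambda_star, 0.5)
  expect_equal(res3$lambda_touch, 0.5)

  ## threshold monotonicity: higher threshold flags a subset
  res_lo <- classifyDECall(repsA2, repsB2, threshold = 0)
  res_hi <- classifyDECall(repsA2, repsB2, threshold = 1.01)
  expect_false(any(res_hi$table$questionable))
  expect_true(all(res2$table$questionable <= res_lo$table$questionable))

  expect_error(classifyDECall(list(), repsB), "at least one replicate")
})

test_that("identical flows in both conditions are questionable everywhere", {
  fx <- randomFlowDAG(seed = 17)
  paths <- enumerateSTPaths(fx$graph)
  p <- paths[[1]]
  rng1 <- transcriptRangeGraph(fx$graph, fx$flow, p)
  rep <- list(range0 = rng1, range1 = rng1)
  res <- classifyDECall(list(rep, rep), list(rep, rep))
  expect_true(all(res$table$overlap == 1))
  expect_true(all(res$table$questionable))
  expect_equal(res$lambda_star, 0)
})

test_that("sibling ranking flags exactly the overlapping isoforms", {
  expect_equal(unname(siblingRankingInconclusive(
    list(T1 = AbundanceRange(0, 3), T2 = AbundanceRange(2, 5)))),
    c(TRUE, TRUE))
  expect_equal(unname(siblingRankingInconclusive(
    list(AbundanceRange(0, 1), AbundanceRange(2, 3)))), c(FALSE, FALSE))
  expect_equal(unname(siblingRankingInconclusive(
    list(AbundanceRange(1, 2)))), FALSE)
  ## mixed gene: only the overlapping pair is flagged
  flags <- siblingRankingInconclusive(
    list(a = AbundanceRange(0, 3), b = AbundanceRange(2, 5),
         c = AbundanceRange(9, 11)))
  expect_equal(unname(flags), c(TRUE, TRUE, FALSE))
})

test_that("range-table normalization scales onto the per-million scale", {
  tab <- data.frame(abundance = c(2, 8), lo = c(0, 5), hi = c(3, 10))
  out <- normalizeRangeTable(tab)
  expect_equal(sum(out$abundance), 1e6)
  expect_equal(out$lo, c(0, 5) * 1e5)
  expect_error(normalizeRangeTable(tab, total = 0), "positive")
})
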