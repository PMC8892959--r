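## Lambda-interpolated hybrid ranges, DE-reliability auditing and
## sibling-isoform ranking checks.

#' Interpolate between complete- and incomplete-reference ranges
#'
#' With `lambda` the assumed fraction of expression arising from
#' unannotated splice-graph paths, the hybrid range is the affine
#' combination `[lambda*l1 + (1-lambda)*l0, lambda*u1 + (1-lambda)*u0]` of
#' the complete-reference LP range (`range0`) and the splice-graph flow
#' range (`range1`). `lambda = 0` reproduces `range0` exactly and
#' `lambda = 1` reproduces `range1`.
#'
#' @param range0 [AbundanceRange-class] under the complete-reference
#'   assumption.
#' @param range1 [AbundanceRange-class] under the incomplete-reference
#'   (graph) assumption.
#' @param lambda number in `[0, 1]`.
#' @return An [AbundanceRange-class].
#' @examples
#' interpolateRange(AbundanceRange(1, 2), AbundanceRange(0, 3), 0.5)
#' @export
interpolateRange <- function(range0, range1, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  AbundanceRange(lambda * range1@lo + (1 - lambda) * range0@lo,
                 lambda * range1@hi + (1 - lambda) * range0@hi)
}

#' Overlap fraction of two abundance ranges
#'
#' The size of the intersection over the size of the smaller range. When
#' the smaller range has zero width the ratio is undefined; the convention
#' here is maximally conservative: a point inside (or on the boundary of)
#' the other closed range counts as full overlap (1), a point outside as 0,
#' and two points overlap iff they coincide within `eps`.
#'
#' @param a,b [AbundanceRange-class] objects in the same units.
#' @param eps tolerance for point comparisons (default `1e-6`).
#' @return Number in `[0, 1]`.
#' @examples
#' overlapFraction(AbundanceRange(0, 4), AbundanceRange(2, 10))  # 0.5
#' @export
overlapFraction <- function(a, b, eps = .EPS_LP) {
  inter <- min(a@hi, b@hi) - max(a@lo, b@lo)
  wa <- a@hi - a@lo
  wb <- b@hi - b@lo
  wmin <- min(wa, wb)
  if (wmin <= eps) {
    ## the smaller range is a point
    p <- if (wa <= wb) (a@lo + a@hi) / 2 else (b@lo + b@hi) / 2
    other_lo <- if (wa <= wb) b@lo else a@lo
    other_hi <- if (wa <= wb) b@hi else a@hi
    if (wa <= eps && wb <= eps) {
      return(as.numeric(abs(a@lo - b@lo) <= eps))
    }
    return(as.numeric(p >= other_lo - eps && p <= other_hi + eps))
  }
  max(0, min(1, inter / wmin))
}

#' Mean range across replicates
#'
#' Component-wise arithmetic mean: (mean of the lower bounds, mean of the
#' upper bounds).
#'
#' @param ranges non-empty list of [AbundanceRange-class] objects.
#' @return An [AbundanceRange-class].
#' @export
meanRange <- function(ranges) {
  if (!length(ranges)) stop("meanRange needs at least one range")
  AbundanceRange(mean(vapply(ranges, rangeLo, numeric(1))),
                 mean(vapply(ranges, rangeHi, numeric(1))))
}

#' Audit one detected DE transcript across the lambda grid
#'
#' For a transcript already detected as differentially expressed by an
#' external pipeline, each replicate of each condition contributes a
#' complete-reference range and a graph range (in shared, normalized
#' units). For every `lambda` on the grid the per-replicate ranges are
#' interpolated, averaged within each condition, and compared: the call is
#' *questionable* at that `lambda` when the overlap fraction of the two
#' mean ranges exceeds `threshold` (default 25%). Interpolation and
#' averaging are both affine, so their order does not matter.
#'
#' An alternative `rule = "gap"` mode flags the call when the mean lower
#' bound of the over-expressed condition fails to exceed the mean upper
#' bound of the other condition by at least `gapThreshold` (condition A is
#' taken as the over-expressed one).
#'
#' @param groupA,groupB lists of replicates; each replicate is a
#'   `list(range0 = , range1 = )` of [AbundanceRange-class] objects.
#' @param lambdaGrid numeric vector of lambda values (default 0, 0.1, ..., 1).
#' @param threshold overlap fraction above which the call is questionable
#'   (strict `>`; default 0.25).
#' @param rule `"overlap"` (primary) or `"gap"`.
#' @param gapThreshold margin for the gap rule (default 0; no claim of a
#'   canonical value is made for it).
#' @return A list with `table` (data.frame: `lambda`, `overlap`,
#'   `questionable`), `lambda_star` (smallest grid lambda with overlap
#'   above threshold, `NA` if none) and `lambda_touch` (smallest grid
#'   lambda at which the mean ranges intersect at all, `NA` if never).
#' @examples
#' repA <- list(list(range0 = AbundanceRange(10, 10),
#'                   range1 = AbundanceRange(8, 12)))
#' repB <- list(list(range0 = AbundanceRange(2, 2),
#'                   range1 = AbundanceRange(1, 3)))
#' classifyDECall(repA, repB)$lambda_star
#' @export
classifyDECall <- function(groupA, groupB, lambdaGrid = seq(0, 1, by = 0.1),
                           threshold = 0.25,
                           rule = c("overlap", "gap"), gapThreshold = 0) {
  rule <- match.arg(rule)
  if (!length(groupA) || !length(groupB)) {
    stop("both groups need at least one replicate")
  }
  check_rep <- function(r) {
    is.list(r) && is(r$range0, "AbundanceRange") &&
      is(r$range1, "AbundanceRange")
  }
  if (!all(vapply(groupA, check_rep, logical(1))) ||
      !all(vapply(groupB, check_rep, logical(1)))) {
    stop("each replicate must be a list(range0=, range1=) of AbundanceRange")
  }
  rows <- lapply(lambdaGrid, function(lam) {
    mA <- meanRange(lapply(groupA, function(r)
      interpolateRange(r$range0, r$range1, lam)))
    mB <- meanRange(lapply(groupB, function(r)
      interpolateRange(r$range0, r$range1, lam)))
    ov <- overlapFraction(mA, mB)
    quest <- if (rule == "overlap") {
      ov > threshold
    } else {
      mA@lo < mB@hi + gapThreshold
    }
    touching <- min(mA@hi, mB@hi) >= max(mA@lo, mB@lo) - .EPS_LP
    data.frame(lambda = lam, overlap = ov, questionable = quest,
               touching = touching)
  })
  tab <- do.call(rbind, rows)
  lambda_star <- if (any(tab$questionable)) {
    tab$lambda[which(tab$questionable)[1L]]
  } else NA_real_
  lambda_touch <- if (any(tab$touching)) {
    tab$lambda[which(tab$touching)[1L]]
  } else NA_real_
  list(table = tab[, c("lambda", "overlap", "questionable")],
       lambda_star = lambda_star, lambda_touch = lambda_touch)
}

#' Flag transcripts whose sibling-isoform ranking is inconclusive
#'
#' Within one gene, a transcript's expression ranking against a sibling
#' isoform is inconclusive when their abundance ranges intersect (closed
#' intervals; a point touching the other range counts). Each transcript is
#' flagged iff its range overlaps that of at least one sibling. A
#' single-isoform gene is never flagged.
#'
#' @param ranges named list of [AbundanceRange-class] objects, the isoforms
#'   of one gene.
#' @param eps tolerance for closed-interval intersection.
#' @return Named logical vector parallel to `ranges`.
#' @examples
#' siblingRankingInconclusive(list(T1 = AbundanceRange(0, 3),
#'                                 T2 = AbundanceRange(2, 5)))
#' @export
siblingRankingInconclusive <- function(ranges, eps = .EPS_LP) {
  n <- length(ranges)
  if (!n) return(logical(0))
  flag <- logical(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        a <- ranges[[i]]
        b <- ranges[[j]]
        if (min(a@hi, b@hi) >= max(a@lo, b@lo) - eps) {
          flag[i] <- TRUE
          flag[j] <- TRUE
        }
      }
    }
  }
  names(flag) <- names(ranges)
  flag
}

#' Normalize a range table for cross-sample comparison
#'
#' Scales the `lo`, `hi` and `abundance` columns of a per-transcript range
#' table by `1e6 / total`, bringing complete-reference ranges onto a TPM
#' scale and graph ranges onto a total flow of one million per sample.
#'
#' @param table data.frame with `abundance`, `lo`, `hi` columns.
#' @param total the sample total to normalise by (default: sum of the
#'   `abundance` column).
#' @return The table with scaled columns.
#' @export
normalizeRangeTable <- function(table, total = sum(table$abundance)) {
  if (!is.finite(total) || total <= 0) {
    stop("total must be a positive number")
  }
  k <- 1e6 / total
  for (col in intersect(c("abundance", "lo", "hi"), names(table))) {
    table[[col]] <- table[[col]] * k
  }
  table
}
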