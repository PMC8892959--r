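## Constructive witnesses: explicit flow decompositions achieving the
## OR-Quant endpoints.

## Greedy path stripping of non-negative edge weights `w` (named by edge
## id) balanced at every vertex except `source`/`sink`: repeatedly follow
## the smallest-id positive-residual out-edge from `source` to `sink` and
## subtract the bottleneck. On a DAG this terminates in <= |E| paths.
.strip_paths <- function(graph, w, source, sink, tol) {
  out <- .out_edges(graph)
  ids <- graph@edges$id
  to <- graph@edges$to
  res <- stats::setNames(numeric(length(ids)), ids)
  idx <- match(names(w), ids)
  res[idx[!is.na(idx)]] <- w[!is.na(idx)]
  paths <- list()
  weights <- numeric(0)
  repeat {
    start_edges <- out[[source]]
    start_edges <- start_edges[res[ids[start_edges]] > tol]
    if (!length(start_edges)) break
    path <- character(0)
    cur <- source
    while (cur != sink) {
      cand <- out[[cur]]
      cand <- cand[res[ids[cand]] > tol]
      if (!length(cand)) {
        stop("internal error: flow stranded at vertex '", cur,
             "' during decomposition")
      }
      e <- cand[order(ids[cand])][1L]
      path <- c(path, ids[e])
      cur <- to[e]
    }
    wgt <- min(res[path])
    res[path] <- res[path] - wgt
    paths[[length(paths) + 1L]] <- path
    weights <- c(weights, wgt)
  }
  list(paths = paths, weights = weights, residual = res)
}

#' Decompose a flow into weighted S-T paths
#'
#' Produces one (of generally many) full decompositions by greedy path
#' stripping with a deterministic tie-break (ascending edge id). Every
#' valid flow on a finite DAG admits such a decomposition.
#'
#' @inheritParams orQuant
#' @param tol residual treated as zero, relative to `max(1, U)`.
#' @return A [Decomposition-class] whose per-edge weight sums reproduce the
#'   flow.
#' @examples
#' w <- wGraphFixture()
#' decomposeFlow(w$graph, w$flow)
#' @export
decomposeFlow <- function(graph, flow, tol = .EPS_BALANCE) {
  U <- totalFlow(graph, flow)
  st <- .strip_paths(graph, flow@values, graph@source, graph@sink,
                     tol * max(1, U))
  Decomposition(st$paths, st$weights)
}

#' Total good flow of a decomposition
#'
#' Sums the weights of the good paths: paths intersecting `eprime`
#' (OR-sense) or, when `query` is given, paths intersecting every set of
#' the query (AND-sense).
#'
#' @param decomposition a [Decomposition-class].
#' @param eprime character vector of edge ids (OR-sense predicate).
#' @param query an [EdgeSetQuery-class] (AND-sense predicate), used when
#'   `eprime` is missing.
#' @return Scalar total good flow.
#' @export
goodFlow <- function(decomposition, eprime = NULL, query = NULL) {
  good <- if (!is.null(eprime)) {
    vapply(decomposition@paths, function(p) any(p %in% eprime), logical(1))
  } else if (!is.null(query)) {
    vapply(decomposition@paths, function(p)
      all(vapply(query@sets, function(s) any(p %in% s), logical(1))),
      logical(1))
  } else {
    stop("supply eprime or query")
  }
  sum(decomposition@weights[good])
}

## Check that a decomposition reproduces the flow edge-for-edge.
.decomposition_valid <- function(graph, flow, decomposition, tol) {
  sums <- stats::setNames(numeric(nrow(graph@edges)), graph@edges$id)
  for (k in seq_along(decomposition@paths)) {
    p <- decomposition@paths[[k]]
    sums[p] <- sums[p] + decomposition@weights[k]
  }
  f <- stats::setNames(.flow_vector(graph, flow), graph@edges$id)
  max(abs(sums - f)) <= tol
}

#' Witness decomposition achieving an OR-Quant endpoint
#'
#' Constructs a full decomposition of the flow whose total good flow equals
#' the requested [orQuant()] endpoint.
#'
#' For the minimum: a maximum flow on `G-` (the graph without `E'`) is
#' decomposed into bad paths, and the residual flow is decomposed into
#' paths that are necessarily all good.
#'
#' For the maximum: a maximum flow on `G*` (`E'` redirected into the
#' auxiliary sink) is decomposed into truncated source-to-`T_prime` paths,
#' which are then completed to full S-T paths one at a time: always pick
#' the truncated path whose second-to-last vertex is topologically latest
#' (ties broken by ascending path index), route its weight onward to the
#' sink with a max-flow on the remaining capacity, prepend the truncated
#' prefix to the resulting paths, and recurse on the residuals; the final
#' residual decomposes into bad paths.
#'
#' The returned decomposition is re-validated (edge sums reproduce the
#' flow) and its good flow re-evaluated against the endpoint; a mismatch is
#' an internal error and aborts loudly.
#'
#' @inheritParams orQuant
#' @param target `"min"` or `"max"`: which endpoint to witness.
#' @return A [Decomposition-class] with `goodFlow(., eprime)` equal to the
#'   endpoint.
#' @examples
#' w <- wGraphFixture()
#' d <- witnessDecomposition(w$graph, w$flow, c("S->A", "M->C"), "max")
#' goodFlow(d, eprime = c("S->A", "M->C"))  # 7
#' @export
witnessDecomposition <- function(graph, flow, eprime,
                                 target = c("min", "max")) {
  target <- match.arg(target)
  U <- totalFlow(graph, flow)
  rng <- orQuant(graph, flow, eprime)
  endpoint <- if (target == "min") rng@lo else rng@hi
  tol <- max(.EPS_LP, .EPS_BALANCE * max(1, U))
  if (U <= 0) return(Decomposition())
  f <- stats::setNames(.flow_vector(graph, flow), graph@edges$id)

  if (target == "min") {
    gm <- buildGMinus(graph, eprime)
    mf <- maxFlow(gm, flow)
    bad <- .strip_paths(gm, mf$flow, graph@source, graph@sink, tol)
    resid <- f
    resid[names(mf$flow)] <- resid[names(mf$flow)] - mf$flow
    good <- .strip_paths(graph, resid, graph@source, graph@sink, tol)
    dec <- Decomposition(c(bad$paths, good$paths),
                         c(bad$weights, good$weights))
  } else {
    gp <- buildGPlus(graph, eprime)
    mf <- maxFlow(gp, flow, sink = .T_PRIME)
    trunc <- .strip_paths(gp, mf$flow, graph@source, .T_PRIME, tol)
    dec <- .complete_truncated(graph, f, trunc, tol)
  }

  achieved <- goodFlow(dec, eprime = eprime)
  if (abs(achieved - endpoint) > max(tol, 1e-6 * max(1, U))) {
    stop("internal error: witness good flow ", achieved,
         " does not match the ", target, " endpoint ", endpoint)
  }
  if (!.decomposition_valid(graph, flow, dec, max(tol, 1e-6 * max(1, U)))) {
    stop("internal error: witness is not a full decomposition of the flow")
  }
  dec
}

## Complete truncated S-T' paths to full S-T paths by the induction
## protocol, then decompose the residual into bad paths.
.complete_truncated <- function(graph, f, trunc, tol) {
  topo <- topologicalOrder(graph)
  pos <- stats::setNames(seq_along(topo), topo)
  efrom <- stats::setNames(graph@edges$from, graph@edges$id)
  eto <- stats::setNames(graph@edges$to, graph@edges$id)
  f_cur <- f
  paths_out <- list()
  weights_out <- numeric(0)
  Rstar <- trunc$paths
  cstar <- trunc$weights
  while (length(Rstar)) {
    ## second-to-last vertex = tail of the last (redirected) edge
    u_of <- vapply(Rstar, function(p) efrom[p[length(p)]], character(1))
    pick <- which.max(pos[u_of])  # ties: first (ascending path index)
    P <- Rstar[[pick]]
    cc <- cstar[pick]
    Rstar <- Rstar[-pick]
    cstar <- cstar[-pick]
    if (cc <= tol) next
    v <- eto[P[length(P)]]  # original destination of the redirected edge
    if (v == graph@sink) {
      paths_out[[length(paths_out) + 1L]] <- P
      weights_out <- c(weights_out, cc)
      f_cur[P] <- f_cur[P] - cc
      next
    }
    mfv <- maxFlow(graph, f_cur, source = v, sink = graph@sink)
    if (mfv$value < cc - max(tol, 1e-6)) {
      stop("internal error: cannot route ", cc, " from '", v,
           "' to the sink during witness completion")
    }
    ext <- .strip_paths(graph, mfv$flow, v, graph@sink, tol)
    remaining <- cc
    for (k in seq_along(ext$paths)) {
      if (remaining <= tol) break
      w <- min(ext$weights[k], remaining)
      full <- c(P, ext$paths[[k]])
      paths_out[[length(paths_out) + 1L]] <- full
      weights_out <- c(weights_out, w)
      f_cur[full] <- f_cur[full] - w
      remaining <- remaining - w
    }
    if (remaining > max(tol, 1e-6)) {
      stop("internal error: witness completion left ", remaining,
           " unrouted")
    }
  }
  resid <- .strip_paths(graph, f_cur, graph@source, graph@sink, tol)
  Decomposition(c(paths_out, resid$paths), c(weights_out, resid$weights))
}
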