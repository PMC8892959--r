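## Incomplete-reference ranges: OR-Quant and AND-Quant on a splice-graph
## flow via auxiliary-graph max-flows and the block-graph construction.

.T_PRIME <- "T_prime"  # reserved auxiliary-sink vertex name

## igraph view of a SpliceGraph; edge order preserved.
.as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph@edges[, c("from", "to", "id")],
    directed = TRUE,
    vertices = data.frame(name = graph@vertices))
}

#' Maximum s-t flow with real capacities
#'
#' Thin deterministic wrapper around `igraph::max_flow()` on the splice
#' graph with the given per-edge capacities. An unreachable sink yields
#' value 0. Returned witness flows are clamped into `[0, capacity]` to
#' absorb solver noise.
#'
#' @param graph a [SpliceGraph-class] (a DAG).
#' @param capacities named numeric vector (edge id -> capacity) or a
#'   [Flow-class]; missing edges default to capacity 0.
#' @param source,sink vertex ids; default the graph's own.
#' @return list with `value` (scalar) and `flow` (named numeric, a feasible
#'   witness flow of that value).
#' @examples
#' w <- wGraphFixture()
#' maxFlow(w$graph, w$flow)$value  # 10
#' @export
maxFlow <- function(graph, capacities, source = graphSource(graph),
                    sink = graphSink(graph)) {
  if (is(capacities, "Flow")) capacities <- capacities@values
  cap <- numeric(nrow(graph@edges))
  idx <- match(names(capacities), graph@edges$id)
  cap[idx[!is.na(idx)]] <- capacities[!is.na(idx)]
  cap <- pmax(cap, 0)
  if (!all(c(source, sink) %in% graph@vertices)) {
    stop("source/sink not in vertex set")
  }
  if (identical(source, sink)) stop("source and sink must differ")
  empty <- stats::setNames(numeric(nrow(graph@edges)), graph@edges$id)
  if (nrow(graph@edges) == 0L) return(list(value = 0, flow = empty))
  ig <- .as_igraph(graph)
  mf <- igraph::max_flow(ig, source = source, target = sink, capacity = cap)
  f <- pmin(pmax(as.numeric(mf$flow), 0), cap)
  list(value = as.numeric(mf$value),
       flow = stats::setNames(f, graph@edges$id))
}

#' Auxiliary graphs for OR-Quant
#'
#' `buildGMinus` removes the query edges `E'` from the graph: its max-flow
#' (edge flows as capacities) is the largest amount of flow that can be
#' routed entirely over *bad* paths, so `U - MaxFlow(G-)` is the minimum
#' good flow. `buildGPlus` redirects every edge of `E'` into a fresh
#' auxiliary sink `"T_prime"`, keeping the original destination as the edge
#' label; its max-flow is the maximum good flow. Edge ids are preserved in
#' both constructions so flows and witnesses map back to the original
#' graph.
#'
#' @param graph a [SpliceGraph-class].
#' @param eprime character vector of edge ids (`E'`, a subset of the edges).
#' @return A [SpliceGraph-class]: `G-` without the `E'` edges, or `G+`
#'   (also called `G*`) with sink `"T_prime"`.
#' @examples
#' w <- wGraphFixture()
#' gm <- buildGMinus(w$graph, c("S->A", "M->C"))
#' maxFlow(gm, w$flow)$value  # 6
#' gp <- buildGPlus(w$graph, c("S->A", "M->C"))
#' maxFlow(gp, w$flow, sink = "T_prime")$value  # 7
#' @export
buildGMinus <- function(graph, eprime) {
  if (length(eprime)) .edge_index(graph, eprime)  # id check
  e <- graph@edges[!(graph@edges$id %in% eprime), , drop = FALSE]
  SpliceGraph(e, source = graph@source, sink = graph@sink,
              vertices = graph@vertices)
}

#' @rdname buildGMinus
#' @export
buildGPlus <- function(graph, eprime) {
  if (.T_PRIME %in% graph@vertices) {
    stop("graph already contains the reserved vertex '", .T_PRIME, "'")
  }
  if (length(eprime)) .edge_index(graph, eprime)
  e <- graph@edges
  redirect <- e$id %in% eprime
  e$label[redirect] <- e$to[redirect]
  e$to[redirect] <- .T_PRIME
  SpliceGraph(e, source = graph@source, sink = .T_PRIME,
              vertices = c(graph@vertices, .T_PRIME))
}

#' OR-Quant: range of total good flow for a single edge set
#'
#' An S-T path is *good* when it intersects `E'`; the good flow of a
#' decomposition is the total weight of its good paths. Over all
#' decompositions of the flow the good flow spans exactly
#' `[U - MaxFlow(G-), MaxFlow(G+)]`, with the edge flows as capacities.
#' Endpoints are clamped into `[0, U]` to absorb solver noise.
#'
#' @param graph a [SpliceGraph-class].
#' @param flow a valid [Flow-class] on the graph.
#' @param eprime character vector of edge ids.
#' @return An [AbundanceRange-class].
#' @examples
#' w <- wGraphFixture()
#' orQuant(w$graph, w$flow, c("S->A", "M->C"))  # [4, 7]
#' @export
orQuant <- function(graph, flow, eprime) {
  U <- totalFlow(graph, flow)  # refuses invalid flows
  if (U <= 0) return(AbundanceRange(0, 0))
  if (!length(eprime)) return(AbundanceRange(0, 0))
  lo <- U - maxFlow(buildGMinus(graph, eprime), flow)$value
  gp <- buildGPlus(graph, eprime)
  hi <- maxFlow(gp, flow, sink = .T_PRIME)$value
  lo <- min(max(lo, 0), U)
  hi <- min(max(hi, lo), U)
  AbundanceRange(lo, hi)
}

#' Check the well-ordering property of a query
#'
#' A query is well-ordered when no S-T path visits an edge of `E_i` and
#' later an edge of `E_j` with `i >= j`. Checked through the reachability
#' partial order on the graph restricted to vertices lying on S-T paths:
#' edge `e` precedes edge `f` on some S-T path iff `head(e)` reaches
#' `tail(f)`.
#'
#' @param graph a [SpliceGraph-class].
#' @param query an [EdgeSetQuery-class].
#' @return list with `ok` (logical); on violation also `i`, `j`
#'   (set indices with `i >= j` but `E_i` visited first) and `witness`, an
#'   S-T path (edge ids) exhibiting the violation.
#' @export
checkWellOrdering <- function(graph, query) {
  sets <- query@sets
  for (s in sets) if (length(s)) .edge_index(graph, s)
  pg <- .prune_to_st(graph)
  if (nrow(pg@edges) == 0L || length(sets) == 0L) return(list(ok = TRUE))
  reach <- .reachability(pg)
  em <- pg@edges
  for (i in seq_along(sets)) {
    for (j in seq_len(i)) {
      for (ei in intersect(sets[[i]], em$id)) {
        for (ej in intersect(sets[[j]], em$id)) {
          if (ei == ej) next
          hi <- em$to[em$id == ei]
          tj <- em$from[em$id == ej]
          if (reach[hi, tj]) {
            return(list(ok = FALSE, i = i, j = j,
                        witness = .st_path_through(pg, ei, ej, reach)))
          }
        }
      }
    }
  }
  list(ok = TRUE)
}

## An S-T path passing through edge `a` then edge `b` (head(a) reaches
## tail(b)); used to produce well-ordering violation witnesses.
.st_path_through <- function(pg, a, b, reach) {
  em <- pg@edges
  seg1 <- .any_path(pg, pg@source, em$from[em$id == a], reach)
  seg2 <- .any_path(pg, em$to[em$id == a], em$from[em$id == b], reach)
  seg3 <- .any_path(pg, em$to[em$id == b], pg@sink, reach)
  c(seg1, a, seg2, b, seg3)
}

## Any directed path u ->* v as an edge-id sequence (empty when u == v).
.any_path <- function(pg, u, v, reach) {
  if (u == v) return(character(0))
  out <- .out_edges(pg)
  path <- character(0)
  cur <- u
  while (cur != v) {
    cand <- out[[cur]]
    nxt <- cand[vapply(pg@edges$to[cand], function(w) reach[w, v],
                       logical(1))]
    if (!length(nxt)) stop("internal error: lost path from ", u, " to ", v)
    e <- nxt[order(pg@edges$id[nxt])][1L]
    path <- c(path, pg@edges$id[e])
    cur <- pg@edges$to[e]
  }
  path
}

#' Linear-time reachability labels for a well-ordered query
#'
#' On the graph pruned to S-T-path vertices, `s(v)` is the largest `i` such
#' that some path from the source reaches `v` via an edge of each
#' `E_1..E_i` in order, and `t(v)` the smallest `i` such that some path
#' from `v` reaches the sink via an edge of each `E_i..E_m` in order.
#' Computed by forward/backward dynamic programming over the topological
#' order: `s(v)` is initialized to the largest `s(u)` over predecessors,
#' then raised to `j` for every query edge `(u, v)` in `E_j` with
#' `s(u) = j - 1` (symmetrically for `t`).
#'
#' @param graph a [SpliceGraph-class]; vertices off S-T paths are pruned
#'   internally (the input is never mutated).
#' @param query a well-ordered [EdgeSetQuery-class]; a violating query is
#'   refused.
#' @return list with named integer vectors `s` and `t` (over the pruned
#'   vertex set), the pruned `graph`, and `m` (the number of query sets).
#' @examples
#' w <- wGraphFixture()
#' q <- EdgeSetQuery(list("S->A", "M->C"))
#' computeReachLabels(w$graph, q)$s  # S=0 A=1 B=0 M=1 C=2 D=1 T=2
#' @export
computeReachLabels <- function(graph, query) {
  chk <- checkWellOrdering(graph, query)
  if (!chk$ok) {
    stop("query violates the well-ordering property (set ", chk$i,
         " visited before set ", chk$j, ")")
  }
  pg <- .prune_to_st(graph)
  sets <- query@sets
  m <- length(sets)
  topo <- topologicalOrder(pg)
  level_of <- stats::setNames(rep(NA_integer_, nrow(pg@edges)), pg@edges$id)
  for (k in seq_along(sets)) {
    level_of[intersect(sets[[k]], pg@edges$id)] <- k
  }
  s <- stats::setNames(integer(length(topo)), topo)
  in_by_v <- .in_edges(pg)
  for (v in topo) {
    if (v == pg@source) { s[v] <- 0L; next }
    eidx <- in_by_v[[v]]
    preds <- pg@edges$from[eidx]
    s[v] <- if (length(preds)) max(s[preds]) else 0L
    for (r in seq_along(eidx)) {
      jlev <- level_of[pg@edges$id[eidx[r]]]
      if (!is.na(jlev) && s[preds[r]] == jlev - 1L) {
        s[v] <- max(s[v], jlev)
      }
    }
  }
  t <- stats::setNames(integer(length(topo)), topo)
  out_by_v <- .out_edges(pg)
  for (v in rev(topo)) {
    if (v == pg@sink) { t[v] <- m + 1L; next }
    eidx <- out_by_v[[v]]
    succs <- pg@edges$to[eidx]
    t[v] <- if (length(succs)) min(t[succs]) else m + 1L
    for (r in seq_along(eidx)) {
      jlev <- level_of[pg@edges$id[eidx[r]]]
      if (!is.na(jlev) && t[succs[r]] == jlev + 1L) {
        t[v] <- min(t[v], jlev)
      }
    }
  }
  list(s = s, t = t, graph = pg, m = m)
}

#' Filter query edge sets to edges on good paths
#'
#' An edge `(u, v)` of `E_i` lies on a good S-T path iff `s(u) = i - 1` and
#' `t(v) = i + 1`; all other query edges can be discarded without changing
#' the AND-Quant answer. An `E_i` left empty proves that no good path
#' exists (the query is infeasible and the good-flow range is `[0, 0]`).
#'
#' @inheritParams computeReachLabels
#' @param labels result of [computeReachLabels()] for the same query.
#' @return An [EdgeSetQuery-class] with the surviving edges (sets may be
#'   empty).
#' @export
filterEdgeSets <- function(graph, query, labels = computeReachLabels(graph, query)) {
  pg <- labels$graph
  em <- pg@edges
  sets <- lapply(seq_along(query@sets), function(i) {
    keep <- character(0)
    for (e in intersect(query@sets[[i]], em$id)) {
      u <- em$from[em$id == e]
      v <- em$to[em$id == e]
      if (labels$s[u] == i - 1L && labels$t[v] == i + 1L) keep <- c(keep, e)
    }
    keep
  })
  EdgeSetQuery(sets)
}

#' Build the block graph of a well-ordered query
#'
#' The block graph `G_B` consists of the (filtered) query edges plus the
#' block edges: non-query edges `(u, v)` with `s(u) + 1 = t(v)`, i.e. edges
#' lying between consecutive query levels. Every S-T path inside `G_B` is
#' good, and every good S-T path of the graph lies inside `G_B`, which is
#' what makes the AND-to-OR complementation exact.
#'
#' @inheritParams filterEdgeSets
#' @param filteredQuery result of [filterEdgeSets()]; every set must be
#'   non-empty.
#' @return A [SpliceGraph-class]: the subgraph `G_B`.
#' @examples
#' w <- wGraphFixture()
#' q <- EdgeSetQuery(list("S->A", "M->C"))
#' graphEdges(buildBlockGraph(w$graph, q))$id  # S->A, A->M, M->C, C->T
#' @export
buildBlockGraph <- function(graph, query,
                            labels = computeReachLabels(graph, query),
                            filteredQuery = filterEdgeSets(graph, query, labels)) {
  if (any(lengths(filteredQuery@sets) == 0L) && length(filteredQuery@sets)) {
    stop("query is infeasible: an edge set has no edge on any good path")
  }
  pg <- labels$graph
  em <- pg@edges
  qids <- unlist(filteredQuery@sets)
  block <- vapply(seq_len(nrow(em)), function(r) {
    if (em$id[r] %in% qids) return(FALSE)
    labels$s[em$from[r]] + 1L == labels$t[em$to[r]]
  }, logical(1))
  keep <- em$id %in% qids | block
  SpliceGraph(em[keep, , drop = FALSE], source = pg@source, sink = pg@sink,
              vertices = pg@vertices)
}

#' AND-Quant: range of total good flow for an ordered query
#'
#' An S-T path is *good* when it intersects every set of the well-ordered
#' query. The range of total good flow over all decompositions of the flow
#' is obtained by complementation: with
#' `[l, r] = orQuant(graph, flow, E - edges(G_B))`, the answer is
#' `[U - r, U - l]`, clamped into `[0, U]`. An infeasible query (an edge
#' set with no edge on any good path) short-circuits to `[0, 0]`, as does a
#' zero flow. An empty query (`m = 0`) makes every path good: `[U, U]`.
#'
#' @inheritParams orQuant
#' @param query an [EdgeSetQuery-class]; must satisfy well-ordering.
#' @return An [AbundanceRange-class].
#' @examples
#' w <- wGraphFixture()
#' andQuant(w$graph, w$flow, EdgeSetQuery(list("S->A", "M->C")))  # [0, 3]
#' @export
andQuant <- function(graph, flow, query) {
  U <- totalFlow(graph, flow)
  if (U <= 0) return(AbundanceRange(0, 0))
  labels <- computeReachLabels(graph, query)  # refuses ill-ordered queries
  fq <- filterEdgeSets(graph, query, labels)
  if (length(fq@sets) && any(lengths(fq@sets) == 0L)) {
    return(AbundanceRange(0, 0))
  }
  gb <- buildBlockGraph(graph, query, labels, fq)
  eprime <- setdiff(graph@edges$id, gb@edges$id)
  if (!length(eprime)) return(AbundanceRange(U, U))
  or <- orQuant(graph, flow, eprime)
  lo <- min(max(U - or@hi, 0), U)
  hi <- min(max(U - or@lo, lo), U)
  AbundanceRange(lo, hi)
}

#' Range of optima for a full transcript on the splice graph
#'
#' Converts the transcript's S-T path to a singleton-set query
#' ([pathToQuery()]) and runs [andQuant()]: the result is the interval of
#' abundances the transcript attains across all flow decompositions.
#'
#' @inheritParams orQuant
#' @param path character vector of edge ids: the transcript's S-T path.
#' @return An [AbundanceRange-class].
#' @examples
#' w <- wGraphFixture()
#' transcriptRangeGraph(w$graph, w$flow, c("S->A", "A->M", "M->C", "C->T"))
#' @export
transcriptRangeGraph <- function(graph, flow, path) {
  andQuant(graph, flow, pathToQuery(graph, path))
}
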