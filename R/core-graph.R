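## Graph/flow primitives shared by all modules.

## Default tolerances: flow balance is checked relative to the total flow
## (double-precision solver noise grows with U); LP/max-flow endpoint
## comparisons use an absolute 1e-6.
.EPS_BALANCE <- 1e-9
.EPS_LP <- 1e-6

.out_edges <- function(graph) split(seq_len(nrow(graph@edges)), graph@edges$from)
.in_edges  <- function(graph) split(seq_len(nrow(graph@edges)), graph@edges$to)

.edge_index <- function(graph, ids) {
  idx <- match(ids, graph@edges$id)
  if (anyNA(idx)) {
    stop("unknown edge id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Topological order of a splice graph
#'
#' Kahn's algorithm with a deterministic tie-break (ascending vertex id).
#' The source sorts first among vertices reachable from it and the sink
#' last, because in-/out-degrees force it. A cycle aborts with a witness
#' naming the vertices involved.
#'
#' @param graph a [SpliceGraph-class].
#' @return Character vector: a permutation of the vertex set in which every
#'   edge points forward.
#' @examples
#' g <- wGraphFixture()$graph
#' topologicalOrder(g)
#' @export
setGeneric("topologicalOrder", function(graph) standardGeneric("topologicalOrder"))

#' @rdname topologicalOrder
#' @export
setMethod("topologicalOrder", "SpliceGraph", function(graph) {
  verts <- sort(graph@vertices)
  indeg <- stats::setNames(integer(length(verts)), verts)
  tab <- table(graph@edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- .out_edges(graph)
  order_out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  indeg_left <- indeg
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    order_out <- c(order_out, v)
    succ <- graph@edges$to[out[[v]]]
    for (w in succ) {
      indeg_left[w] <- indeg_left[w] - 1L
      if (indeg_left[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order_out) != length(verts)) {
    witness <- setdiff(verts, order_out)
    stop("graph contains a cycle through vertices: ",
         paste(witness, collapse = ", "))
  }
  order_out
})

#' Validate a flow against a splice graph
#'
#' Checks the flow axioms: non-negativity on every edge and flow balance at
#' every vertex except the source and sink, each within `tol * max(1, U)`.
#' Referencing an edge id absent from the graph is a structural error (a
#' `stop()`), distinct from a numeric violation (a report row).
#'
#' @param graph a [SpliceGraph-class].
#' @param flow a [Flow-class] whose names are edge ids of `graph`. Edges
#'   without an entry carry zero flow.
#' @param tol relative balance tolerance (default `1e-9`).
#' @return data.frame with columns `type` (`"negative"` or `"imbalance"`),
#'   `location` (edge or vertex id) and `residual`; zero rows iff the flow
#'   is valid.
#' @examples
#' g <- SpliceGraph(data.frame(id = c("S->A", "A->T", "S->B", "B->T"),
#'                             from = c("S", "A", "S", "B"),
#'                             to   = c("A", "T", "B", "T")))
#' validateFlow(g, Flow(c("S->A" = 3, "A->T" = 2, "S->B" = 7, "B->T" = 7)))
#' @export
setGeneric("validateFlow", function(graph, flow, tol = .EPS_BALANCE)
  standardGeneric("validateFlow"))

#' @rdname validateFlow
#' @export
setMethod("validateFlow", signature("SpliceGraph", "Flow"),
  function(graph, flow, tol = .EPS_BALANCE) {
    vals <- flow@values
    unknown <- setdiff(names(vals), graph@edges$id)
    if (length(unknown)) {
      stop("flow references unknown edge id(s): ",
           paste(unknown, collapse = ", "))
    }
    f <- .flow_vector(graph, flow)
    U <- sum(f[graph@edges$from == graph@source])
    eps <- tol * max(1, abs(U))
    report <- data.frame(type = character(), location = character(),
                         residual = numeric(), stringsAsFactors = FALSE)
    neg <- which(f < -eps)
    if (length(neg)) {
      report <- rbind(report, data.frame(
        type = "negative", location = graph@edges$id[neg],
        residual = f[neg], stringsAsFactors = FALSE))
    }
    internal <- setdiff(graph@vertices, c(graph@source, graph@sink))
    for (v in internal) {
      res <- sum(f[graph@edges$to == v]) - sum(f[graph@edges$from == v])
      if (abs(res) > eps) {
        report <- rbind(report, data.frame(
          type = "imbalance", location = v, residual = res,
          stringsAsFactors = FALSE))
      }
    }
    rownames(report) <- NULL
    report
  })

## Per-edge flow in graph edge order; absent edges carry 0.
.flow_vector <- function(graph, flow) {
  f <- numeric(nrow(graph@edges))
  idx <- match(names(flow@values), graph@edges$id)
  f[idx[!is.na(idx)]] <- flow@values[!is.na(idx)]
  f
}

#' Total flow of a valid flow
#'
#' The total flow U is the total outflow of the source (equal, for a valid
#' flow, to the total inflow of the sink).
#'
#' @inheritParams validateFlow
#' @return Non-negative scalar U.
#' @export
setGeneric("totalFlow", function(graph, flow) standardGeneric("totalFlow"))

#' @rdname totalFlow
#' @export
setMethod("totalFlow", signature("SpliceGraph", "Flow"), function(graph, flow) {
  report <- validateFlow(graph, flow)
  if (nrow(report)) {
    stop("invalid flow: ", paste(
      sprintf("%s at %s (residual %g)", report$type, report$location,
              report$residual), collapse = "; "))
  }
  f <- .flow_vector(graph, flow)
  sum(f[graph@edges$from == graph@source])
})

#' Convert a transcript's S-T path to a full-transcript query
#'
#' For quantifying a full transcript, the AND-Quant query is the ordered
#' list of singleton edge sets, one per edge of the transcript's S-T path.
#' On a DAG the result satisfies the well-ordering property by construction.
#'
#' @param graph a [SpliceGraph-class].
#' @param path character vector of edge ids forming a contiguous
#'   source-to-sink path.
#' @return An [EdgeSetQuery-class] of singletons in path order.
#' @examples
#' w <- wGraphFixture()
#' pathToQuery(w$graph, c("S->A", "A->M", "M->C", "C->T"))
#' @export
setGeneric("pathToQuery", function(graph, path) standardGeneric("pathToQuery"))

#' @rdname pathToQuery
#' @export
setMethod("pathToQuery", "SpliceGraph", function(graph, path) {
  idx <- .edge_index(graph, path)
  e <- graph@edges[idx, , drop = FALSE]
  if (nrow(e) == 0L) stop("path must contain at least one edge")
  if (e$from[1L] != graph@source) {
    stop("path must start at the source '", graph@source, "'")
  }
  if (e$to[nrow(e)] != graph@sink) {
    stop("path must end at the sink '", graph@sink, "'")
  }
  if (nrow(e) > 1L && !all(e$to[-nrow(e)] == e$from[-1L])) {
    gap <- which(e$to[-nrow(e)] != e$from[-1L])[1L]
    stop("path is not contiguous between edges '", e$id[gap], "' and '",
         e$id[gap + 1L], "'")
  }
  EdgeSetQuery(as.list(e$id))
})

## Vertices reachable from `start` following edge direction (`forward`)
## or against it.
.reachable_set <- function(graph, start, forward = TRUE) {
  adj <- if (forward) .out_edges(graph) else .in_edges(graph)
  target_col <- if (forward) "to" else "from"
  seen <- stats::setNames(logical(length(graph@vertices)), graph@vertices)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nxt <- graph@edges[[target_col]][adj[[v]]]
    nxt <- nxt[!seen[nxt]]
    if (length(nxt)) {
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  names(seen)[seen]
}

## Restrict graph to vertices that lie on at least one S-T path
## (reachable from S and co-reachable to T): two BFS passes, on a copy.
.prune_to_st <- function(graph) {
  keep <- intersect(.reachable_set(graph, graph@source, TRUE),
                    .reachable_set(graph, graph@sink, FALSE))
  keep <- union(keep, c(graph@source, graph@sink))
  e <- graph@edges[graph@edges$from %in% keep & graph@edges$to %in% keep, ,
                   drop = FALSE]
  SpliceGraph(e, source = graph@source, sink = graph@sink, vertices = keep)
}

## Boolean reachability: reach[u, v] is TRUE iff a directed path u ->* v
## exists (including u == v). Dense DP over the topological order; fine at
## the gene-level graph sizes this package works on.
.reachability <- function(graph) {
  topo <- topologicalOrder(graph)
  n <- length(topo)
  reach <- matrix(FALSE, n, n, dimnames = list(topo, topo))
  diag(reach) <- TRUE
  in_by_v <- .in_edges(graph)
  for (v in topo) {
    preds <- graph@edges$from[in_by_v[[v]]]
    for (u in preds) {
      reach[, v] <- reach[, v] | reach[, u]
    }
  }
  reach
}

#' Read / write the plain-text edge-list graph format
#'
#' One line per edge, `edge_id<TAB>u<TAB>v<TAB>flow`, preceded by header
#' lines `#source S` and `#sink T`. Flow values are serialized with 17
#' significant digits so the round trip is bit-exact.
#'
#' @param path file path.
#' @return `readGraphTSV`: list with elements `graph` ([SpliceGraph-class])
#'   and `flow` ([Flow-class]).
#' @examples
#' w <- wGraphFixture()
#' tf <- tempfile(fileext = ".tsv")
#' writeGraphTSV(w$graph, w$flow, tf)
#' rt <- readGraphTSV(tf)
#' identical(flowValues(rt$flow), flowValues(w$flow))
#' @export
readGraphTSV <- function(path) {
  lines <- readLines(path)
  src <- sub("^#source\\s+", "", grep("^#source\\s", lines, value = TRUE)[1L])
  snk <- sub("^#sink\\s+", "", grep("^#sink\\s", lines, value = TRUE)[1L])
  if (is.na(src) || is.na(snk)) {
    stop("graph file must carry '#source' and '#sink' header lines")
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(list(graph = SpliceGraph(NULL, source = src, sink = snk),
                flow = Flow(stats::setNames(numeric(0), character(0)))))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop("malformed edge line(s): ", paste(bad, collapse = ", "))
  }
  m <- do.call(rbind, parts)
  edges <- data.frame(id = m[, 1L], from = m[, 2L], to = m[, 3L],
                      stringsAsFactors = FALSE)
  f <- as.numeric(m[, 4L])
  graph <- SpliceGraph(edges, source = src, sink = snk)
  list(graph = graph, flow = Flow(stats::setNames(f, edges$id)))
}

#' @rdname readGraphTSV
#' @param graph a [SpliceGraph-class].
#' @param flow a [Flow-class] on the graph's edges.
#' @return `writeGraphTSV`: the path, invisibly.
#' @export
writeGraphTSV <- function(graph, flow, path) {
  f <- .flow_vector(graph, flow)
  lines <- c(paste("#source", graph@source),
             paste("#sink", graph@sink),
             sprintf("%s\t%s\t%s\t%s", graph@edges$id, graph@edges$from,
                     graph@edges$to, sprintf("%.17g", f)))
  writeLines(lines, path)
  invisible(path)
}
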