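#' @import methods
NULL

#' SpliceGraph: a directed acyclic graph of (partial) exons
#'
#' A splice graph is a DAG with a distinguished source `S` (transcript
#' starts) and sink `T` (transcript ends); every other vertex is a (partial)
#' exon and every edge a splice junction. Transcripts are S-T paths.
#' Auxiliary graphs built during subgraph quantification may carry a
#' redirected sink (conventionally named `"T_prime"`); redirected edges keep
#' their original edge id and remember their original destination in the
#' `label` column, so parallel edges into the auxiliary sink are permitted.
#'
#' Vertex and edge ids are opaque strings. Structural basics (unique edge
#' ids, endpoints drawn from the vertex set) are enforced on construction;
#' acyclicity is checked by [topologicalOrder()], which names a cycle witness
#' on failure, so that deliberately broken graphs can still be constructed
#' and diagnosed.
#'
#' @slot edges data.frame with columns `id`, `from`, `to`, `label`
#'   (character; `label` is `NA` except on redirected edges).
#' @slot source,sink single vertex ids.
#' @slot vertices character vector of all vertex ids.
#'
#' @seealso [SpliceGraph()] the constructor, [Flow-class], [topologicalOrder()]
#' @exportClass SpliceGraph
setClass("SpliceGraph",
  slots = c(
    edges    = "data.frame",
    source   = "character",
    sink     = "character",
    vertices = "character"
  )
)

setValidity("SpliceGraph", function(object) {
  e <- object@edges
  msgs <- character()
  need <- c("id", "from", "to", "label")
  if (!all(need %in% names(e))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(e$id)) msgs <- c(msgs, "edge ids must be unique")
  if (length(object@source) != 1L || length(object@sink) != 1L) {
    msgs <- c(msgs, "source and sink must be single vertex ids")
  }
  v <- object@vertices
  if (anyDuplicated(v)) msgs <- c(msgs, "vertex ids must be unique")
  if (!all(c(object@source, object@sink) %in% v)) {
    msgs <- c(msgs, "source and sink must be listed vertices")
  }
  if (nrow(e) && !all(c(e$from, e$to) %in% v)) {
    msgs <- c(msgs, "edge endpoints must be listed vertices")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpliceGraph
#'
#' @param edges data.frame with character columns `id`, `from`, `to` and
#'   optionally `label` (original destination of a redirected edge).
#' @param source,sink vertex ids of the virtual source and sink
#'   (defaults `"S"` and `"T"`).
#' @param vertices optional explicit vertex set; defaults to the union of
#'   edge endpoints plus source and sink. Supply it to keep isolated
#'   vertices.
#' @return A [SpliceGraph-class] object.
#' @examples
#' g <- SpliceGraph(data.frame(
#'   id = c("S->A", "A->T"), from = c("S", "A"), to = c("A", "T")))
#' topologicalOrder(g)
#' @export
SpliceGraph <- function(edges, source = "S", sink = "T", vertices = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(id = character(), from = character(),
                        to = character(), label = character(),
                        stringsAsFactors = FALSE)
  }
  edges$id <- as.character(edges$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$label)) edges$label <- NA_character_
  edges$label <- as.character(edges$label)
  edges <- edges[, c("id", "from", "to", "label")]
  rownames(edges) <- NULL
  if (is.null(vertices)) {
    vertices <- unique(c(source, edges$from, edges$to, sink))
  }
  new("SpliceGraph", edges = edges, source = as.character(source),
      sink = as.character(sink), vertices = as.character(vertices))
}

#' Flow: non-negative edge weights balanced at internal vertices
#'
#' A flow assigns each edge of a splice graph a weight (in abundance units,
#' e.g. fragments or normalised flow) that is non-negative and balanced at
#' every vertex except the source and sink. Construction only checks the
#' container (named, finite numeric values); the flow axioms are checked
#' against a graph by [validateFlow()], so that deliberately invalid flows
#' can be built and diagnosed.
#'
#' @slot values named numeric vector, names are edge ids.
#' @seealso [Flow()], [validateFlow()], [totalFlow()]
#' @exportClass Flow
setClass("Flow", slots = c(values = "numeric"))

setValidity("Flow", function(object) {
  v <- object@values
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
    return("flow values must be named by edge id")
  }
  if (anyDuplicated(names(v))) return("duplicate edge ids in flow")
  if (anyNA(v) || any(!is.finite(v))) return("flow values must be finite")
  TRUE
})

#' Construct a Flow
#' @param values named numeric vector of per-edge weights (names = edge ids).
#' @return A [Flow-class] object.
#' @examples
#' Flow(c("S->A" = 3, "A->T" = 3))
#' @export
Flow <- function(values) {
  new("Flow", values = values)
}

#' EdgeSetQuery: an ordered list of edge sets defining good paths
#'
#' An AND-Quant query is an ordered list of edge sets `E_1 ... E_m` with the
#' well-ordering property: no S-T path visits an edge of `E_i` and later an
#' edge of `E_j` with `i >= j`. An S-T path is *good* when it intersects
#' every set. Queries for full transcripts are lists of singletons, one per
#' path edge ([pathToQuery()]). Well-ordering is verified by
#' [checkWellOrdering()] against a concrete graph.
#'
#' Sets must be pairwise disjoint (enforced at construction). When one edge
#' belongs to two levels, "a path crossing every level" and "a path
#' intersecting every set" stop being the same predicate, and only the
#' former is computed by the linear-time labelling; disjoint sets — which is
#' what splicing-pattern cuts produce — make the two readings coincide.
#'
#' @slot sets list of character vectors of edge ids. Filtering may leave a
#'   set empty, which signals an infeasible query (no good path).
#' @seealso [EdgeSetQuery()], [andQuant()], [checkWellOrdering()]
#' @exportClass EdgeSetQuery
setClass("EdgeSetQuery", slots = c(sets = "list"))

setValidity("EdgeSetQuery", function(object) {
  if (!all(vapply(object@sets, is.character, logical(1)))) {
    return("each query set must be a character vector of edge ids")
  }
  all_ids <- unlist(object@sets)
  if (anyDuplicated(all_ids)) {
    return(paste0("query sets must be pairwise disjoint (duplicated: ",
                  paste(unique(all_ids[duplicated(all_ids)]),
                        collapse = ", "), ")"))
  }
  TRUE
})

#' Construct an EdgeSetQuery
#' @param sets list of character vectors of edge ids, in path order.
#' @return An [EdgeSetQuery-class] object.
#' @examples
#' EdgeSetQuery(list("S->A", c("M->C", "M->D")))
#' @export
EdgeSetQuery <- function(sets) {
  sets <- lapply(sets, as.character)
  new("EdgeSetQuery", sets = sets)
}

#' AbundanceRange: interval of abundance across co-optimal solutions
#'
#' The closed interval `[lo, hi]` of abundance values a transcript (or
#' splicing pattern) attains across all equally optimal solutions of a
#' quantification model, in the units of the input abundances. A width of
#' zero means the quantity is identifiable.
#'
#' @slot lo,hi non-negative reals with `lo <= hi` (up to solver tolerance).
#' @seealso [AbundanceRange()], [interpolateRange()], [overlapFraction()]
#' @exportClass AbundanceRange
setClass("AbundanceRange", slots = c(lo = "numeric", hi = "numeric"))

setValidity("AbundanceRange", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L) {
    return("lo and hi must be scalars")
  }
  if (!is.finite(object@lo) || !is.finite(object@hi)) {
    return("range endpoints must be finite")
  }
  if (object@lo < -1e-6) return("lo must be non-negative")
  if (object@lo > object@hi + 1e-6) return("lo must not exceed hi")
  TRUE
})

#' Construct an AbundanceRange
#' @param lo,hi interval endpoints, `0 <= lo <= hi` (solver noise up to
#'   `1e-6` is tolerated and clamped).
#' @return An [AbundanceRange-class] object.
#' @examples
#' AbundanceRange(0, 3)
#' @export
AbundanceRange <- function(lo, hi) {
  lo <- max(0, as.numeric(lo))
  hi <- max(lo, as.numeric(hi))
  new("AbundanceRange", lo = lo, hi = hi)
}

#' Decomposition: a weighted set of S-T paths realizing a flow
#'
#' A (full) decomposition expresses a flow as weighted S-T paths: for every
#' edge the weights of the paths through it sum to the edge flow. Witness
#' decompositions returned by [witnessDecomposition()] additionally achieve
#' an OR-Quant endpoint with their good flow.
#'
#' @slot paths list of character vectors (edge-id sequences, each an S-T path).
#' @slot weights numeric vector of non-negative path weights.
#' @seealso [Decomposition()], [witnessDecomposition()], [goodFlow()]
#' @exportClass Decomposition
setClass("Decomposition", slots = c(paths = "list", weights = "numeric"))

setValidity("Decomposition", function(object) {
  if (length(object@paths) != length(object@weights)) {
    return("paths and weights must have equal length")
  }
  if (!all(vapply(object@paths, is.character, logical(1)))) {
    return("each path must be a character vector of edge ids")
  }
  if (any(object@weights < -1e-9)) return("weights must be non-negative")
  TRUE
})

#' Construct a Decomposition
#' @param paths list of edge-id sequences (each an S-T path).
#' @param weights numeric vector of path weights, one per path.
#' @return A [Decomposition-class] object.
#' @export
Decomposition <- function(paths = list(), weights = numeric()) {
  new("Decomposition", paths = lapply(paths, as.character),
      weights = as.numeric(weights))
}

## ---- accessors ----

#' @rdname SpliceGraph-class
#' @param x a SpliceGraph
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname SpliceGraph-class
#' @export
setMethod("graphEdges", "SpliceGraph", function(x) x@edges)

#' @rdname SpliceGraph-class
#' @export
setGeneric("graphVertices", function(x) standardGeneric("graphVertices"))
#' @rdname SpliceGraph-class
#' @export
setMethod("graphVertices", "SpliceGraph", function(x) x@vertices)

#' @rdname SpliceGraph-class
#' @export
setGeneric("graphSource", function(x) standardGeneric("graphSource"))
#' @rdname SpliceGraph-class
#' @export
setMethod("graphSource", "SpliceGraph", function(x) x@source)

#' @rdname SpliceGraph-class
#' @export
setGeneric("graphSink", function(x) standardGeneric("graphSink"))
#' @rdname SpliceGraph-class
#' @export
setMethod("graphSink", "SpliceGraph", function(x) x@sink)

#' @rdname Flow-class
#' @param x a Flow
#' @export
setGeneric("flowValues", function(x) standardGeneric("flowValues"))
#' @rdname Flow-class
#' @export
setMethod("flowValues", "Flow", function(x) x@values)

#' @rdname EdgeSetQuery-class
#' @param x an EdgeSetQuery
#' @export
setGeneric("querySets", function(x) standardGeneric("querySets"))
#' @rdname EdgeSetQuery-class
#' @export
setMethod("querySets", "EdgeSetQuery", function(x) x@sets)

#' @rdname AbundanceRange-class
#' @param x an AbundanceRange
#' @export
setGeneric("rangeLo", function(x) standardGeneric("rangeLo"))
#' @rdname AbundanceRange-class
#' @export
setMethod("rangeLo", "AbundanceRange", function(x) x@lo)

#' @rdname AbundanceRange-class
#' @export
setGeneric("rangeHi", function(x) standardGeneric("rangeHi"))
#' @rdname AbundanceRange-class
#' @export
setMethod("rangeHi", "AbundanceRange", function(x) x@hi)

#' @rdname AbundanceRange-class
#' @export
setGeneric("rangeWidth", function(x) standardGeneric("rangeWidth"))
#' @rdname AbundanceRange-class
#' @export
setMethod("rangeWidth", "AbundanceRange", function(x) x@hi - x@lo)

#' @rdname Decomposition-class
#' @param x a Decomposition
#' @export
setGeneric("decompPaths", function(x) standardGeneric("decompPaths"))
#' @rdname Decomposition-class
#' @export
setMethod("decompPaths", "Decomposition", function(x) x@paths)

#' @rdname Decomposition-class
#' @export
setGeneric("decompWeights", function(x) standardGeneric("decompWeights"))
#' @rdname Decomposition-class
#' @export
setMethod("decompWeights", "Decomposition", function(x) x@weights)

## ---- show methods ----

setMethod("show", "SpliceGraph", function(object) {
  cat(sprintf("SpliceGraph with %d vertices, %d edges (source '%s', sink '%s')\n",
              length(object@vertices), nrow(object@edges),
              object@source, object@sink))
  if (nrow(object@edges)) {
    head_n <- min(6L, nrow(object@edges))
    print(utils::head(object@edges, head_n))
    if (nrow(object@edges) > head_n) {
      cat(sprintf("... and %d more edges\n", nrow(object@edges) - head_n))
    }
  }
  invisible(NULL)
})

setMethod("show", "Flow", function(object) {
  cat(sprintf("Flow on %d edges, total weight range [%g, %g]\n",
              length(object@values),
              if (length(object@values)) min(object@values) else 0,
              if (length(object@values)) max(object@values) else 0))
  invisible(NULL)
})

setMethod("show", "EdgeSetQuery", function(object) {
  cat(sprintf("EdgeSetQuery with %d ordered set(s): %s\n",
              length(object@sets),
              paste(vapply(object@sets, function(s)
                paste0("{", paste(s, collapse = ","), "}"), character(1)),
                collapse = " -> ")))
  invisible(NULL)
})

setMethod("show", "AbundanceRange", function(object) {
  cat(sprintf("AbundanceRange [%g, %g] (width %g)\n",
              object@lo, object@hi, object@hi - object@lo))
  invisible(NULL)
})

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition with %d path(s), total weight %g\n",
              length(object@paths), sum(object@weights)))
  invisible(NULL)
})
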