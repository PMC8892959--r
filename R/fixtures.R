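## Synthetic instances and brute-force oracles: every algorithmic claim in
## the package is testable without downloading data.

#' The W-shaped worked example
#'
#' A 7-vertex splice graph (S, A, B, M, C, D, T) whose flow admits many
#' decompositions: 4 units enter through A, 6 through B, and after merging
#' at M, 3 leave through C and 7 through D. The abundance of the path
#' S-A-M-C-T is nonidentifiable with range `[0, 3]`.
#'
#' @return list with `graph` ([SpliceGraph-class]), `flow` ([Flow-class])
#'   and `paths` (the four S-T paths as edge-id vectors).
#' @examples
#' w <- wGraphFixture()
#' transcriptRangeGraph(w$graph, w$flow, w$paths$SAMCT)
#' @export
wGraphFixture <- function() {
  edges <- data.frame(
    id   = c("S->A", "S->B", "A->M", "B->M", "M->C", "M->D", "C->T", "D->T"),
    from = c("S", "S", "A", "B", "M", "M", "C", "D"),
    to   = c("A", "B", "M", "M", "C", "D", "T", "T"),
    stringsAsFactors = FALSE)
  graph <- SpliceGraph(edges)
  flow <- Flow(stats::setNames(c(4, 6, 4, 6, 3, 7, 3, 7), edges$id))
  paths <- list(
    SAMCT = c("S->A", "A->M", "M->C", "C->T"),
    SAMDT = c("S->A", "A->M", "M->D", "D->T"),
    SBMCT = c("S->B", "B->M", "M->C", "C->T"),
    SBMDT = c("S->B", "B->M", "M->D", "D->T"))
  list(graph = graph, flow = flow, paths = paths)
}

#' Random flow-carrying DAG with a known witness decomposition
#'
#' Builds a random DAG over a fixed topological order (vertex 1 is the
#' source, vertex n the sink), guarantees S-T connectivity (with retries at
#' low density), samples `nPaths` random S-T paths with positive weights,
#' and sets the flow to the per-edge sum of path weights. The flow is
#' decomposable by construction and the sampled paths are an exact witness.
#' Deterministic given `seed`.
#'
#' @param nVertices number of vertices including source and sink (>= 3).
#' @param edgeDensity probability of each forward edge.
#' @param nPaths number of witness paths.
#' @param maxWeight path weights are drawn uniformly from `[0.5, maxWeight]`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `graph`, `flow`, `witness` (a [Decomposition-class])
#'   and `seed`.
#' @examples
#' fx <- randomFlowDAG(seed = 7)
#' nrow(validateFlow(fx$graph, fx$flow))  # 0
#' @export
randomFlowDAG <- function(nVertices = 8, edgeDensity = 0.4, nPaths = 4,
                          maxWeight = 10, seed = NULL) {
  stopifnot(nVertices >= 3)
  if (!is.null(seed)) set.seed(seed)
  verts <- c("S", sprintf("V%02d", seq_len(max(0, nVertices - 2L)) + 1L), "T")
  n <- length(verts)
  graph <- NULL
  for (attempt in seq_len(100L)) {
    from <- character(0)
    to <- character(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1) < edgeDensity) {
          from <- c(from, verts[i])
          to <- c(to, verts[j])
        }
      }
    }
    if (!length(from)) next
    g <- SpliceGraph(data.frame(id = paste0(from, "->", to), from = from,
                                to = to, stringsAsFactors = FALSE),
                     vertices = verts)
    reaches_T <- .reachable_set(g, "T", forward = FALSE)
    if ("S" %in% reaches_T) {
      graph <- g
      break
    }
  }
  if (is.null(graph)) {
    stop("edge density too low to connect source to sink after 100 attempts")
  }
  reaches_T <- .reachable_set(graph, "T", forward = FALSE)
  out <- .out_edges(graph)
  sample_path <- function() {
    path <- character(0)
    cur <- "S"
    while (cur != "T") {
      cand <- out[[cur]]
      cand <- cand[graph@edges$to[cand] %in% reaches_T]
      e <- if (length(cand) == 1L) cand else sample(cand, 1L)
      path <- c(path, graph@edges$id[e])
      cur <- graph@edges$to[e]
    }
    path
  }
  paths <- lapply(seq_len(nPaths), function(i) sample_path())
  weights <- stats::runif(nPaths, 0.5, maxWeight)
  f <- stats::setNames(numeric(nrow(graph@edges)), graph@edges$id)
  for (k in seq_len(nPaths)) f[paths[[k]]] <- f[paths[[k]]] + weights[k]
  list(graph = graph, flow = Flow(f),
       witness = Decomposition(paths, weights), seed = seed)
}

#' Enumerate all S-T paths of a DAG
#'
#' Exhaustive, duplicate-free, deterministic (out-edges explored in
#' ascending edge-id order). Guarded against combinatorial explosion.
#'
#' @param graph a [SpliceGraph-class].
#' @param guard maximum number of paths (default `1e5`); exceeding it is an
#'   error suggesting a smaller instance.
#' @return list of edge-id vectors.
#' @examples
#' length(enumerateSTPaths(wGraphFixture()$graph))  # 4
#' @export
enumerateSTPaths <- function(graph, guard = 1e5) {
  reaches_T <- .reachable_set(graph, graph@sink, forward = FALSE)
  if (!(graph@source %in% reaches_T)) return(list())
  out <- .out_edges(graph)
  acc <- vector("list", 0L)
  walk <- function(v, prefix) {
    if (v == graph@sink) {
      if (length(acc) + 1L > guard) {
        stop("more than ", guard, " S-T paths; use a smaller instance")
      }
      acc[[length(acc) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    cand <- out[[v]]
    cand <- cand[graph@edges$to[cand] %in% reaches_T]
    for (e in cand[order(graph@edges$id[cand])]) {
      walk(graph@edges$to[e], c(prefix, graph@edges$id[e]))
    }
  }
  walk(graph@source, character(0))
  acc
}

#' Ground-truth range of good flow by LP over all paths
#'
#' Independent oracle for [orQuant()] and [andQuant()]: enumerates every
#' S-T path, introduces one non-negative weight per path, constrains the
#' per-edge weight sums to equal the flow, and minimises/maximises the
#' total weight of the paths satisfying `goodPredicate` with the internal
#' LP. Exact at test scale (path count below the enumeration guard).
#'
#' @inheritParams orQuant
#' @param goodPredicate function taking an edge-id vector and returning
#'   `TRUE` for good paths. For OR-sense use
#'   `function(p) any(p %in% eprime)`; for AND-sense
#'   `function(p) all(vapply(sets, function(s) any(p %in% s), logical(1)))`.
#' @param guard passed to [enumerateSTPaths()].
#' @return An [AbundanceRange-class].
#' @examples
#' w <- wGraphFixture()
#' oracleFlowRange(w$graph, w$flow,
#'                 function(p) any(p %in% c("S->A", "M->C")))  # [4, 7]
#' @export
oracleFlowRange <- function(graph, flow, goodPredicate, guard = 1e5) {
  U <- totalFlow(graph, flow)
  paths <- enumerateSTPaths(graph, guard)
  if (!length(paths)) {
    if (U > .EPS_LP) stop("internal error: positive flow but no S-T paths")
    return(AbundanceRange(0, 0))
  }
  A <- matrix(0, nrow = nrow(graph@edges), ncol = length(paths),
              dimnames = list(graph@edges$id, NULL))
  for (k in seq_along(paths)) A[paths[[k]], k] <- 1
  b <- .flow_vector(graph, flow)
  good <- vapply(paths, goodPredicate, logical(1))
  cvec <- as.numeric(good)
  lo <- .lp_solve(A, b, cvec, maximize = FALSE)
  hi <- .lp_solve(A, b, cvec, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop("internal error: oracle LP returned status ", lo$status, "/",
         hi$status)
  }
  AbundanceRange(min(max(lo$objective, 0), U),
                 min(max(hi$objective, 0), U))
}

#' Sample a random well-ordered query
#'
#' Samples a random S-T path, picks up to `maxSets` of its edges in path
#' order, and replaces each picked edge by a random subset of the
#' topological cut it crosses (all edges from before its head to at or
#' after it), always containing the path edge itself. Since an S-T path
#' crosses each topological cut exactly once and the cuts are visited in
#' order, any such list of subsets satisfies the well-ordering property by
#' construction; edges assigned to an earlier set are withheld from later
#' ones so the sets are pairwise disjoint.
#'
#' @param graph a [SpliceGraph-class] with at least one S-T path.
#' @param maxSets maximum number of query sets (default 3).
#' @return An [EdgeSetQuery-class].
#' @export
randomWellOrderedQuery <- function(graph, maxSets = 3) {
  pg <- .prune_to_st(graph)
  if (nrow(pg@edges) == 0L) stop("graph has no S-T path")
  topo <- topologicalOrder(pg)
  pos <- stats::setNames(seq_along(topo), topo)
  reaches_T <- .reachable_set(pg, pg@sink, forward = FALSE)
  out <- .out_edges(pg)
  path <- character(0)
  cur <- pg@source
  while (cur != pg@sink) {
    cand <- out[[cur]]
    cand <- cand[pg@edges$to[cand] %in% reaches_T]
    e <- if (length(cand) == 1L) cand else sample(cand, 1L)
    path <- c(path, pg@edges$id[e])
    cur <- pg@edges$to[e]
  }
  m <- sample.int(min(maxSets, length(path)), 1L)
  picked <- sort(sample.int(length(path), m))
  used <- path[picked]  # every set keeps its own path edge
  sets <- list()
  for (k in picked) {
    e <- path[k]
    cut_at <- pos[pg@edges$to[pg@edges$id == e]]
    crossing <- pg@edges$id[pos[pg@edges$from] < cut_at &
                            pos[pg@edges$to] >= cut_at]
    extra <- setdiff(crossing, used)
    keep <- extra[stats::runif(length(extra)) < 0.5]
    used <- c(used, keep)
    sets[[length(sets) + 1L]] <- c(e, keep)
  }
  EdgeSetQuery(sets)
}

#' Brute-force block graph from the reachability definition
#'
#' Independent oracle for [buildBlockGraph()]: filters each query set to
#' edges contained in at least one good S-T path (by exhaustive path
#' enumeration), then takes block `B_i` as the edges `(u, v)` with some
#' filtered end-vertex of level `i - 1` reaching `u` and `v` reaching some
#' filtered start-vertex of level `i` (with the virtual conventions
#' `V_0 = {S}`, `U_{m+1} = {T}`). The block graph is the union of the
#' blocks and the filtered query sets.
#'
#' @inheritParams checkWellOrdering
#' @param guard passed to [enumerateSTPaths()].
#' @return Character vector of the block-graph edge ids (sorted).
#' @export
bruteForceBlockGraph <- function(graph, query, guard = 1e5) {
  pg <- .prune_to_st(graph)
  sets <- query@sets
  m <- length(sets)
  paths <- enumerateSTPaths(pg, guard)
  good <- paths[vapply(paths, function(p)
    all(vapply(sets, function(s) any(p %in% s), logical(1))), logical(1))]
  if (!length(good)) return(character(0))
  fsets <- lapply(sets, function(s) {
    s[vapply(s, function(e) any(vapply(good, function(p) e %in% p,
                                       logical(1))), logical(1))]
  })
  em <- pg@edges
  reach <- .reachability(pg)
  Uset <- lapply(fsets, function(s) unique(em$from[em$id %in% s]))
  Vset <- lapply(fsets, function(s) unique(em$to[em$id %in% s]))
  V0 <- pg@source
  Um1 <- pg@sink
  Vlev <- c(list(V0), Vset)        # V_0 .. V_m
  Ulev <- c(Uset, list(Um1))       # U_1 .. U_{m+1}
  block <- character(0)
  for (i in seq_len(m + 1L)) {
    for (r in seq_len(nrow(em))) {
      u <- em$from[r]
      v <- em$to[r]
      from_ok <- any(vapply(Vlev[[i]], function(x) reach[x, u], logical(1)))
      to_ok <- any(vapply(Ulev[[i]], function(x) reach[v, x], logical(1)))
      if (from_ok && to_ok) block <- c(block, em$id[r])
    }
  }
  sort(unique(c(block, unlist(fsets))))
}

#' Synthetic multi-gene transcriptome with ground-truth abundances
#'
#' Per gene: a repertoire of alternative first exons (transcription start
#' choice), internal cassette exons (included or skipped) and alternative
#' last exons (termination choice). An isoform picks one first exon, a
#' subset of the cassettes and one last exon; all isoforms of a gene are
#' distinct. This is the splicing structure under which nonidentifiability
#' actually arises (two start choices and two end choices sharing internal
#' exons create co-optimal solutions, as in [wGraphFixture()]), unlike
#' pure cassette chains where almost every isoform owns a private
#' junction. Ground-truth abundances are drawn log-uniformly over
#' `[0.1, 1000]`; the gene's splice graph and the exact edge flow implied
#' by the abundances are returned. Roughly a third of genes are placed on
#' the minus strand. Also emits the quantifier-style table (columns Name,
#' Length, EffectiveLength, TPM, NumReads) and GTF-style exon records for
#' annotation round-trips. Deterministic given `seed`.
#'
#' No read-level simulation is attempted: the package consumes quantifier
#' output, so the fixture emulates that layer exactly, with junction
#' totals consistent with the truth by construction.
#'
#' @param nGenes number of genes.
#' @param isoformsPerGene isoforms per gene (>= 1; default 4, around the
#'   human average).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `genes` (per gene: `gene_id`, `graph`, `flow`,
#'   `transcripts` (list of [TranscriptModel-class]), `paths`,
#'   `abundances`), `quant` (data.frame in quantifier dialect) and
#'   `annotation` (data.frame of exon records).
#' @examples
#' fx <- syntheticTranscriptome(nGenes = 2, seed = 1)
#' names(fx$genes[[1]])
#' @export
syntheticTranscriptome <- function(nGenes = 10, isoformsPerGene = 4,
                                   seed = NULL) {
  stopifnot(nGenes >= 1, isoformsPerGene >= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- list()
  ann_rows <- list()
  quant_rows <- list()
  for (g in seq_len(nGenes)) {
    gene_id <- sprintf("G%03d", g)
    n_first <- sample(1:2, 1L)
    n_mid <- sample(2:4, 1L)
    n_last <- sample(1:2, 1L)
    n_ex <- n_first + n_mid + n_last
    firsts <- seq_len(n_first)
    mids <- n_first + seq_len(n_mid)
    lasts <- n_first + n_mid + seq_len(n_last)
    strand <- if (stats::runif(1) < 1 / 3) "-" else "+"
    ex_len <- sample(100:300, n_ex, replace = TRUE)
    base <- (g - 1L) * 100000L + 1000L
    ## exon index in transcription order; minus-strand genes run from
    ## high to low genomic coordinates
    coord_index <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    ex_start <- base + (coord_index - 1L) * 1000L
    ex_end <- ex_start + ex_len - 1L
    ## isoforms: one first exon + cassette subset + one last exon,
    ## all distinct
    iso <- list(c(firsts[1L], mids, lasts[1L]))
    tries <- 0L
    while (length(iso) < isoformsPerGene && tries < 200L) {
      tries <- tries + 1L
      ## isoform diversity is dominated by start/end choice: half the
      ## draws keep the full internal structure and differ only at the
      ## ends, the other half also toggle cassettes
      keep_mids <- if (stats::runif(1) < 0.5) mids else
        mids[stats::runif(n_mid) < 0.6]
      pick1 <- function(x) x[sample.int(length(x), 1L)]
      pick <- sort(c(pick1(firsts), pick1(lasts), keep_mids))
      if (!any(vapply(iso, identical, logical(1), y = pick))) {
        iso[[length(iso) + 1L]] <- pick
      }
    }
    abund <- 10^stats::runif(length(iso), -1, 3)
    ## splice graph: vertices S, E1..En, T; edges from isoform adjacencies
    vnames <- c("S", sprintf("E%d", seq_len(n_ex)), "T")
    from <- character(0)
    to <- character(0)
    paths <- list()
    tx_ids <- sprintf("%s.T%02d", gene_id, seq_along(iso))
    for (k in seq_along(iso)) {
      chain <- c("S", sprintf("E%d", iso[[k]]), "T")
      pf <- chain[-length(chain)]
      pt <- chain[-1L]
      from <- c(from, pf)
      to <- c(to, pt)
      paths[[tx_ids[k]]] <- paste0(pf, "->", pt)
    }
    eid <- paste0(from, "->", to)
    keep <- !duplicated(eid)
    graph <- SpliceGraph(data.frame(id = eid[keep], from = from[keep],
                                    to = to[keep], stringsAsFactors = FALSE),
                         vertices = vnames)
    f <- stats::setNames(numeric(sum(keep)), eid[keep])
    for (k in seq_along(iso)) f[paths[[k]]] <- f[paths[[k]]] + abund[k]
    transcripts <- lapply(seq_along(iso), function(k)
      TranscriptModel(tx_ids[k], gene_id, paths[[k]]))
    genes[[gene_id]] <- list(
      gene_id = gene_id, graph = graph, flow = Flow(f),
      transcripts = transcripts, paths = paths,
      abundances = stats::setNames(abund, tx_ids))
    for (k in seq_along(iso)) {
      sel <- iso[[k]]
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        gene_id = gene_id, transcript_id = tx_ids[k], seqnames = "chr1",
        start = ex_start[sel], end = ex_end[sel], strand = strand,
        stringsAsFactors = FALSE)
      quant_rows[[length(quant_rows) + 1L]] <- data.frame(
        Name = tx_ids[k], Length = sum(ex_len[sel]),
        EffectiveLength = max(sum(ex_len[sel]) - 200, 1),
        TPM = NA_real_, NumReads = abund[k], stringsAsFactors = FALSE)
    }
  }
  quant <- do.call(rbind, quant_rows)
  quant$TPM <- quant$NumReads / sum(quant$NumReads) * 1e6
  annotation <- do.call(rbind, ann_rows)
  rownames(quant) <- rownames(annotation) <- NULL
  list(genes = genes, quant = quant, annotation = annotation)
}
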