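## Complete-reference ranges of optima: phasing-path linear system and
## per-transcript min/max LPs.

#' TranscriptModel: a transcript as a junction path
#'
#' A transcript is identified by its ordered junction list (edge ids of its
#' gene's splice graph, forming a contiguous S-T path). Junction-free
#' (single-exon) transcripts carry an empty list; the linear system says
#' nothing about them and they are flagged rather than constrained.
#'
#' @slot id transcript id.
#' @slot gene gene id.
#' @slot junctions character vector of edge ids in path order.
#' @seealso [TranscriptModel()], [buildLinearSystem()]
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  slots = c(id = "character", gene = "character", junctions = "character"))

#' Construct a TranscriptModel
#' @param id transcript id.
#' @param gene gene id.
#' @param junctions ordered edge ids of the transcript's path.
#' @return A [TranscriptModel-class].
#' @export
TranscriptModel <- function(id, gene = "gene", junctions = character()) {
  new("TranscriptModel", id = as.character(id), gene = as.character(gene),
      junctions = as.character(junctions))
}

#' LinearSystem: phasing-path equality constraints on abundances
#'
#' One variable per transcript (its re-estimated abundance, `>= 0`) and one
#' equality constraint per phasing path: the total abundance of transcripts
#' containing the path in full must equal `g_i`, the value that total takes
#' at the supplied optimal abundances. Two quantifications satisfying every
#' constraint are indistinguishable under the generative model, so the
#' feasible polytope is exactly the set of co-optimal solutions.
#'
#' @slot membership 0/1 matrix, phasing paths x transcripts; entry 1 when
#'   the transcript contains the path as a contiguous junction subsequence.
#' @slot g right-hand sides, evaluated at the input optimum.
#' @slot transcript_ids,gene_ids column metadata.
#' @slot abundances the input optimal abundances (used for containment
#'   checks and reporting).
#' @seealso [buildLinearSystem()], [transcriptRangeLP()]
#' @exportClass LinearSystem
setClass("LinearSystem",
  slots = c(membership = "matrix", g = "numeric",
            transcript_ids = "character", gene_ids = "character",
            abundances = "numeric"))

setValidity("LinearSystem", function(object) {
  if (nrow(object@membership) != length(object@g)) {
    return("one g value per constraint row required")
  }
  if (ncol(object@membership) != length(object@transcript_ids)) {
    return("one column per transcript required")
  }
  TRUE
})

## is `sub` a contiguous subsequence of `full`?
.contig_contains <- function(full, sub) {
  nf <- length(full)
  ns <- length(sub)
  if (ns == 0L || ns > nf) return(FALSE)
  for (s in seq_len(nf - ns + 1L)) {
    if (all(full[s:(s + ns - 1L)] == sub)) return(TRUE)
  }
  FALSE
}

#' Build the phasing-path linear system
#'
#' Each phasing path (the ordered junctions co-occurring in one fragment)
#' contributes one equality: the total abundance of transcripts containing
#' it in full equals `g_i`, computed from the supplied optimal abundances.
#' Containment means the path's junction sequence appears as a contiguous
#' subsequence of the transcript's junction list. Duplicate phasing paths
#' are collapsed. A path contained in no transcript signals malformed input
#' and is an error.
#'
#' @param transcripts list of [TranscriptModel-class] objects (one gene).
#' @param abundances numeric vector of optimal abundances, parallel to
#'   `transcripts` (or named by transcript id).
#' @param phasingPaths list of character vectors of junction ids; default
#'   `NULL` uses all single junctions of the transcripts.
#' @return A [LinearSystem-class].
#' @examples
#' tr <- list(TranscriptModel("T1", "g", c("SA", "AM", "MC", "CT")),
#'            TranscriptModel("T2", "g", c("SA", "AM", "MD", "DT")),
#'            TranscriptModel("T3", "g", c("SB", "BM", "MC", "CT")),
#'            TranscriptModel("T4", "g", c("SB", "BM", "MD", "DT")))
#' sys <- buildLinearSystem(tr, c(3, 1, 0, 6))
#' transcriptRangeLP(sys, "T1")  # [0, 3]
#' @export
buildLinearSystem <- function(transcripts, abundances, phasingPaths = NULL) {
  ids <- vapply(transcripts, function(t) t@id, character(1))
  genes <- vapply(transcripts, function(t) t@gene, character(1))
  if (!is.null(names(abundances))) abundances <- abundances[ids]
  abundances <- as.numeric(abundances)
  if (length(abundances) != length(transcripts) || anyNA(abundances)) {
    stop("one abundance per transcript required")
  }
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (is.null(phasingPaths)) {
    phasingPaths <- lapply(
      unique(unlist(lapply(transcripts, function(t) t@junctions))), identity)
  }
  phasingPaths <- lapply(phasingPaths, as.character)
  keys <- vapply(phasingPaths, paste, character(1), collapse = "\r")
  phasingPaths <- phasingPaths[!duplicated(keys)]
  M <- matrix(0, nrow = length(phasingPaths), ncol = length(transcripts),
              dimnames = list(
                vapply(phasingPaths, paste, character(1), collapse = ","),
                ids))
  for (i in seq_along(phasingPaths)) {
    for (j in seq_along(transcripts)) {
      if (.contig_contains(transcripts[[j]]@junctions, phasingPaths[[i]])) {
        M[i, j] <- 1
      }
    }
  }
  orphan <- which(rowSums(M) == 0)
  if (length(orphan)) {
    stop("phasing path(s) contained in no transcript: ",
         paste(rownames(M)[orphan], collapse = "; "))
  }
  g <- as.vector(M %*% abundances)
  new("LinearSystem", membership = M, g = g, transcript_ids = ids,
      gene_ids = genes, abundances = abundances)
}

#' Min/max abundance of one transcript over all co-optimal solutions
#'
#' Solves the two LPs min and max of the transcript's variable subject to
#' the phasing-path equalities and non-negativity. Because the feasible set
#' is a polytope and the objective a coordinate, every value between the
#' extremes is attained by some co-optimal solution (the range is a true
#' interval; probe with [probeAbundance()]).
#'
#' @param system a [LinearSystem-class].
#' @param transcriptId transcript id (a column of the system).
#' @return An [AbundanceRange-class].
#' @export
transcriptRangeLP <- function(system, transcriptId) {
  j <- match(transcriptId, system@transcript_ids)
  if (is.na(j)) stop("unknown transcript id: ", transcriptId)
  if (length(system@g) == 0L) {
    stop("system has no constraints; transcript range is unbounded")
  }
  bounds <- .lp_bounds(system@membership, system@g, j)
  AbundanceRange(bounds[1L], bounds[2L])
}

#' Is a probe abundance attainable by a co-optimal solution?
#'
#' Adds the constraint `c'_j = value` to the system and reports phase-1
#' feasibility. Used to verify the interval property of
#' [transcriptRangeLP()].
#'
#' @inheritParams transcriptRangeLP
#' @param value probe abundance.
#' @return `TRUE` iff some co-optimal solution assigns `value` to the
#'   transcript.
#' @export
probeAbundance <- function(system, transcriptId, value) {
  j <- match(transcriptId, system@transcript_ids)
  if (is.na(j)) stop("unknown transcript id: ", transcriptId)
  if (value < 0) return(FALSE)
  extra <- matrix(0, 1L, ncol(system@membership))
  extra[1L, j] <- 1
  .lp_feasible(rbind(system@membership, extra), c(system@g, value))
}

#' Abundance ranges for all transcripts, grouped by gene
#'
#' Batch driver over [transcriptRangeLP()]: transcripts of different genes
#' are solved independently; a failure in one gene is recorded and does not
#' abort the others. Transcripts without junctions (single-exon) are not
#' constrained by junction evidence; they receive the range
#' `[0, sum of the gene's abundances]` with a warning and are marked
#' non-identifiable.
#'
#' @inheritParams buildLinearSystem
#' @param epsIdentifiable width below which a range counts as a point
#'   (default `1e-6`).
#' @return data.frame with columns `transcript_id`, `gene_id`, `abundance`,
#'   `lo`, `hi`, `identifiable` (0/1), plus attribute `"failed_genes"`
#'   naming genes whose LP failed.
#' @examples
#' tr <- list(TranscriptModel("T1", "g", c("SA", "AM", "MC", "CT")),
#'            TranscriptModel("T2", "g", c("SA", "AM", "MD", "DT")),
#'            TranscriptModel("T3", "g", c("SB", "BM", "MC", "CT")),
#'            TranscriptModel("T4", "g", c("SB", "BM", "MD", "DT")))
#' allRangesLP(tr, c(3, 1, 0, 6))
#' @export
allRangesLP <- function(transcripts, abundances, phasingPaths = NULL,
                        epsIdentifiable = .EPS_LP) {
  if (!length(transcripts)) {
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      abundance = numeric(), lo = numeric(), hi = numeric(),
                      identifiable = integer(), stringsAsFactors = FALSE)
    attr(out, "failed_genes") <- character(0)
    return(out)
  }
  ids <- vapply(transcripts, function(t) t@id, character(1))
  genes <- vapply(transcripts, function(t) t@gene, character(1))
  if (!is.null(names(abundances))) abundances <- abundances[ids]
  abundances <- as.numeric(abundances)
  rows <- list()
  failed <- character(0)
  for (g in unique(genes)) {
    sel <- which(genes == g)
    trg <- transcripts[sel]
    abg <- abundances[sel]
    has_junc <- vapply(trg, function(t) length(t@junctions) > 0L, logical(1))
    res <- try({
      tbl <- data.frame(transcript_id = ids[sel], gene_id = g,
                        abundance = abg, lo = NA_real_, hi = NA_real_,
                        identifiable = NA_integer_, stringsAsFactors = FALSE)
      if (any(!has_junc)) {
        warning("gene ", g, ": transcript(s) without junctions are ",
                "unconstrained by junction evidence; range set to ",
                "[0, total gene abundance]: ",
                paste(ids[sel][!has_junc], collapse = ", "))
        tbl$lo[!has_junc] <- 0
        tbl$hi[!has_junc] <- sum(abg)
        tbl$identifiable[!has_junc] <- 0L
      }
      if (any(has_junc)) {
        sys <- buildLinearSystem(trg[has_junc], abg[has_junc], phasingPaths)
        for (k in which(has_junc)) {
          r <- transcriptRangeLP(sys, ids[sel][k])
          tbl$lo[k] <- r@lo
          tbl$hi[k] <- r@hi
          tbl$identifiable[k] <-
            as.integer((r@hi - r@lo) <= epsIdentifiable)
        }
      }
      tbl
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failed <- c(failed, g)
    } else {
      rows[[g]] <- res
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      abundance = numeric(), lo = numeric(), hi = numeric(),
                      identifiable = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "failed_genes") <- failed
  out
}

#' Write / read the per-transcript range table
#'
#' TSV with columns `transcript_id`, `gene_id`, `abundance`, `lo`, `hi`,
#' `identifiable` (0/1).
#'
#' @param table a data.frame as returned by [allRangesLP()].
#' @param path file path.
#' @return `writeRangeTable`: the path invisibly; `readRangeTable`: the
#'   data.frame.
#' @export
writeRangeTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRangeTable
#' @export
readRangeTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
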