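## Annotation and quantification-table IO, and splice-graph construction
## from exon records.

#' Read exon records from a GTF annotation
#'
#' Tolerant wrapper around `rtracklayer::import()`: lines with fewer than
#' nine tab-separated fields are skipped and reported with their line
#' numbers before parsing, and exon features missing a `gene_id` or
#' `transcript_id` attribute are reported and dropped. Coordinates stay
#' 1-based inclusive, as in GTF.
#'
#' @param path GTF file path.
#' @return data.frame with columns `gene_id`, `transcript_id`, `seqnames`,
#'   `start`, `end`, `strand`, one row per exon; attribute
#'   `"skipped_lines"` lists the offending line numbers.
#' @export
readGTF <- function(path) {
  lines <- readLines(path)
  empty_out <- data.frame(gene_id = character(), transcript_id = character(),
                          seqnames = character(), start = integer(),
                          end = integer(), strand = character(),
                          stringsAsFactors = FALSE)
  is_comment <- startsWith(lines, "#") | !nzchar(lines)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  malformed <- which(!is_comment & nfield < 9L)
  if (length(malformed)) {
    warning("skipping malformed GTF line(s): ",
            paste(malformed, collapse = ", "))
  }
  keep <- lines[!is_comment & nfield >= 9L]
  if (!length(keep)) {
    attr(empty_out, "skipped_lines") <- malformed
    return(empty_out)
  }
  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(keep, tmp)
  gr <- rtracklayer::import(tmp, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  gene_id <- if ("gene_id" %in% names(md)) md$gene_id else
    rep(NA_character_, length(gr))
  tx_id <- if ("transcript_id" %in% names(md)) md$transcript_id else
    rep(NA_character_, length(gr))
  bad <- is.na(gene_id) | is.na(tx_id)
  if (any(bad)) {
    warning(sum(bad), " exon record(s) missing gene_id/transcript_id; dropped")
  }
  gr <- gr[!bad]
  out <- data.frame(
    gene_id = gene_id[!bad], transcript_id = tx_id[!bad],
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  attr(out, "skipped_lines") <- malformed
  out
}

#' Write exon records as GTF
#'
#' Counterpart of [readGTF()], used mainly to serialize
#' [syntheticTranscriptome()] fixtures.
#'
#' @param annotation data.frame with `gene_id`, `transcript_id`,
#'   `seqnames`, `start`, `end`, `strand` columns (one row per exon).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGTF <- function(annotation, path) {
  lines <- sprintf(
    '%s\tquantrange\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    annotation$seqnames, annotation$start, annotation$end,
    annotation$strand, annotation$gene_id, annotation$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene's splice graph from its exon records
#'
#' Vertices are partial exons: exons are split at every exon boundary
#' coordinate observed in the gene, so overlapping exons of different
#' transcripts share vertices on their common intervals. Edges are the
#' exon adjacencies observed within transcripts (both the splice junctions
#' and the within-exon continuations created by the splitting), plus a
#' virtual source edge into each transcript's first segment and a sink
#' edge out of its last. Minus-strand genes are traversed in transcription
#' order, so all paths run source-to-sink. Coordinates are handled
#' half-open internally and converted from GTF's 1-based inclusive at the
#' boundary.
#'
#' @param records data.frame of exon rows (as from [readGTF()]) for one
#'   gene.
#' @return list with `graph` ([SpliceGraph-class]) and `paths` (named list
#'   mapping each transcript id to its S-T path as an edge-id vector).
#' @examples
#' fx <- syntheticTranscriptome(nGenes = 1, seed = 3)
#' sg <- buildSpliceGraph(fx$annotation)
#' names(sg$paths)
#' @export
buildSpliceGraph <- function(records) {
  if (!nrow(records)) stop("no exon records supplied")
  strands <- unique(records$strand)
  if (length(strands) != 1L || !strands %in% c("+", "-")) {
    stop("gene '", records$gene_id[1L],
         "': transcripts must lie on one strand (found: ",
         paste(strands, collapse = ", "), ")")
  }
  minus <- strands == "-"
  ## half-open intervals; split at every boundary within the gene
  s0 <- records$start
  e0 <- records$end + 1L
  cuts <- sort(unique(c(s0, e0)))
  seg_start <- cuts[-length(cuts)]
  seg_end <- cuts[-1L]
  seg_id <- sprintf("%s:%d-%d", records$seqnames[1L], seg_start,
                    seg_end - 1L)
  segments_of_exon <- function(st, en) {
    idx <- which(seg_start >= st & seg_end <= en)
    idx[order(seg_start[idx])]
  }
  paths <- list()
  from <- character(0)
  to <- character(0)
  for (tx in unique(records$transcript_id)) {
    rows <- records[records$transcript_id == tx, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1L] <= rows$end[-nrow(rows)])) {
      stop("transcript '", tx, "': exons overlap")
    }
    segs <- unlist(lapply(seq_len(nrow(rows)), function(r)
      segments_of_exon(rows$start[r], rows$end[r] + 1L)))
    verts <- seg_id[segs]
    if (minus) verts <- rev(verts)  # transcription order
    chain <- c("S", verts, "T")
    pf <- chain[-length(chain)]
    pt <- chain[-1L]
    from <- c(from, pf)
    to <- c(to, pt)
    paths[[tx]] <- paste0(pf, "->", pt)
  }
  eid <- paste0(from, "->", to)
  keep <- !duplicated(eid)
  graph <- SpliceGraph(data.frame(id = eid[keep], from = from[keep],
                                  to = to[keep], stringsAsFactors = FALSE))
  ## sanity: the transcript -> path map must be injective
  keys <- vapply(paths, paste, character(1), collapse = "|")
  if (anyDuplicated(keys)) {
    warning("gene '", records$gene_id[1L],
            "': transcripts with identical splice structure share a path: ",
            paste(names(paths)[duplicated(keys) |
                               duplicated(keys, fromLast = TRUE)],
                  collapse = ", "))
  }
  list(graph = graph, paths = paths)
}

#' Read a quantifier output table
#'
#' TSV with a header containing at least `Name` and one abundance column
#' (`TPM` and/or `NumReads`; extra columns are ignored). Rows with a
#' negative abundance are rejected and reported.
#'
#' @param path file path.
#' @param abundanceCol which column to use as abundance (default `"TPM"`).
#' @return data.frame with columns `Name` and `abundance`; attribute
#'   `"rejected"` holds the names of rejected rows.
#' @export
readQuantTable <- function(path, abundanceCol = "TPM") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"Name" %in% names(tab)) {
    stop("quantification table must have a 'Name' column; found: ",
         paste(names(tab), collapse = ", "))
  }
  if (!abundanceCol %in% names(tab)) {
    stop("abundance column '", abundanceCol, "' not found; available: ",
         paste(setdiff(names(tab), "Name"), collapse = ", "))
  }
  ab <- as.numeric(tab[[abundanceCol]])
  bad <- which(is.na(ab) | ab < 0)
  if (length(bad)) {
    warning("rejecting ", length(bad),
            " row(s) with negative or missing abundance: ",
            paste(utils::head(tab$Name[bad], 5L), collapse = ", "))
  }
  out <- data.frame(Name = tab$Name, abundance = ab,
                    stringsAsFactors = FALSE)[setdiff(seq_along(ab), bad), ,
                                              drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- tab$Name[bad]
  out
}

#' Write a quantifier-style table
#' @param quant data.frame with columns Name, Length, EffectiveLength, TPM,
#'   NumReads (as emitted by [syntheticTranscriptome()]).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeQuantTable <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Complete-reference ranges from annotation plus quantification
#'
#' End-to-end driver: read the GTF, build each gene's splice graph and
#' transcript paths, attach the abundances (transcripts absent from the
#' table are reported and given abundance 0), and run [allRangesLP()] with
#' single-junction phasing paths.
#'
#' @param gtf path to the annotation GTF.
#' @param quant path to the quantification table.
#' @param abundanceCol abundance column to use (default `"TPM"`).
#' @return The range table of [allRangesLP()].
#' @export
lpRangesFromFiles <- function(gtf, quant, abundanceCol = "TPM") {
  ann <- readGTF(gtf)
  if (!nrow(ann)) stop("annotation contains no exon records")
  qt <- readQuantTable(quant, abundanceCol)
  ab_lookup <- stats::setNames(qt$abundance, qt$Name)
  transcripts <- list()
  abundances <- numeric(0)
  for (g in unique(ann$gene_id)) {
    sg <- buildSpliceGraph(ann[ann$gene_id == g, , drop = FALSE])
    for (tx in names(sg$paths)) {
      transcripts[[length(transcripts) + 1L]] <-
        TranscriptModel(tx, g, sg$paths[[tx]])
      abundances <- c(abundances, ab_lookup[tx])
    }
  }
  missing <- vapply(transcripts, function(t) t@id, character(1))[
    is.na(abundances)]
  if (length(missing)) {
    warning(length(missing), " annotated transcript(s) absent from the ",
            "quantification table (abundance 0): ",
            paste(utils::head(missing, 5L), collapse = ", "))
    abundances[is.na(abundances)] <- 0
  }
  unknown <- setdiff(qt$Name, vapply(transcripts, function(t) t@id,
                                     character(1)))
  if (length(unknown)) {
    warning(length(unknown), " quantified transcript(s) not in the ",
            "annotation; ignored: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  allRangesLP(transcripts, abundances)
}
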