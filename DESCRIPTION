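Package: quantrange
Title: Ranges of Co-Optimal Transcript Abundance Estimates under Nonidentifiability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transcript expression quantification from RNA-seq is frequently
    nonidentifiable: many different abundance assignments explain the observed
    reads equally well. quantrange computes, for every transcript or splicing
    pattern, the closed interval of abundances attainable across all equally
    optimal solutions. Under a complete-reference assumption the interval is
    obtained by linear programming over phasing-path sufficient statistics;
    under an incomplete-reference (splice-graph flow) assumption it is obtained
    by max-flow reductions on auxiliary graphs (OR-Quant / AND-Quant with the
    block-graph construction); a lambda-interpolated hybrid connects the two.
    The intervals are used to flag inconclusive sibling-isoform expression
    rankings and questionable differential-expression calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Transcriptomics, RNASeq, AlternativeSplicing, DifferentialExpression, GraphAndNetwork
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
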