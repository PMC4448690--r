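#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   colData rowData
NULL

#' TranscriptSet: a set of spliced transcript models
#'
#' Container for transcript models: one exon chain per transcript (a
#' \code{GRangesList}, all exons of a transcript on one chromosome and
#' strand, sorted and non-overlapping) plus per-transcript metadata
#' (\code{biotype} in \{coding, noncoding\}, \code{source} tag, optional
#' \code{locus_id}).
#'
#' Transcription start and end sites are derived strand-aware: on the plus
#' strand the TSS is the first exon start, on the minus strand the last exon
#' end (positions reported in 1-based genomic coordinates).
#'
#' @slot exons GRangesList of exon chains, names are transcript ids.
#' @slot txData DataFrame with one row per transcript: \code{transcript_id},
#'   \code{biotype}, \code{source}, \code{locus_id}.
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(exons = "CompressedGRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData must have the same length")
  if (length(ex) == 0L) return(TRUE)
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("transcript ids must be unique, non-NULL names on the exon list")
  if (!identical(names(ex), as.character(td$transcript_id)))
    return("txData rows must align with exon list names")
  nchr <- lengths(unique(GenomicRanges::seqnames(ex)))
  nstr <- lengths(unique(GenomicRanges::strand(ex)))
  if (any(nchr != 1L) || any(nstr != 1L))
    return("each transcript must lie on a single chromosome and strand")
  str1 <- as.character(unlist(unique(GenomicRanges::strand(ex)), use.names = FALSE))
  if (any(!str1 %in% c("+", "-")))
    return("transcript strand must be '+' or '-'")
  # sorted, non-overlapping exon chains (vectorized over adjacent pairs)
  st <- unlist(GenomicRanges::start(ex), use.names = FALSE)
  en <- unlist(GenomicRanges::end(ex), use.names = FALSE)
  nper <- lengths(ex)
  if (any(nper > 1L)) {
    first_of_tx <- rep.int(seq_along(ex), nper) !=
                   c(0L, rep.int(seq_along(ex), nper)[-length(st)])
    bad <- !first_of_tx & st <= c(0L, en[-length(en)])
    if (any(bad))
      return("exon chains must be sorted in genome order and non-overlapping")
  }
  if (!all(c("transcript_id", "biotype", "source") %in% colnames(td)))
    return("txData must contain transcript_id, biotype, source")
  if (any(!td$biotype %in% c("coding", "noncoding")))
    return("biotype must be 'coding' or 'noncoding'")
  TRUE
})

#' CoverageTrack: genome-wide read density with a library size
#'
#' Wraps a per-chromosome run-length encoded density vector (as produced by
#' \code{GenomicRanges::coverage} or read from a bedGraph) together with the
#' total number of mapped reads used for RPM normalization.
#'
#' @slot cov RleList of per-base densities, one element per chromosome.
#' @slot totalReads total mapped reads of the library (numeric scalar).
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(cov = "SimpleRleList", totalReads = "numeric"))

setValidity("CoverageTrack", function(object) {
  if (length(object@totalReads) != 1L || !is.finite(object@totalReads) ||
      object@totalReads <= 0)
    return("totalReads must be a single positive number")
  if (any(vapply(object@cov, function(r) any(S4Vectors::runValue(r) < 0),
                 logical(1))))
    return("coverage densities must be non-negative")
  TRUE
})

#' PolysomeExperiment: polysome-fraction array intensities
#'
#' A \code{SummarizedExperiment} whose columns are microarray hybridizations
#' labelled by \code{state} (stress/control), \code{pool} (Total, None, Low,
#' High — whole-cell RNA plus the untranslated, low-translated and
#' highly-translated sucrose-gradient pools) and \code{replicate}, and whose
#' rows are probes carrying \code{probe_id}, \code{transcript_id} and
#' \code{biotype}. The \code{"intensity"} assay holds linear-scale signal;
#' normalization adds a \code{"log2norm"} assay.
#'
#' @exportClass PolysomeExperiment
setClass("PolysomeExperiment", contains = "SummarizedExperiment")

setValidity("PolysomeExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("state", "pool", "replicate")
  if (!all(need %in% colnames(cd)))
    return("colData must contain state, pool, replicate")
  if (any(!cd$state %in% c("stress", "control")))
    return("state must be 'stress' or 'control'")
  if (any(!cd$pool %in% c("Total", "None", "Low", "High")))
    return("pool must be one of Total, None, Low, High")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("transcript_id", "biotype") %in% colnames(rd)))
    return("rowData must contain transcript_id and biotype")
  TRUE
})
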