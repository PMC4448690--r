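#' Construct a TranscriptSet
#'
#' @param exons named \code{GRangesList} of exon chains (names = transcript
#'   ids). Exons are sorted in genome order automatically.
#' @param biotype character vector (\code{"coding"}/\code{"noncoding"}),
#'   recycled.
#' @param source annotation source tag per transcript (e.g. \code{"RefSeq"},
#'   \code{"GENCODE"}, \code{"ENCODE"}, \code{"de-novo"}), recycled.
#' @param locus_id optional locus assignment per transcript.
#' @return A \code{\linkS4class{TranscriptSet}}.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   tx1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(101, 301), c(200, 400)), "+"))
#' TranscriptSet(ex, biotype = "noncoding", source = "de-novo")
#' @export
TranscriptSet <- function(exons, biotype = "noncoding", source = "de-novo",
                          locus_id = NA_character_) {
  if (!is(exons, "GRangesList")) exons <- GenomicRanges::GRangesList(exons)
  exons <- sort(exons)
  n <- length(exons)
  td <- S4Vectors::DataFrame(
    transcript_id = if (n) names(exons) else character(0),
    biotype = rep_len(as.character(biotype), n),
    source = rep_len(as.character(source), n),
    locus_id = rep_len(as.character(locus_id), n))
  new("TranscriptSet", exons = as(exons, "CompressedGRangesList"), txData = td)
}

#' @rdname TranscriptSet
#' @param object,x a TranscriptSet
#' @export
setGeneric("exonsBy", function(x) standardGeneric("exonsBy"))

#' @rdname TranscriptSet
#' @export
setMethod("exonsBy", "TranscriptSet", function(x) x@exons)

#' @rdname TranscriptSet
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))

#' @rdname TranscriptSet
#' @export
setMethod("txData", "TranscriptSet", function(x) x@txData)

#' @rdname TranscriptSet
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @rdname TranscriptSet
#' @export
setMethod("txIds", "TranscriptSet", function(x) names(x@exons))

setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@exons))
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' Strand-aware transcription start sites
#'
#' @param x a TranscriptSet
#' @return named integer vector of TSS genomic positions (1-based; for a
#'   plus-strand transcript the first exon start, for minus strand the last
#'   exon end).
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname tss
#' @export
setMethod("tss", "TranscriptSet", function(x) {
  plus <- txStrand(x) == "+"
  out <- ifelse(plus, min(GenomicRanges::start(x@exons)),
                max(GenomicRanges::end(x@exons)))
  names(out) <- txIds(x)
  out
})

#' Strand-aware transcription end sites
#' @param x a TranscriptSet
#' @return named integer vector of TES genomic positions (1-based).
#' @export
setGeneric("tes", function(x) standardGeneric("tes"))

#' @rdname tes
#' @export
setMethod("tes", "TranscriptSet", function(x) {
  plus <- txStrand(x) == "+"
  out <- ifelse(plus, max(GenomicRanges::end(x@exons)),
                min(GenomicRanges::start(x@exons)))
  names(out) <- txIds(x)
  out
})

#' @rdname TranscriptSet
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))

#' @rdname TranscriptSet
#' @export
setMethod("txStrand", "TranscriptSet", function(x) {
  u <- unique(GenomicRanges::strand(x@exons))
  s <- as.character(unlist(u, use.names = FALSE))
  names(s) <- txIds(x)
  s
})

#' Spliced (exonic) transcript length
#' @param x a TranscriptSet
#' @return named integer vector: sum of exon widths per transcript.
#' @export
setGeneric("splicedLength", function(x) standardGeneric("splicedLength"))

#' @rdname splicedLength
#' @export
setMethod("splicedLength", "TranscriptSet", function(x) {
  out <- sum(GenomicRanges::width(x@exons))
  names(out) <- txIds(x)
  out
})

#' Genomic span (TSS to TES footprint) of each transcript
#' @param x a TranscriptSet
#' @return a \code{GRanges}, one range per transcript, with mcols carried
#'   over from \code{txData}.
#' @export
setGeneric("txSpan", function(x) standardGeneric("txSpan"))

#' @rdname txSpan
#' @export
setMethod("txSpan", "TranscriptSet", function(x) {
  gr <- unlist(range(x@exons))
  S4Vectors::mcols(gr) <- x@txData
  gr
})

#' Flag transcripts qualifying as lncRNAs
#'
#' A transcript counts as a long noncoding RNA when its biotype is
#' noncoding and its spliced length exceeds 200 nt. Shorter noncoding
#' transcripts are retained in the model but flagged FALSE here: the 200 nt
#' bound is a classification gate, not a parsing gate.
#'
#' @param x a TranscriptSet
#' @return named logical vector.
#' @export
setGeneric("isLncrna", function(x) standardGeneric("isLncrna"))

#' @rdname isLncrna
#' @export
setMethod("isLncrna", "TranscriptSet", function(x) {
  out <- x@txData$biotype == "noncoding" & splicedLength(x) > 200L
  names(out) <- txIds(x)
  out
})

setMethod("show", "TranscriptSet", function(object) {
  n <- length(object)
  cat("TranscriptSet with", n, "transcripts\n")
  if (n) {
    bt <- table(object@txData$biotype)
    cat("  biotypes:", paste(names(bt), bt, sep = ":", collapse = "  "), "\n")
    cat("  sources: ", paste(sort(unique(object@txData$source)),
                             collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Intron chains of each transcript
#' @param x a TranscriptSet
#' @return \code{GRangesList} of introns (empty element for mono-exonic
#'   transcripts).
#' @export
setGeneric("intronsBy", function(x) standardGeneric("intronsBy"))

#' @rdname intronsBy
#' @export
setMethod("intronsBy", "TranscriptSet", function(x) {
  GenomicRanges::psetdiff(unlist(range(x@exons)), x@exons)
})
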