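#' Read transcript annotation from GTF or BED12
#'
#' Parses a transcript annotation into a \code{\linkS4class{TranscriptSet}}.
#' GTF input uses its native 1-based inclusive coordinates; BED12 input its
#' 0-based half-open block coordinates; both are mapped onto the package's
#' internal 1-based closed ranges so that writing back out in the same
#' dialect round-trips coordinates bit-exactly.
#'
#' @param path file path (GTF/GFF2 or BED12).
#' @param format \code{"auto"} (by extension), \code{"gtf"} or
#'   \code{"bed12"}.
#' @param biotype_rule either a function mapping the per-transcript metadata
#'   DataFrame to a \code{"coding"}/\code{"noncoding"} vector, or
#'   \code{NULL} for the default rule: a transcript is coding when any of
#'   its \code{gene_biotype}/\code{transcript_biotype}/\code{gene_type}
#'   attributes equals \code{"protein_coding"}; BED12 names are noncoding
#'   unless the rule says otherwise.
#' @param source_tag source label to record when the file does not carry one.
#' @return a \code{TranscriptSet}. Transcripts whose exons mix strands or
#'   chromosomes are rejected with a warning naming them.
#' @export
readAnnotation <- function(path, format = c("auto", "gtf", "bed12"),
                           biotype_rule = NULL, source_tag = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (!"transcript_id" %in% names(S4Vectors::mcols(gr)))
      stop("GTF records must carry a transcript_id attribute: ", path)
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path)
    ex <- split(GenomicRanges::granges(gr), gr$transcript_id)
    meta <- S4Vectors::mcols(gr)[!duplicated(gr$transcript_id), , drop = FALSE]
    meta <- meta[match(names(ex), meta$transcript_id), , drop = FALSE]
    src <- if (!is.null(source_tag)) source_tag
           else if ("source" %in% colnames(meta)) as.character(meta$source)
           else "de-novo"
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    if (is.null(bed$blocks))
      stop("BED input must be 12-column (blocked): ", path)
    ids <- bed$name
    if (is.null(ids) || anyDuplicated(ids))
      ids <- make.unique(if (is.null(ids)) rep("tx", length(bed)) else ids)
    ex <- rtracklayer::blocks(bed)
    names(ex) <- ids
    meta <- S4Vectors::DataFrame(transcript_id = ids)
    src <- if (!is.null(source_tag)) source_tag else "de-novo"
  }

  # reject transcripts with exons on mixed strands or chromosomes
  ok <- lengths(unique(GenomicRanges::seqnames(ex))) == 1L &
        lengths(unique(GenomicRanges::strand(ex))) == 1L
  one_strand <- as.character(unlist(unique(GenomicRanges::strand(ex[ok])),
                                    use.names = FALSE))
  ok[ok] <- one_strand %in% c("+", "-")
  if (any(!ok)) {
    warning("rejected ", sum(!ok), " transcript(s) with mixed or missing ",
            "strand/chromosome: ",
            paste(utils::head(names(ex)[!ok], 5L), collapse = ", "))
    ex <- ex[ok]
    meta <- meta[ok, , drop = FALSE]
    if (length(src) > 1L) src <- src[ok]
  }

  biotype <- if (is.function(biotype_rule)) {
    biotype_rule(meta)
  } else {
    cand <- intersect(c("gene_biotype", "transcript_biotype", "gene_type",
                        "transcript_type"), colnames(meta))
    coding <- rep(FALSE, length(ex))
    for (col in cand)
      coding <- coding | (!is.na(meta[[col]]) & meta[[col]] == "protein_coding")
    ifelse(coding, "coding", "noncoding")
  }
  TranscriptSet(ex, biotype = biotype, source = src)
}

#' Write a TranscriptSet as BED12 or GTF
#'
#' @param x a \code{TranscriptSet}.
#' @param path output file.
#' @param format \code{"bed12"} or \code{"gtf"}.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(x, path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") {
    bed <- rtracklayer::asBED(exonsBy(x))
    bed$name <- txIds(x)[match(bed$name, txIds(x))]
    rtracklayer::export(bed, path, format = "bed")
  } else {
    ex <- exonsBy(x)
    gr <- unlist(ex, use.names = FALSE)
    n <- lengths(ex)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source = rep(txData(x)$source, n),
      type = "exon",
      transcript_id = rep(txIds(x), n),
      gene_id = rep(ifelse(is.na(txData(x)$locus_id), txIds(x),
                           txData(x)$locus_id), n))
    rtracklayer::export(gr, path, format = "gtf")
  }
  invisible(path)
}
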