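#' Merge transcripts into gene loci by same-strand exonic overlap
#'
#' Transcripts sharing at least \code{min_overlap} bp of exon–exon overlap
#' on the same strand are grouped; the transitive closure of that relation
#' defines a gene locus. Transcripts with no overlap partner form singleton
#' loci. Locus ids are deterministic: the lexicographically smallest member
#' transcript id prefixed with \code{"locus:"}, so the partition is
#' invariant to input order.
#'
#' @param x a \code{TranscriptSet}.
#' @param min_overlap minimum exonic overlap in bp (default 1).
#' @return the same \code{TranscriptSet} with \code{locus_id} filled in.
#' @export
mergeLoci <- function(x, min_overlap = 1L) {
  n <- length(x)
  if (n == 0L) return(x)
  ex <- exonsBy(x)
  exu <- unlist(ex, use.names = FALSE)
  txi <- rep(seq_len(n), lengths(ex))
  hits <- GenomicRanges::findOverlaps(exu, exu,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = FALSE)
  # union-find over transcripts
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- txi[S4Vectors::queryHits(hits)]
  b <- txi[S4Vectors::subjectHits(hits)]
  keep <- a < b
  a <- a[keep]; b <- b[keep]
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  ids <- txIds(x)
  locus <- character(n)
  for (members in comp)
    locus[members] <- paste0("locus:", min(ids[members]))
  out <- x
  out@txData$locus_id <- locus
  methods::validObject(out)
  out
}

#' Per-locus summary spans
#'
#' @param x a \code{TranscriptSet} with \code{locus_id} assigned (see
#'   \code{\link{mergeLoci}}).
#' @return \code{GRanges} of locus spans with \code{locus_id},
#'   \code{n_transcripts} and \code{strand} carried in mcols.
#' @export
geneLoci <- function(x) {
  if (any(is.na(txData(x)$locus_id)))
    stop("locus_id not assigned; run mergeLoci() first")
  sp <- txSpan(x)
  spl <- split(GenomicRanges::granges(sp), txData(x)$locus_id)
  out <- unlist(range(spl))
  S4Vectors::mcols(out)$locus_id <- names(out)
  S4Vectors::mcols(out)$n_transcripts <- lengths(spl)[names(out)]
  out
}

#' Select the representative transcript of each locus
#'
#' The representative of a gene locus is the member transcript with the
#' highest RPKM in any experimental condition. Ties are broken first by
#' longer spliced length, then by lexicographic transcript id, so the
#' choice is deterministic across runs.
#'
#' @param x a \code{TranscriptSet} with \code{locus_id} assigned.
#' @param rpkm numeric matrix of per-condition RPKM values, rows named by
#'   transcript id (all members must be present), columns = conditions.
#' @return named character vector: representative transcript id per locus
#'   (names are locus ids).
#' @export
selectRepresentative <- function(x, rpkm) {
  ids <- txIds(x)
  if (!all(ids %in% rownames(rpkm)))
    stop("rpkm matrix is missing transcripts: ",
         paste(utils::head(setdiff(ids, rownames(rpkm)), 5L), collapse = ", "))
  loc <- txData(x)$locus_id
  if (any(is.na(loc))) stop("locus_id not assigned; run mergeLoci() first")
  maxr <- apply(rpkm[ids, , drop = FALSE], 1L, max)
  slen <- splicedLength(x)
  vapply(split(seq_along(ids), loc), function(members) {
    m <- maxr[members]
    cand <- members[m == max(m)]
    if (length(cand) > 1L) {
      l <- slen[cand]
      cand <- cand[l == max(l)]
    }
    ids[cand[order(ids[cand])[1L]]]
  }, character(1))
}
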