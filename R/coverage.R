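#' Construct a CoverageTrack
#'
#' @param cov an \code{RleList} of per-base densities, or a \code{GRanges}
#'   with a \code{score} column (piecewise-constant density, e.g. parsed
#'   bedGraph) in which case coverage is expanded internally.
#' @param total_reads total mapped reads for RPM normalization; when
#'   \code{NULL}, the summed density is used as a proxy.
#' @param seqlengths optional named chromosome lengths.
#' @return a \code{\linkS4class{CoverageTrack}}.
#' @export
CoverageTrack <- function(cov, total_reads = NULL, seqlengths = NULL) {
  if (is(cov, "GRanges")) {
    if (is.null(cov$score)) stop("GRanges coverage input needs a score column")
    if (!is.null(seqlengths))
      GenomeInfoDb::seqlengths(cov) <- seqlengths[GenomeInfoDb::seqlevels(cov)]
    cov <- GenomicRanges::coverage(cov, weight = "score")
  }
  cov <- methods::as(cov, "SimpleRleList")
  if (is.null(total_reads))
    total_reads <- sum(vapply(cov, function(r) sum(as.numeric(r)), numeric(1)))
  new("CoverageTrack", cov = cov, totalReads = as.numeric(total_reads))
}

#' @rdname CoverageTrack
#' @param x a CoverageTrack
#' @export
setGeneric("trackCoverage", function(x) standardGeneric("trackCoverage"))

#' @rdname CoverageTrack
#' @export
setMethod("trackCoverage", "CoverageTrack", function(x) x@cov)

#' @rdname CoverageTrack
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname CoverageTrack
#' @export
setMethod("totalReads", "CoverageTrack", function(x) x@totalReads)

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack over", length(object@cov), "chromosome(s);",
      "total reads:", format(object@totalReads, big.mark = ","), "\n")
  invisible(NULL)
})

#' Read a bedGraph file into a CoverageTrack
#'
#' @param path bedGraph file (4 columns, 0-based half-open intervals).
#' @param total_reads library size; defaults to the summed density.
#' @return a \code{CoverageTrack}.
#' @export
readBedGraph <- function(path, total_reads = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  CoverageTrack(gr, total_reads = total_reads)
}

#' Write a CoverageTrack as bedGraph
#' @param x a \code{CoverageTrack}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(x, path) {
  gr <- GenomicRanges::GRanges(trackCoverage(x))
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# mean density over [from, to] (1-based closed), zero-padded beyond ends
.meanCov <- function(rle, from, to) {
  n <- length(rle)
  lo <- max(1L, from); hi <- min(n, to)
  if (hi < lo) return(0)
  s <- sum(as.numeric(rle[lo:hi]))
  s / (to - from + 1)
}

#' PolII traveling ratio per gene
#'
#' The traveling ratio (stalling index) compares PolII density at the
#' promoter with density over the gene body: the promoter window spans
#' \code{promoter_window} bp around the TSS (default \code{c(-30, 300)},
#' oriented by strand, so a minus-strand gene is mirrored) and the body is
#' the remainder of the gene, from the downstream edge of the promoter
#' window to the TES. \code{tr = promoter_density / body_density}, each a
#' per-bp mean. Genes shorter than \code{min_length} or with zero body
#' density get \code{NA} with a reason.
#'
#' @param genes a \code{TranscriptSet}.
#' @param track a \code{CoverageTrack}.
#' @param promoter_window integer pair, bp relative to TSS (strand-aware).
#' @param min_length minimum genomic gene length in bp (default 600).
#' @param mode \code{"density"}: per-bp mean density ratio (default);
#'   \code{"counts"}: ratio of summed signal.
#' @return data.frame (gene_id, promoter_density, body_density, tr,
#'   reason for NA rows).
#' @export
travelingRatio <- function(genes, track, promoter_window = c(-30L, 300L),
                           min_length = 600L,
                           mode = c("density", "counts")) {
  mode <- match.arg(mode)
  cov <- trackCoverage(track)
  ids <- txIds(genes)
  sp <- txSpan(genes)
  chrom <- as.character(GenomicRanges::seqnames(sp))
  gtss <- tss(genes); gtes <- tes(genes)
  str <- txStrand(genes)
  glen <- GenomicRanges::width(sp)
  winlen <- promoter_window[2] - promoter_window[1] + 1L
  out <- data.frame(gene_id = ids, promoter_density = NA_real_,
                    body_density = NA_real_, tr = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    if (!chrom[i] %in% names(cov)) { out$reason[i] <- "no_coverage"; next }
    if (glen[i] <= winlen) { out$reason[i] <- "too_short"; next }
    if (glen[i] < min_length) { out$reason[i] <- "below_min_length"; next }
    r <- cov[[chrom[i]]]
    if (str[i] == "+") {
      p1 <- gtss[i] + promoter_window[1]; p2 <- gtss[i] + promoter_window[2]
      b1 <- p2 + 1L; b2 <- gtes[i]
    } else {
      p1 <- gtss[i] - promoter_window[2]; p2 <- gtss[i] - promoter_window[1]
      b1 <- gtes[i]; b2 <- p1 - 1L
    }
    if (b2 < b1) { out$reason[i] <- "too_short"; next }
    pd <- .meanCov(r, p1, p2)
    bd <- .meanCov(r, b1, b2)
    if (mode == "counts") {
      pd <- pd * (p2 - p1 + 1); bd <- bd * (b2 - b1 + 1)
    }
    out$promoter_density[i] <- pd
    out$body_density[i] <- bd
    if (bd > 0) out$tr[i] <- pd / bd else out$reason[i] <- "zero_body"
  }
  out
}

#' Strand-aware average coverage metaprofile around anchors
#'
#' Extracts the RPM-normalized coverage in a symmetric window around each
#' anchor (e.g. TSSs), reverses minus-strand vectors so that downstream is
#' always to the right, and averages bin-wise across anchors. Windows
#' extending past chromosome ends are clipped (their out-of-range positions
#' are excluded from the bin means; the number of clipped anchors is
#' reported as an attribute).
#'
#' @param anchors data.frame with columns \code{chrom}, \code{pos} (1-based
#'   anchor position), \code{strand}.
#' @param track a \code{CoverageTrack}.
#' @param window_bp half-window in bp (profile covers ±\code{window_bp}).
#' @param bin_width bin width in bp (default 50).
#' @return data.frame (bin_center, mean_rpm) with attributes
#'   \code{n_anchors} and \code{n_clipped}.
#' @export
metaProfile <- function(anchors, track, window_bp = 3000L, bin_width = 50L) {
  stopifnot(nrow(anchors) > 0, window_bp %% bin_width == 0)
  cov <- trackCoverage(track)
  L <- 2L * window_bp
  nb <- L %/% bin_width
  acc <- matrix(0, nrow(anchors), L)
  valid <- matrix(FALSE, nrow(anchors), L)
  clipped <- 0L
  for (i in seq_len(nrow(anchors))) {
    ch <- as.character(anchors$chrom[i])
    if (!ch %in% names(cov)) { clipped <- clipped + 1L; next }
    r <- cov[[ch]]
    n <- length(r)
    from <- anchors$pos[i] - window_bp
    to <- anchors$pos[i] + window_bp - 1L
    lo <- max(1L, from); hi <- min(n, to)
    if (lo > from || hi < to) clipped <- clipped + 1L
    if (hi < lo) next
    v <- as.numeric(r[lo:hi])
    idx <- (lo - from + 1L):(hi - from + 1L)
    acc[i, idx] <- v
    valid[i, idx] <- TRUE
    if (anchors$strand[i] == "-") {
      acc[i, ] <- rev(acc[i, ])
      valid[i, ] <- rev(valid[i, ])
    }
  }
  rpm <- acc * 1e6 / totalReads(track)
  bin <- rep(seq_len(nb), each = bin_width)
  mean_rpm <- vapply(seq_len(nb), function(b) {
    cols <- which(bin == b)
    nv <- sum(valid[, cols, drop = FALSE])
    if (nv == 0L) return(0)
    sum(rpm[, cols, drop = FALSE][valid[, cols, drop = FALSE]]) / nv
  }, numeric(1))
  centers <- -window_bp + (seq_len(nb) - 0.5) * bin_width
  out <- data.frame(bin_center = centers, mean_rpm = mean_rpm)
  attr(out, "n_anchors") <- nrow(anchors)
  attr(out, "n_clipped") <- clipped
  out
}

#' Paired traveling-ratio shift between two conditions
#'
#' Joins two traveling-ratio tables on gene id, reports the median TR per
#' condition, the median per-gene TR ratio, and a two-sided rank-sum
#' p-value comparing the two TR distributions.
#'
#' @param tr_a,tr_b data.frames from \code{\link{travelingRatio}} (e.g.
#'   control and 30-min stress).
#' @return list with \code{n}, \code{median_tr_a}, \code{median_tr_b},
#'   \code{median_ratio} (b over a), \code{p_ranksum}.
#' @export
stallingShift <- function(tr_a, tr_b) {
  shared <- intersect(tr_a$gene_id[!is.na(tr_a$tr)],
                      tr_b$gene_id[!is.na(tr_b$tr)])
  if (length(shared) == 0L) stop("no shared genes with defined TR")
  a <- tr_a$tr[match(shared, tr_a$gene_id)]
  b <- tr_b$tr[match(shared, tr_b$gene_id)]
  list(n = length(shared),
       median_tr_a = stats::median(a),
       median_tr_b = stats::median(b),
       median_ratio = stats::median(b / a),
       p_ranksum = stats::wilcox.test(a, b, exact = FALSE)$p.value)
}
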