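#' Classification windows for positional lncRNA classes
#'
#' Window geometry used by \code{\link{classifyLncrna}}. The promoter
#' window is measured upstream of a coding gene's TSS along that gene's
#' strand axis, the terminal window downstream of its TES; a lncRNA whose
#' own TSS falls in \code{(inner, outer]} bp of the anchor belongs to the
#' class. \code{distal_min_gap_bp} records the gap beyond which a lncRNA is
#' considered distal (it also drives placement in the synthetic generator).
#'
#' @param promoter_inner,promoter_outer upstream window (bp), default (0, 5000].
#' @param terminal_inner,terminal_outer downstream window (bp), default (0, 5000].
#' @param distal_min_gap_bp minimum gap to any coding gene for the distal
#'   class (default 5000).
#' @return a named list of class \code{"ClassWindows"}.
#' @export
classWindows <- function(promoter_inner = 0L, promoter_outer = 5000L,
                         terminal_inner = 0L, terminal_outer = 5000L,
                         distal_min_gap_bp = 5000L) {
  stopifnot(promoter_inner < promoter_outer,
            terminal_inner < terminal_outer,
            promoter_outer > 0, terminal_outer > 0, distal_min_gap_bp > 0)
  structure(list(promoter_inner = as.integer(promoter_inner),
                 promoter_outer = as.integer(promoter_outer),
                 terminal_inner = as.integer(terminal_inner),
                 terminal_outer = as.integer(terminal_outer),
                 distal_min_gap_bp = as.integer(distal_min_gap_bp)),
            class = "ClassWindows")
}

#' Build the coding-gene index used by the classifier
#'
#' One span per coding gene (TSS to TES footprint of the representative
#' transcript / locus), with strand-aware TSS and TES in the metadata
#' columns. Nearest-gene queries break ties by smaller distance, then
#' lexicographic gene id.
#'
#' @param coding a \code{TranscriptSet} of coding genes (one transcript per
#'   gene; use representative transcripts).
#' @return \code{GRanges} with mcols \code{gene_id}, \code{gtss},
#'   \code{gtes}.
#' @export
buildGeneIndex <- function(coding) {
  if (length(coding) == 0L) stop("coding set must be non-empty")
  gr <- GenomicRanges::granges(txSpan(coding))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = txIds(coding), gtss = tss(coding), gtes = tes(coding))
  names(gr) <- txIds(coding)
  gr
}

# pick, per query, the candidate hit with the smallest `dist`, ties by
# lexicographically smallest gene id
.pickNearest <- function(qh, gene_id, dist) {
  ord <- order(qh, dist, gene_id)
  qh <- qh[ord]
  keep <- !duplicated(qh)
  list(q = qh[keep], gene = gene_id[ord][keep], dist = dist[ord][keep])
}

#' Classify lncRNAs by position relative to coding genes
#'
#' Each lncRNA receives exactly one of four positional classes, by
#' precedence: (1) \emph{overlapping} when its genomic span shares at least
#' one bp with a coding gene span (either strand); (2)
#' \emph{promoter_associated} when its TSS lies in the window upstream of a
#' coding TSS (measured on the coding gene's strand axis); (3)
#' \emph{terminal_associated} when its TSS lies in the window downstream of
#' a coding TES; (4) \emph{distal} otherwise. Orientation is concurrent
#' when lncRNA and partner share a strand, opposite when they do not; a
#' promoter-associated, opposite-strand lncRNA is a promoter-associated
#' antisense ncRNA (paancRNA). Signed distances are negative upstream of
#' the anchor (partner TSS for promoter class, partner TES for terminal,
#' partner TSS for overlapping).
#'
#' @param lnc a \code{TranscriptSet} of lncRNAs (spliced length > 200 nt;
#'   shorter/coding entries are dropped with a message).
#' @param index coding-gene index from \code{\link{buildGeneIndex}}.
#' @param windows a \code{\link{classWindows}} object.
#' @return data.frame with one row per lncRNA: \code{lnc_id}, \code{klass},
#'   \code{orientation}, \code{partner_gene_id}, \code{signed_distance_bp},
#'   \code{anchor}.
#' @export
classifyLncrna <- function(lnc, index, windows = classWindows()) {
  keep <- isLncrna(lnc)
  if (!all(keep)) {
    message("dropping ", sum(!keep),
            " transcript(s) not qualifying as lncRNA (biotype/length)")
    lnc <- lnc[which(keep)]
  }
  n <- length(lnc)
  ids <- txIds(lnc)
  span <- txSpan(lnc)
  ltss <- tss(lnc)
  lstr <- txStrand(lnc)
  gid <- index$gene_id
  gstr <- as.character(GenomicRanges::strand(index))
  gtss <- index$gtss
  gtes <- index$gtes

  off <- !(as.character(GenomicRanges::seqnames(span)) %in%
           as.character(GenomeInfoDb::seqlevels(index)))
  if (any(off))
    warning(sum(off), " lncRNA(s) on chromosomes absent from the gene ",
            "index; classified distal")
  # harmonize sequence levels so overlap queries stay silent
  lv <- union(GenomeInfoDb::seqlevels(span), GenomeInfoDb::seqlevels(index))
  GenomeInfoDb::seqlevels(span) <- lv
  GenomeInfoDb::seqlevels(index) <- lv

  klass <- rep("distal", n)
  partner <- rep(NA_character_, n)
  sdist <- rep(NA_real_, n)
  anchor <- rep("none", n)

  # (1) genomic span overlap, either strand; partner = largest overlap,
  # ties by smaller gene id
  ov <- GenomicRanges::findOverlaps(span, index, ignore.strand = TRUE)
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- pmin(GenomicRanges::end(span)[qh], GenomicRanges::end(index)[sh]) -
         pmax(GenomicRanges::start(span)[qh],
              GenomicRanges::start(index)[sh]) + 1L
    pick <- .pickNearest(qh, gid[sh], -w)  # largest overlap first
    klass[pick$q] <- "overlapping"
    partner[pick$q] <- pick$gene
    gi <- match(pick$gene, gid)
    sdist[pick$q] <- ifelse(gstr[gi] == "+",
                            ltss[pick$q] - gtss[gi], gtss[gi] - ltss[pick$q])
    anchor[pick$q] <- "partner_TSS"
  }

  tssPoints <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(span), IRanges::IRanges(ltss, width = 1L))
  GenomeInfoDb::seqlevels(tssPoints) <-
    union(GenomeInfoDb::seqlevels(tssPoints), GenomeInfoDb::seqlevels(index))

  # (2) promoter window upstream of a coding TSS
  pw <- windows
  promWin <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(index),
    IRanges::IRanges(
      start = ifelse(gstr == "+", gtss - pw$promoter_outer,
                     gtss + pw$promoter_inner + 1L),
      end = ifelse(gstr == "+", gtss - pw$promoter_inner - 1L,
                   gtss + pw$promoter_outer)))
  hv <- GenomicRanges::findOverlaps(tssPoints, promWin, ignore.strand = TRUE)
  if (length(hv)) {
    qh <- S4Vectors::queryHits(hv); sh <- S4Vectors::subjectHits(hv)
    free <- klass[qh] == "distal"
    qh <- qh[free]; sh <- sh[free]
    if (length(qh)) {
      d <- ifelse(gstr[sh] == "+", gtss[sh] - ltss[qh], ltss[qh] - gtss[sh])
      pick <- .pickNearest(qh, gid[sh], d)
      klass[pick$q] <- "promoter_associated"
      partner[pick$q] <- pick$gene
      sdist[pick$q] <- -pick$dist
      anchor[pick$q] <- "partner_TSS"
    }
  }

  # (3) terminal window downstream of a coding TES
  termWin <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(index),
    IRanges::IRanges(
      start = ifelse(gstr == "+", gtes + pw$terminal_inner + 1L,
                     gtes - pw$terminal_outer),
      end = ifelse(gstr == "+", gtes + pw$terminal_outer,
                   gtes - pw$terminal_inner - 1L)))
  hv <- GenomicRanges::findOverlaps(tssPoints, termWin, ignore.strand = TRUE)
  if (length(hv)) {
    qh <- S4Vectors::queryHits(hv); sh <- S4Vectors::subjectHits(hv)
    free <- klass[qh] == "distal"
    qh <- qh[free]; sh <- sh[free]
    if (length(qh)) {
      d <- ifelse(gstr[sh] == "+", ltss[qh] - gtes[sh], gtes[sh] - ltss[qh])
      pick <- .pickNearest(qh, gid[sh], d)
      klass[pick$q] <- "terminal_associated"
      partner[pick$q] <- pick$gene
      sdist[pick$q] <- pick$dist
      anchor[pick$q] <- "partner_TES"
    }
  }

  orientation <- ifelse(is.na(partner), "not_applicable",
                        ifelse(lstr == gstr[match(partner, gid)],
                               "concurrent", "opposite"))
  data.frame(lnc_id = ids, klass = klass, orientation = orientation,
             partner_gene_id = partner, signed_distance_bp = sdist,
             anchor = anchor, stringsAsFactors = FALSE)
}

#' Class-by-orientation table with percent up-regulated
#'
#' Counts lncRNAs per (class, orientation) cell and, when differential
#' calls are supplied, the percentage of each cell called up-regulated
#' (half-up, one decimal; \code{NA} for empty cells).
#'
#' @param assignments data.frame from \code{\link{classifyLncrna}}.
#' @param de_calls optional data.frame from \code{\link{callDifferential}}
#'   sharing feature ids with \code{assignments$lnc_id}.
#' @return data.frame (klass, orientation, n, pct_up).
#' @export
classTable <- function(assignments, de_calls = NULL) {
  lv_k <- c("distal", "overlapping", "terminal_associated",
            "promoter_associated")
  lv_o <- c("concurrent", "opposite", "not_applicable")
  cells <- expand.grid(klass = lv_k, orientation = lv_o,
                       stringsAsFactors = FALSE)
  # distal is orientation-free; oriented classes have no "not_applicable"
  cells <- cells[(cells$klass == "distal") ==
                 (cells$orientation == "not_applicable"), ]
  up <- NULL
  if (!is.null(de_calls))
    up <- de_calls$feature_id[de_calls$direction == "up"]
  key <- paste(assignments$klass, assignments$orientation)
  cells$n <- vapply(paste(cells$klass, cells$orientation),
                    function(k) sum(key == k), integer(1))
  cells$pct_up <- NA_real_
  if (!is.null(up)) {
    cells$pct_up <- vapply(paste(cells$klass, cells$orientation),
      function(k) {
        m <- key == k
        if (!any(m)) return(NA_real_)
        roundHalfUp(100 * mean(assignments$lnc_id[m] %in% up), 1L)
      }, numeric(1))
  }
  rownames(cells) <- NULL
  cells
}
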