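#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count * 1e9 / (length_nt * library_size)}: read count
#' normalized for feature length (kb) and sequencing depth (millions of
#' mapped reads). Vectorized over all three arguments.
#'
#' @param count non-negative read counts.
#' @param length_nt feature length in nucleotides (> 0).
#' @param library_size total mapped reads of the library (> 0).
#' @return numeric RPKM values.
#' @examples
#' computeRpkm(10, 1000, 1e7)  # 1
#' @export
computeRpkm <- function(count, length_nt, library_size) {
  if (any(length_nt <= 0)) stop("length_nt must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e9 / (as.numeric(length_nt) * as.numeric(library_size))
}

# half-up decimal rounding, used for all reported percentages
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fold change with a pseudocount guard
#'
#' Ratio of two RPKM values; when either side is exactly zero a pseudocount
#' (default 0.1 RPKM) is added to both before dividing, so fold changes
#' stay finite.
#' @param num,den numerator / denominator RPKM.
#' @param pseudocount value added to both sides when either is zero.
#' @return numeric linear fold change.
#' @export
foldChange <- function(num, den, pseudocount = 0.1) {
  zero <- num == 0 | den == 0
  out <- num / den
  out[zero] <- (num[zero] + pseudocount) / (den[zero] + pseudocount)
  out
}

#' Call differential expression for one feature set
#'
#' Implements the RPKM fold-change filter: a feature is up-regulated when
#' treated/control RPKM exceeds \code{fc_cut} AND the treated sample has
#' more than \code{min_reads} reads AND treated RPKM exceeds
#' \code{min_rpkm}. Down-regulation is the mirrored rule with the detection
#' filter applied to the control sample. Everything else is unchanged.
#'
#' @param feature_id feature identifiers (recycled checks apply).
#' @param treated_reads,treated_rpkm counts and RPKM in the treated sample.
#' @param control_reads,control_rpkm counts and RPKM in the control sample.
#' @param fc_cut linear fold-change cut-off (default 1.5).
#' @param min_reads read-count detection filter (default 10, strict >).
#' @param min_rpkm RPKM detection filter (default 1, strict >).
#' @param pseudocount see \code{\link{foldChange}}.
#' @return data.frame with \code{feature_id}, \code{fold_change},
#'   \code{treated_reads}, \code{treated_rpkm}, \code{detected} (treated
#'   sample passes both detection filters) and \code{direction}
#'   (\code{up}/\code{down}/\code{unchanged}).
#' @export
callDifferential <- function(feature_id, treated_reads, treated_rpkm,
                             control_reads, control_rpkm,
                             fc_cut = 1.5, min_reads = 10, min_rpkm = 1,
                             pseudocount = 0.1) {
  n <- length(feature_id)
  rec <- function(v) if (length(v) == 1L) rep_len(v, n) else v
  treated_reads <- rec(treated_reads); treated_rpkm <- rec(treated_rpkm)
  control_reads <- rec(control_reads); control_rpkm <- rec(control_rpkm)
  stopifnot(length(treated_reads) == n, length(treated_rpkm) == n,
            length(control_reads) == n, length(control_rpkm) == n)
  fc <- foldChange(treated_rpkm, control_rpkm, pseudocount)
  up <- fc > fc_cut & treated_reads > min_reads & treated_rpkm > min_rpkm
  down <- (1 / fc) > fc_cut & control_reads > min_reads &
          control_rpkm > min_rpkm
  direction <- rep("unchanged", n)
  direction[up] <- "up"
  direction[down & !up] <- "down"
  data.frame(
    feature_id = as.character(feature_id),
    fold_change = fc,
    treated_reads = treated_reads,
    treated_rpkm = treated_rpkm,
    detected = treated_reads > min_reads & treated_rpkm > min_rpkm,
    direction = direction,
    stringsAsFactors = FALSE)
}

#' Summarize a set of differential calls
#'
#' A feature is detected when it passes the read/RPKM gate (> min reads and
#' > min RPKM) in at least one treated sample; when calls from several
#' treated conditions are supplied for the same features, a feature counts
#' as up (or down) if any condition calls it so. Percentages are reported
#' half-up to one decimal.
#'
#' @param calls data.frame from \code{\link{callDifferential}} (several
#'   conditions may be row-bound).
#' @return list with \code{n_detected}, \code{n_up}, \code{n_down},
#'   \code{pct_up}, \code{pct_down} (percent of detected; \code{NA} when
#'   nothing is detected).
#' @export
summarizeDe <- function(calls) {
  agg <- function(v) tapply(v, calls$feature_id, any)
  det <- agg(calls$detected)
  up <- agg(calls$direction == "up" & calls$detected)
  down <- agg(calls$direction == "down" & calls$detected)
  n_det <- sum(det)
  n_up <- sum(up & det)
  n_down <- sum(down & det)
  list(
    n_detected = n_det, n_up = n_up, n_down = n_down,
    pct_up = if (n_det > 0) roundHalfUp(100 * n_up / n_det, 1L) else NA_real_,
    pct_down = if (n_det > 0) roundHalfUp(100 * n_down / n_det, 1L)
               else NA_real_)
}

#' Intron/exon fold-change quadrant analysis
#'
#' For each gene with intronic sequence, compares the stress-vs-control
#' fold change of exonic RPKM against that of intronic RPKM (reads pooled
#' over the concatenation of all introns). Quadrants follow the sign pair
#' of the log2 fold changes — I: both up; II: exonic down, intronic up;
#' III: both down; IV: exonic up, intronic down. A gene is altered when
#' either axis moves at least \code{fc_cut}-fold in either direction.
#'
#' @param gene_id gene identifiers.
#' @param exonic_treated,exonic_control exonic RPKM per gene.
#' @param intronic_treated,intronic_control pooled intronic RPKM per gene.
#' @param intron_length total intronic length per gene; genes with zero
#'   intronic length are excluded (reported in the \code{excluded}
#'   attribute).
#' @param fc_cut altered threshold (default 1.5).
#' @param pseudocount see \code{\link{foldChange}}.
#' @return data.frame (gene_id, exonic_fc, intronic_fc, quadrant, altered)
#'   with attribute \code{excluded} listing intron-less genes, plus
#'   \code{quadrant_counts}: altered genes per quadrant.
#' @export
intronExonQuadrants <- function(gene_id, exonic_treated, exonic_control,
                                intronic_treated, intronic_control,
                                intron_length, fc_cut = 1.5,
                                pseudocount = 0.1) {
  n <- length(gene_id)
  exonic_treated <- rep_len(exonic_treated, n)
  exonic_control <- rep_len(exonic_control, n)
  intronic_treated <- rep_len(intronic_treated, n)
  intronic_control <- rep_len(intronic_control, n)
  intron_length <- rep_len(intron_length, n)
  keep <- intron_length > 0
  excluded <- as.character(gene_id[!keep])
  g <- gene_id[keep]
  efc <- foldChange(exonic_treated[keep], exonic_control[keep], pseudocount)
  ifc <- foldChange(intronic_treated[keep], intronic_control[keep],
                    pseudocount)
  le <- log2(efc); li <- log2(ifc)
  quadrant <- ifelse(le >= 0 & li >= 0, "I",
              ifelse(le < 0 & li >= 0, "II",
              ifelse(le < 0 & li < 0, "III", "IV")))
  altered <- abs(le) >= log2(fc_cut) | abs(li) >= log2(fc_cut)
  out <- data.frame(gene_id = as.character(g), exonic_fc = efc,
                    intronic_fc = ifc, quadrant = quadrant,
                    altered = altered, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "quadrant_counts") <-
    table(factor(quadrant[altered], levels = c("I", "II", "III", "IV")))
  out
}

#' Compare gene structure of up- vs down-regulated genes
#'
#' Two-sided Mann–Whitney–Wilcoxon tests on genomic length and exon number
#' between two gene groups (typically the up- and down-regulated coding
#' genes); medians reported per group.
#'
#' @param up_ids,down_ids transcript ids of the two groups (non-empty).
#' @param x a \code{TranscriptSet} containing all of them.
#' @return list with \code{median_length_up/down},
#'   \code{median_exons_up/down}, \code{p_length}, \code{p_exons}.
#' @export
geneStructureCompare <- function(up_ids, down_ids, x) {
  if (length(up_ids) == 0L || length(down_ids) == 0L)
    stop("both groups must be non-empty")
  missing <- setdiff(c(up_ids, down_ids), txIds(x))
  if (length(missing))
    stop("unknown transcripts: ", paste(utils::head(missing, 5L),
                                        collapse = ", "))
  len <- GenomicRanges::width(txSpan(x))
  names(len) <- txIds(x)
  nex <- lengths(exonsBy(x))
  lu <- len[up_ids]; ld <- len[down_ids]
  eu <- nex[up_ids]; ed <- nex[down_ids]
  list(
    median_length_up = stats::median(lu),
    median_length_down = stats::median(ld),
    median_exons_up = stats::median(eu),
    median_exons_down = stats::median(ed),
    p_length = stats::wilcox.test(lu, ld, exact = FALSE)$p.value,
    p_exons = stats::wilcox.test(eu, ed, exact = FALSE)$p.value)
}

#' Count reads and RPKM over exonic and intronic parts of loci
#'
#' Convenience quantifier used by the simulation round trips: given per
#' feature counts (features named \code{<tx>} for exonic and
#' \code{<tx>:intron} for intronic sub-records), returns ExpressionRecord
#' style data.frames with RPKM.
#'
#' @param counts named integer vector of read counts.
#' @param length_nt named lengths (same names).
#' @param library_size scalar mapped-read total.
#' @return data.frame (feature_id, length_nt, count, rpkm).
#' @export
expressionRecords <- function(counts, length_nt, library_size) {
  stopifnot(identical(names(counts), names(length_nt)))
  data.frame(
    feature_id = names(counts),
    length_nt = as.integer(length_nt),
    count = as.integer(counts),
    rpkm = computeRpkm(counts, length_nt, library_size),
    stringsAsFactors = FALSE)
}
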