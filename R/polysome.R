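#' Construct a PolysomeExperiment
#'
#' @param intensity numeric matrix of linear-scale probe intensities
#'   (rows = probes, columns = samples).
#' @param sample_sheet data.frame with columns \code{sample} (matching
#'   column names), \code{state} (stress/control), \code{pool}
#'   (Total/None/Low/High), \code{replicate}.
#' @param probe_data data.frame with \code{probe_id}, \code{transcript_id},
#'   \code{biotype} (coding/noncoding), one row per probe; at most two
#'   probes target each transcript.
#' @return a \code{\linkS4class{PolysomeExperiment}} with an
#'   \code{"intensity"} assay.
#' @export
PolysomeExperiment <- function(intensity, sample_sheet, probe_data) {
  stopifnot(ncol(intensity) == nrow(sample_sheet),
            nrow(intensity) == nrow(probe_data))
  intensity <- as.matrix(intensity)
  colnames(intensity) <- sample_sheet$sample
  rownames(intensity) <- probe_data$probe_id
  cd <- S4Vectors::DataFrame(sample_sheet[, c("state", "pool", "replicate")],
                             row.names = sample_sheet$sample)
  rd <- S4Vectors::DataFrame(probe_data, row.names = probe_data$probe_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), colData = cd, rowData = rd)
  new("PolysomeExperiment", se)
}

#' Read a polysome intensity matrix and sample sheet from TSV files
#'
#' The matrix TSV has a \code{probe_id} first column then one column per
#' sample; the sample sheet TSV has columns \code{sample}, \code{state},
#' \code{pool}, \code{replicate}; probe annotation TSV has
#' \code{probe_id}, \code{transcript_id}, \code{biotype}.
#'
#' @param matrix_path,sheet_path,probes_path TSV file paths.
#' @return a \code{PolysomeExperiment}.
#' @export
readPolysomeMatrix <- function(matrix_path, sheet_path, probes_path) {
  m <- utils::read.delim(matrix_path, check.names = FALSE)
  sheet <- utils::read.delim(sheet_path)
  probes <- utils::read.delim(probes_path)
  ids <- m[[1L]]
  m <- as.matrix(m[, -1L, drop = FALSE])
  rownames(m) <- ids
  probes <- probes[match(ids, probes$probe_id), , drop = FALSE]
  sheet <- sheet[match(colnames(m), sheet$sample), , drop = FALSE]
  PolysomeExperiment(m, sheet, probes)
}

#' Background-correct, log2-transform and quantile-normalize array intensities
#'
#' Linear intensities are background-corrected (normexp by default, with a
#' fixed offset as in standard array practice; a simple subtract-and-floor
#' mode is available), floored at a small positive constant, log2
#' transformed, and quantile normalized so that all samples share an
#' identical sorted value multiset. Normalization is applied within each
#' analysis category (coding and noncoding probes separately), matching
#' the two-category analysis design.
#'
#' @param x a \code{PolysomeExperiment} with an \code{"intensity"} assay.
#' @param method \code{"normexp"} (default) or \code{"subtract"} (subtract
#'   the per-sample minimum; for tests) or \code{"none"}.
#' @param offset intensity offset added after background correction
#'   (default 50 for normexp, 0 otherwise).
#' @param floor minimum positive value imposed before log2 (default 1).
#' @param by_category quantile-normalize coding and noncoding probes
#'   separately (default TRUE).
#' @return the experiment with an added \code{"log2norm"} assay.
#' @export
normalizeArrays <- function(x, method = c("normexp", "subtract", "none"),
                            offset = NULL, floor = 1, by_category = TRUE) {
  method <- match.arg(method)
  m <- SummarizedExperiment::assay(x, "intensity")
  if (is.null(offset)) offset <- if (method == "normexp") 50 else 0
  corrected <- switch(method,
    normexp = limma::backgroundCorrect.matrix(m, method = "normexp",
                                              offset = offset,
                                              verbose = FALSE),
    subtract = sweep(m, 2L, apply(m, 2L, min)) + offset,
    none = m + offset)
  nlow <- sum(corrected < floor)
  if (nlow > 0) {
    message(nlow, " value(s) floored at ", floor, " before log2")
    corrected[corrected < floor] <- floor
  }
  lg <- log2(corrected)
  norm <- .quantileByCategory(lg,
    if (by_category) SummarizedExperiment::rowData(x)$biotype else NULL)
  dimnames(norm) <- dimnames(m)
  SummarizedExperiment::assay(x, "log2norm") <- norm
  x
}

.quantileByCategory <- function(lg, category = NULL) {
  if (is.null(category)) return(limma::normalizeQuantiles(lg))
  out <- lg
  for (ct in unique(category)) {
    rows <- category == ct
    out[rows, ] <- limma::normalizeQuantiles(lg[rows, , drop = FALSE])
  }
  out
}

#' Remove replicates that fail to cluster with their group
#'
#' Samples are clustered hierarchically (distance = 1 − Pearson
#' correlation of the normalized log2 values, average linkage). A
#' replicate is flagged anomalous when, at the given distance threshold,
#' it does not share a cluster with any sibling of its (state, pool)
#' group. Survivors are re-quantile-normalized.
#'
#' @param x a normalized \code{PolysomeExperiment}.
#' @param dist_threshold tree cut height (1 − r), default 0.2.
#' @return the experiment with anomalous replicates dropped and the
#'   \code{"log2norm"} assay recomputed; removed sample names in
#'   \code{metadata(x)$removed_replicates}. Groups with fewer than 3
#'   replicates are skipped with a warning; an abort occurs if removal
#'   would leave a group with fewer than 2 replicates.
#' @export
qcReplicates <- function(x, dist_threshold = 0.2) {
  m <- SummarizedExperiment::assay(x, "log2norm")
  cd <- SummarizedExperiment::colData(x)
  grp <- paste(cd$state, cd$pool, sep = ".")
  d <- stats::as.dist(1 - stats::cor(m, method = "pearson"))
  cl <- stats::cutree(stats::hclust(d, method = "average"),
                      h = dist_threshold)
  drop <- logical(ncol(m))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 3L) {
      warning("group ", g, " has <3 replicates; QC skipped for it")
      next
    }
    for (i in idx)
      drop[i] <- !any(cl[setdiff(idx, i)] == cl[i])
    if (sum(!drop[idx]) < 2L)
      stop("QC would leave <2 replicates in group ", g)
  }
  removed <- colnames(m)[drop]
  if (length(removed)) {
    x <- x[, !drop]
    lg <- SummarizedExperiment::assay(x, "log2norm")
    norm <- .quantileByCategory(lg, SummarizedExperiment::rowData(x)$biotype)
    dimnames(norm) <- dimnames(lg)
    SummarizedExperiment::assay(x, "log2norm") <- norm
  }
  S4Vectors::metadata(x)$removed_replicates <- removed
  x
}

#' Stress-vs-control contrasts per fraction pool
#'
#' Per-probe mean log2 differences stress − control for each pool
#' (RT/RN/RL/RH for Total/None/Low/High), plus a per-probe p-value for the
#' Total contrast (Welch two-sample t by default, pooled-variance
#' optionally).
#'
#' @param x a normalized \code{PolysomeExperiment}.
#' @param var \code{"welch"} (default) or \code{"pooled"}.
#' @return data.frame (probe_id, RT, RN, RL, RH, p_total); a pool missing
#'   in one state yields \code{NA} for its contrast.
#' @export
computeContrasts <- function(x, var = c("welch", "pooled")) {
  var <- match.arg(var)
  m <- SummarizedExperiment::assay(x, "log2norm")
  cd <- SummarizedExperiment::colData(x)
  contrastOf <- function(pool) {
    s <- cd$state == "stress" & cd$pool == pool
    c0 <- cd$state == "control" & cd$pool == pool
    if (!any(s) || !any(c0)) return(rep(NA_real_, nrow(m)))
    rowMeans(m[, s, drop = FALSE]) - rowMeans(m[, c0, drop = FALSE])
  }
  out <- data.frame(
    probe_id = rownames(m),
    RT = contrastOf("Total"), RN = contrastOf("None"),
    RL = contrastOf("Low"), RH = contrastOf("High"),
    stringsAsFactors = FALSE)
  s <- cd$state == "stress" & cd$pool == "Total"
  c0 <- cd$state == "control" & cd$pool == "Total"
  out$p_total <- if (sum(s) >= 2L && sum(c0) >= 2L) {
    .rowTTest(m[, s, drop = FALSE], m[, c0, drop = FALSE], var)
  } else NA_real_
  rownames(out) <- NULL
  out
}

# vectorized two-sample t-test p-values per row
.rowTTest <- function(a, b, var = "welch") {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  if (var == "welch") {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  tt <- (ma - mb) / sqrt(se2)
  2 * stats::pt(-abs(tt), df)
}

#' Transcriptional classification of probes
#'
#' Probes significant in the Total contrast (p below \code{p_cut}) are
#' classified by the whole-cell fold change: transcriptionally high when
#' the change is at least \code{fc_cut}-fold up, low when at least
#' \code{fc_cut}-fold down, no_change otherwise. Non-significant probes
#' are excluded (class \code{NA}). With the default log2 scale the cut is
#' applied as |log2 ratio| >= log2(fc_cut); \code{scale = "linear"}
#' applies it to signed linear fold changes instead.
#'
#' @param contrasts data.frame from \code{\link{computeContrasts}}.
#' @param p_cut significance threshold on the Total contrast (default 0.1).
#' @param fc_cut fold-change cut-off (default 1.5).
#' @param scale \code{"log2"} (default) or \code{"linear"} (signed
#'   Partek-style fold changes).
#' @return the input with an added \code{transcriptional_class} column
#'   (\code{"high"}/\code{"low"}/\code{"no_change"}/\code{NA}).
#' @export
classifyTranscription <- function(contrasts, p_cut = 0.1, fc_cut = 1.5,
                                  scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  rt <- contrasts$RT
  thr <- if (scale == "log2") log2(fc_cut) else NULL
  cls <- rep(NA_character_, nrow(contrasts))
  sig <- !is.na(contrasts$p_total) & contrasts$p_total < p_cut & !is.na(rt)
  if (scale == "log2") {
    cls[sig & rt >= thr] <- "high"
    cls[sig & rt <= -thr] <- "low"
    cls[sig & abs(rt) < thr] <- "no_change"
  } else {
    lin <- ifelse(rt >= 0, 2^rt, -2^(-rt))  # signed linear fold change
    cls[sig & lin >= fc_cut] <- "high"
    cls[sig & lin <= -fc_cut] <- "low"
    cls[sig & abs(lin) < fc_cut] <- "no_change"
  }
  contrasts$transcriptional_class <- cls
  contrasts
}

#' Detect translational shifts (the D-rule)
#'
#' For each probe the pairwise absolute differences between the fraction
#' contrasts are computed: \code{d1 = |RN - RL|}, \code{d2 = |RL - RH|},
#' \code{d3 = |RN - RH|}. A probe is translationally regulated when any of
#' them reaches \code{d_cut} (default 1, on the log2 scale of the
#' contrasts). Regulated probes get a trend: the fraction pool whose
#' stress/control ratio is highest, with deterministic tie priority
#' High > Low > None.
#'
#' @param contrasts data.frame with columns RN, RL, RH (e.g. from
#'   \code{\link{computeContrasts}}).
#' @param d_cut shift threshold (default 1; non-strict, >=).
#' @return the input with added columns d1, d2, d3,
#'   \code{translationally_regulated}, \code{trend}
#'   (\code{"None_pool"}/\code{"Low_pool"}/\code{"High_pool"} or \code{NA}
#'   for unregulated probes). Probes with any NA contrast get NA calls.
#' @export
detectTranslationalShift <- function(contrasts, d_cut = 1) {
  rn <- contrasts$RN; rl <- contrasts$RL; rh <- contrasts$RH
  ok <- !(is.na(rn) | is.na(rl) | is.na(rh))
  d1 <- abs(rn - rl); d2 <- abs(rl - rh); d3 <- abs(rn - rh)
  reg <- ifelse(ok, pmax(d1, d2, d3) >= d_cut, NA)
  trend <- rep(NA_character_, nrow(contrasts))
  idx <- which(ok & reg)
  if (length(idx)) {
    # argmax over (RN, RL, RH); ties resolved High > Low > None
    vals <- cbind(rh[idx], rl[idx], rn[idx])
    pick <- apply(vals, 1L, which.max)
    trend[idx] <- c("High_pool", "Low_pool", "None_pool")[pick]
  }
  contrasts$d1 <- d1; contrasts$d2 <- d2; contrasts$d3 <- d3
  contrasts$translationally_regulated <- reg
  contrasts$trend <- trend
  contrasts
}

#' Trend counts per transcriptional class and biotype
#'
#' Counts, among translationally regulated probes, the highest-ratio pool
#' per (transcriptional class x biotype) group — the trend cube behind the
#' final coding/non-coding shift summary.
#'
#' @param calls data.frame carrying \code{transcriptional_class},
#'   \code{trend}, \code{translationally_regulated}.
#' @param biotype character vector aligned with \code{calls} rows.
#' @return 3 x 2 x 3 integer array (class x biotype x trend).
#' @export
trendSummary <- function(calls, biotype) {
  stopifnot(length(biotype) == nrow(calls))
  keep <- !is.na(calls$translationally_regulated) &
          calls$translationally_regulated & !is.na(calls$transcriptional_class)
  table(
    class = factor(calls$transcriptional_class[keep],
                   levels = c("high", "low", "no_change")),
    biotype = factor(biotype[keep], levels = c("coding", "noncoding")),
    trend = factor(calls$trend[keep],
                   levels = c("None_pool", "Low_pool", "High_pool")))
}

#' Percent distribution of a transcript across fraction pools
#'
#' @param quantities non-negative pool quantities (named), not all zero.
#' @return percentages summing to 100.
#' @export
fractionEnrichment <- function(quantities) {
  if (any(quantities < 0)) stop("pool quantities must be non-negative")
  s <- sum(quantities)
  if (s == 0) stop("all pool quantities are zero; enrichment undefined")
  100 * quantities / s
}

#' Collapse probe-level calls to transcripts
#'
#' Median of each transcript's probe contrasts after normalization (at
#' most two probes target a transcript on the array design).
#'
#' @param contrasts data.frame with probe-level contrast columns.
#' @param transcript_id vector aligned with rows.
#' @return data.frame keyed by transcript with median RT/RN/RL/RH and the
#'   minimum p_total of its probes.
#' @export
collapseProbes <- function(contrasts, transcript_id) {
  stopifnot(length(transcript_id) == nrow(contrasts))
  med <- function(col) tapply(contrasts[[col]], transcript_id,
                              stats::median, na.rm = TRUE)
  out <- data.frame(
    transcript_id = names(med("RT")),
    RT = as.numeric(med("RT")), RN = as.numeric(med("RN")),
    RL = as.numeric(med("RL")), RH = as.numeric(med("RH")),
    p_total = as.numeric(tapply(contrasts$p_total, transcript_id, min,
                                na.rm = TRUE)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
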