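#' Find the longest open reading frame of a transcript sequence
#'
#' Scans the three sense-strand frames for spans starting with ATG and
#' ending at the first in-frame stop codon (TAA/TAG/TGA). The longest
#' qualifying ORF is returned; ties are broken by the 5'-most start.
#' Unterminated ATG...end-of-sequence runs do not qualify, so the result
#' is invariant to trailing sequence after the last stop.
#'
#' @param seq a character string or \code{Biostrings::DNAString} over
#'   A/C/G/T/N (transcript orientation, 5' to 3').
#' @param min_codons minimum ORF length in codons, start codon included,
#'   stop excluded (default 10).
#' @return list (frame 0/1/2, start_nt, end_nt — 1-based transcript
#'   coordinates of the ORF including its stop codon, length_codons,
#'   codons — character vector excluding the stop) or \code{NULL} when no
#'   ORF qualifies.
#' @examples
#' findLongestOrf("ATGAAATAA", min_codons = 2)
#' @export
findLongestOrf <- function(seq, min_codons = 10L) {
  s <- toupper(as.character(seq))
  if (nchar(s) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", s)) stop("sequence must be over A/C/G/T/N")
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 0:2) {
    ncod <- (nchar(s) - frame) %/% 3L
    if (ncod < 2L) next
    starts_at <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts_at, starts_at + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stops
    if (!any(is_start) || !any(is_stop)) next
    stop_idx <- which(is_stop)
    for (i in which(is_start)) {
      nxt <- stop_idx[stop_idx > i]
      if (!length(nxt)) next
      j <- nxt[1L]
      len <- j - i  # codons from ATG up to (not incl.) the stop
      if (len < min_codons) next
      if (is.null(best) || len > best$length_codons ||
          (len == best$length_codons && starts_at[i] < best$start_nt)) {
        best <- list(frame = frame,
                     start_nt = starts_at[i],
                     end_nt = starts_at[j] + 2L,
                     length_codons = len,
                     codons = codons[i:(j - 1L)])
      }
    }
  }
  best
}

#' Default human optimal-codon set
#'
#' One preferred (optimal) codon per degenerate amino acid, following
#' codon usage of highly expressed human genes; methionine and tryptophan
#' are non-degenerate and excluded from codon-bias arithmetic.
#'
#' @return named character vector: amino acid (one-letter) -> codon.
#' @export
humanOptimalCodons <- function() {
  c(F = "TTC", L = "CTG", I = "ATC", V = "GTG", S = "AGC", P = "CCC",
    T = "ACC", A = "GCC", Y = "TAC", H = "CAC", Q = "CAG", N = "AAC",
    K = "AAG", D = "GAC", E = "GAG", C = "TGC", R = "CGC", G = "GGC")
}

# standard genetic code: codon -> one-letter amino acid (stop = "*")
.geneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Coding bias index of an ORF
#'
#' Codon-usage statistic comparing observed optimal-codon usage to the
#' expectation under uniform synonymous usage:
#' \deqn{CBI = (N_{opt} - N_{rand}) / (N_{tot} - N_{rand})}
#' where \eqn{N_{opt}} counts codons that are optimal for their amino
#' acid, \eqn{N_{tot}} counts all codons at degenerate amino-acid
#' positions, and \eqn{N_{rand} = \sum_a n_a k_a / s_a} is the expected
#' optimal count when each amino acid \eqn{a} (occurring \eqn{n_a} times,
#' with \eqn{k_a} optimal of \eqn{s_a} synonymous codons) uses its
#' synonyms uniformly. CBI is 1 when every degenerate codon is optimal and
#' 0 when usage matches the uniform expectation.
#'
#' @param codons character vector of codons (e.g. from
#'   \code{\link{findLongestOrf}}; stop codons are ignored).
#' @param optimal named character vector amino acid -> optimal codon(s);
#'   default \code{\link{humanOptimalCodons}}. Amino acids absent from the
#'   set contribute no optimal codons but still count as degenerate.
#' @return CBI value, or \code{NA} when the ORF has no degenerate
#'   positions (N_tot == N_rand undefined denominator).
#' @export
computeCbi <- function(codons, optimal = humanOptimalCodons()) {
  if (length(codons) == 0L) stop("codon list must be non-empty")
  code <- .geneticCode()
  codons <- toupper(codons)
  aa <- code[codons]
  keep <- !is.na(aa) & aa != "*"
  codons <- codons[keep]; aa <- aa[keep]
  syn <- table(factor(code[code != "*"]))           # synonyms per aa
  degen_aa <- names(syn)[syn > 1L]
  deg <- aa %in% degen_aa
  n_tot <- sum(deg)
  opt_by_aa <- split(unname(optimal), names(optimal))
  k <- vapply(degen_aa, function(a) {
    length(intersect(opt_by_aa[[a]], names(code)[code == a]))
  }, numeric(1))
  n_aa <- table(factor(aa[deg], levels = degen_aa))
  n_rand <- sum(as.numeric(n_aa) * k / as.numeric(syn[degen_aa]))
  n_opt <- sum(vapply(which(deg), function(i) {
    codons[i] %in% opt_by_aa[[aa[i]]]
  }, logical(1)))
  if (n_tot == n_rand) return(NA_real_)
  (n_opt - n_rand) / (n_tot - n_rand)
}

#' Scan promoter sequences with a position weight matrix
#'
#' Scores every position of each sequence (both strands) with the
#' log-odds of the PWM against a uniform background, and counts
#' non-overlapping hits at or above the threshold (greedy left-to-right
#' across the merged strands).
#'
#' @param sequences named character vector or \code{DNAStringSet} of
#'   promoter sequences.
#' @param pwm 4 x L probability matrix, rows A, C, G, T, columns summing
#'   to 1 (a small regularization epsilon is added before log).
#' @param threshold log-odds score threshold for a hit.
#' @param eps probability floor guard (default 1e-4).
#' @return integer vector of hit counts, named by sequence.
#' @export
scanPwm <- function(sequences, pwm, threshold, eps = 1e-4) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (nrow(pwm) != 4L) stop("pwm must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    stop("pwm columns must sum to 1 (probabilities)")
  rownames(pwm) <- c("A", "C", "G", "T")
  lo <- log2((pwm + eps) / (0.25 + eps))
  L <- ncol(lo)
  scoreStrand <- function(s) {
    n <- nchar(s)
    if (n < L) return(numeric(0))
    chars <- strsplit(s, "")[[1L]]
    idx <- match(chars, c("A", "C", "G", "T"))  # N -> NA -> worst score
    npos <- n - L + 1L
    sc <- numeric(npos)
    for (j in seq_len(L)) {
      v <- lo[cbind(idx[j:(j + npos - 1L)], j)]
      v[is.na(v)] <- min(lo)
      sc <- sc + v
    }
    sc
  }
  vapply(seqs, function(s) {
    s <- toupper(s)
    if (grepl("[^ACGTN]", s)) stop("sequence alphabet must be A/C/G/T/N")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fw <- scoreStrand(s)
    rv <- scoreStrand(rc)
    n <- nchar(s)
    hits <- data.frame(
      start = c(which(fw >= threshold),
                n - ncol(lo) + 2L - which(rv >= threshold)))
    if (nrow(hits) == 0L) return(0L)
    hits <- hits[order(hits$start), , drop = FALSE]
    cnt <- 0L; lastEnd <- 0L
    for (st in hits$start) {
      if (st > lastEnd) { cnt <- cnt + 1L; lastEnd <- st + ncol(lo) - 1L }
    }
    cnt
  }, integer(1))
}

#' Parse a MEME minimal-format motif file into probability matrices
#'
#' @param path MEME minimal text file.
#' @return named list of 4 x L probability matrices (rows A, C, G, T).
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1L] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    m <- vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]]), numeric(4))
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
    out[[name]] <- m  # 4 x L, rows A C G T
  }
  out
}

#' Motif co-occurrence summary over a promoter universe
#'
#' For each motif: total hit count, number of promoters with at least one
#' hit, mean hits per hit-carrying promoter (half-up, 1 decimal) and the
#' percent of the promoter universe carrying a hit (half-up, 2 decimals);
#' plus the percent of the universe carrying all motifs simultaneously
#' (1 decimal).
#'
#' @param hits integer matrix promoters x motifs of hit counts.
#' @param universe_size total number of promoter regions analyzed
#'   (default: number of rows).
#' @return list with a per-motif data.frame \code{per_motif} (motif,
#'   total_hits, n_promoters_with_hit, mean_hits_per_hit_promoter,
#'   pct_of_universe) and \code{pct_all_motifs}.
#' @export
cooccurrenceSummary <- function(hits, universe_size = nrow(hits)) {
  hits <- as.matrix(hits)
  if (universe_size < max(colSums(hits > 0)))
    stop("universe_size smaller than the number of promoters with hits")
  total <- colSums(hits)
  n_with <- colSums(hits > 0)
  per_motif <- data.frame(
    motif = colnames(hits) %||% paste0("motif", seq_len(ncol(hits))),
    total_hits = as.integer(total),
    n_promoters_with_hit = as.integer(n_with),
    mean_hits_per_hit_promoter =
      ifelse(n_with > 0, roundHalfUp(total / n_with, 1L), NA_real_),
    pct_of_universe = roundHalfUp(100 * n_with / universe_size, 2L),
    stringsAsFactors = FALSE)
  n_all <- sum(rowSums(hits > 0) == ncol(hits))
  list(per_motif = per_motif,
       n_all_motifs = n_all,
       pct_all_motifs = roundHalfUp(100 * n_all / universe_size, 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
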