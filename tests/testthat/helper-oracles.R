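# Independent brute-force oracles used by the property and equivalence
# tests. These deliberately avoid the package's vectorized code paths:
# plain scalar arithmetic and exhaustive loops only.

# --- positional classification oracle -------------------------------------
# genes: data.frame(gene_id, start, end, strand) 1-based closed spans
# lnc:   data.frame(lnc_id, start, end, strand); TSS derived from strand
oracleClassify <- function(lnc, genes, promoter = c(0L, 5000L),
                           terminal = c(0L, 5000L)) {
  gtss <- ifelse(genes$strand == "+", genes$start, genes$end)
  gtes <- ifelse(genes$strand == "+", genes$end, genes$start)
  out <- data.frame(lnc_id = lnc$lnc_id, klass = NA_character_,
                    orientation = NA_character_,
                    partner_gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lnc))) {
    ltss <- if (lnc$strand[i] == "+") lnc$start[i] else lnc$end[i]
    best <- NULL
    # 1. overlap: largest overlap width, ties by smaller gene id
    for (j in order(genes$gene_id)) {
      ow <- min(lnc$end[i], genes$end[j]) - max(lnc$start[i], genes$start[j]) + 1L
      if (ow >= 1L && (is.null(best) || ow > best$w))
        best <- list(j = j, w = ow)
    }
    if (!is.null(best)) {
      out$klass[i] <- "overlapping"
      out$partner_gene_id[i] <- genes$gene_id[best$j]
    } else {
      # 2. promoter window upstream of a coding TSS, nearest wins
      bj <- NA; bd <- Inf
      for (j in order(genes$gene_id)) {
        d <- if (genes$strand[j] == "+") gtss[j] - ltss else ltss - gtss[j]
        if (d > promoter[1] && d <= promoter[2] && d < bd) { bj <- j; bd <- d }
      }
      if (!is.na(bj)) {
        out$klass[i] <- "promoter_associated"
        out$partner_gene_id[i] <- genes$gene_id[bj]
      } else {
        # 3. terminal window downstream of a coding TES
        bj <- NA; bd <- Inf
        for (j in order(genes$gene_id)) {
          d <- if (genes$strand[j] == "+") ltss - gtes[j] else gtes[j] - ltss
          if (d > terminal[1] && d <= terminal[2] && d < bd) { bj <- j; bd <- d }
        }
        if (!is.na(bj)) {
          out$klass[i] <- "terminal_associated"
          out$partner_gene_id[i] <- genes$gene_id[bj]
        } else {
          out$klass[i] <- "distal"
        }
      }
    }
    out$orientation[i] <- if (is.na(out$partner_gene_id[i])) "not_applicable"
      else if (lnc$strand[i] ==
               genes$strand[genes$gene_id == out$partner_gene_id[i]])
        "concurrent" else "opposite"
  }
  out
}

# random gene/lncRNA layout on one chromosome for equivalence testing
randomLayout <- function(n_genes = 8L, n_lnc = 6L, span = 200000L) {
  gs <- sort(sample.int(span - 12000L, n_genes))
  genes <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    start = gs,
    end = gs + sample(600:6000, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  ls <- sample.int(span - 3000L, n_lnc)
  lnc <- data.frame(
    lnc_id = sprintf("l%02d", seq_len(n_lnc)),
    start = ls,
    end = ls + sample(201:2500, n_lnc, replace = TRUE),
    strand = sample(c("+", "-"), n_lnc, replace = TRUE),
    stringsAsFactors = FALSE)
  list(genes = genes, lnc = lnc)
}

# convert layout data.frames into the package's containers
layoutToSets <- function(layout) {
  g <- layout$genes; l <- layout$lnc
  ggr <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(g$start, g$end), g$strand)
  gts <- TranscriptSet(split(ggr, factor(g$gene_id, levels = g$gene_id)),
                       biotype = "coding", source = "RefSeq")
  lgr <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(l$start, l$end), l$strand)
  lts <- TranscriptSet(split(lgr, factor(l$lnc_id, levels = l$lnc_id)),
                       biotype = "noncoding", source = "de-novo")
  list(coding = gts, lnc = lts)
}

# --- locus merge oracle: O(n^2) pairwise exon overlap + naive closure -----
# tx: list of data.frames, each with start/end (exons) plus strand per tx
oracleMergeLoci <- function(exon_list, strand) {
  n <- length(exon_list)
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b || strand[a] != strand[b]) next
    for (i in seq_len(nrow(exon_list[[a]]))) {
      for (j in seq_len(nrow(exon_list[[b]]))) {
        if (exon_list[[a]]$start[i] <= exon_list[[b]]$end[j] &&
            exon_list[[b]]$start[j] <= exon_list[[a]]$end[i]) {
          adj[a, b] <- TRUE
        }
      }
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (adj[a, b] && comp[b] != comp[a]) {
        m <- min(comp[a], comp[b])
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# --- naive traveling-ratio oracle on an explicit per-base vector ----------
oracleTR <- function(covVec, tss, tes, strand, win = c(-30L, 300L)) {
  at <- function(p) if (p >= 1 && p <= length(covVec)) covVec[p] else 0
  if (strand == "+") {
    prom <- vapply((tss + win[1]):(tss + win[2]), at, numeric(1))
    body <- vapply((tss + win[2] + 1L):tes, at, numeric(1))
  } else {
    prom <- vapply((tss - win[2]):(tss - win[1]), at, numeric(1))
    body <- vapply(tes:(tss - win[2] - 1L), at, numeric(1))
  }
  mean(prom) / mean(body)
}

# --- D-rule oracle --------------------------------------------------------
oracleDRule <- function(rn, rl, rh, cut = 1) {
  d1 <- abs(rn - rl); d2 <- abs(rl - rh); d3 <- abs(rn - rh)
  reg <- (d1 >= cut) || (d2 >= cut) || (d3 >= cut)
  trend <- NA_character_
  if (reg) {
    if (rh >= rl && rh >= rn) trend <- "High_pool"
    else if (rl >= rn) trend <- "Low_pool"
    else trend <- "None_pool"
  }
  list(d1 = d1, d2 = d2, d3 = d3, regulated = reg, trend = trend)
}

# --- exhaustive 3-frame ORF oracle ----------------------------------------
oracleLongestOrf <- function(s, min_codons = 1L) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (start in seq_len(max(0L, n - 5L))) {
    if (substr(s, start, start + 2L) != "ATG") next
    p <- start + 3L
    while (p + 2L <= n) {
      cod <- substr(s, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- (p - start) / 3L
        if (len >= min_codons &&
            (is.null(best) || len > best$len ||
             (len == best$len && start < best$start)))
          best <- list(start = start, end = p + 2L, len = len)
        break
      }
      p <- p + 3L
    }
  }
  best
}

# random nucleotide string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# build a single-exon TranscriptSet from vectors (test convenience)
makeTxSet <- function(ids, start, end, strand, chrom = "chrT",
                      biotype = "noncoding", source = "de-novo") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
  TranscriptSet(split(gr, factor(ids, levels = ids)),
                biotype = biotype, source = source)
}

# minimal PolysomeExperiment builder for normalization tests
mkPoly <- function(m, pools = NULL, states = NULL, reps = NULL,
                   biotype = "noncoding") {
  ns <- ncol(m)
  sheet <- data.frame(
    sample = paste0("s", seq_len(ns)),
    state = if (is.null(states)) rep("control", ns) else states,
    pool = if (is.null(pools)) rep("Total", ns) else pools,
    replicate = if (is.null(reps)) seq_len(ns) else reps,
    stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = paste0("p", seq_len(nrow(m))),
                       transcript_id = paste0("t", seq_len(nrow(m))),
                       biotype = rep_len(biotype, nrow(m)),
                       stringsAsFactors = FALSE)
  PolysomeExperiment(m, sheet, probes)
}
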