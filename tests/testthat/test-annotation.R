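gtf_line <- function(chrom, src, type, start, end, strand, attrs) {
  paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
}

writeTestGtf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GTF exons map onto strand-aware transcript models", {
  path <- writeTestGtf(c(
    gtf_line("chr1", "test", "exon", 101, 200, "+",
             'gene_id "gA"; transcript_id "txP";'),
    gtf_line("chr1", "test", "exon", 301, 400, "+",
             'gene_id "gA"; transcript_id "txP";'),
    gtf_line("chr1", "test", "exon", 101, 200, "-",
             'gene_id "gB"; transcript_id "txM";'),
    gtf_line("chr1", "test", "exon", 301, 400, "-",
             'gene_id "gB"; transcript_id "txM";')))
  ts <- readAnnotation(path, format = "gtf")
  expect_setequal(txIds(ts), c("txP", "txM"))
  # plus strand: TSS at the first exon start; minus strand mirrored
  expect_equal(unname(tss(ts)["txP"]), 101)
  expect_equal(unname(tes(ts)["txP"]), 400)
  expect_equal(unname(tss(ts)["txM"]), 400)
  expect_equal(unname(tes(ts)["txM"]), 101)
  expect_equal(unname(splicedLength(ts)["txP"]), 200)
  ex <- exonsBy(ts)[["txP"]]
  expect_equal(GenomicRanges::start(ex), c(101, 301))
  expect_equal(GenomicRanges::end(ex), c(200, 400))
})

test_that("BED12 blocks expand to exons whose lengths sum to blockSizes", {
  path <- withr::local_tempfile(fileext = ".bed")
  # blockCount 3; spliced length must equal 100+50+150 by naive expansion
  writeLines("chr2\t1000\t3000\ttx3\t0\t+\t1000\t3000\t0\t3\t100,50,150\t0,700,1850",
             path)
  ts <- readAnnotation(path, format = "bed12")
  expect_equal(length(ts), 1L)
  expect_equal(lengths(exonsBy(ts))[[1]], 3L)
  expect_equal(unname(splicedLength(ts)[1]), 100 + 50 + 150)
  # naive per-block oracle: chromStart + offset .. + size (0-based half-open)
  ex <- exonsBy(ts)[[1]]
  expect_equal(GenomicRanges::start(ex), 1000 + c(0, 700, 1850) + 1)
  expect_equal(GenomicRanges::width(ex), c(100, 50, 150))
})

test_that("annotation round-trips bit-exactly through both dialects", {
  set.seed(71)
  ids <- sprintf("tx%02d", 1:12)
  ex <- lapply(1:12, function(i) {
    n <- sample(1:4, 1)
    st <- sort(sample(seq(1000, 50000, by = 100), n))
    GenomicRanges::GRanges("chr3", IRanges::IRanges(st, st + sample(50:99, n)),
                           sample(c("+", "-"), 1))
  })
  names(ex) <- ids
  ts <- TranscriptSet(GenomicRanges::GRangesList(ex))
  for (fmt in c("bed12", "gtf")) {
    path <- withr::local_tempfile(fileext = paste0(".", sub("12", "", fmt)))
    writeAnnotation(ts, path, fmt)
    back <- readAnnotation(path, format = fmt)
    expect_setequal(txIds(back), ids)
    for (id in ids) {
      expect_identical(GenomicRanges::start(exonsBy(back)[[id]]),
                       GenomicRanges::start(exonsBy(ts)[[id]]), label = fmt)
      expect_identical(GenomicRanges::end(exonsBy(back)[[id]]),
                       GenomicRanges::end(exonsBy(ts)[[id]]), label = fmt)
    }
    expect_identical(txStrand(back)[ids], txStrand(ts)[ids])
  }
})

test_that("transcripts with exons on mixed strands are rejected with a warning", {
  path <- writeTestGtf(c(
    gtf_line("chr1", "t", "exon", 1, 100, "+", 'transcript_id "bad";'),
    gtf_line("chr1", "t", "exon", 201, 300, "-", 'transcript_id "bad";'),
    gtf_line("chr1", "t", "exon", 501, 700, "+", 'transcript_id "good";')))
  expect_warning(ts <- readAnnotation(path, format = "gtf"), "rejected")
  expect_identical(txIds(ts), "good")
})

test_that("locus merging follows same-strand exonic overlap closure", {
  # one shared exonic bp joins; identical coordinates on opposite strands
  # stay apart
  ts <- makeTxSet(c("a", "b", "c", "d"),
                  start = c(100, 600, 100, 5000),
                  end = c(600, 900, 600, 5400),
                  strand = c("+", "+", "-", "+"))
  m <- mergeLoci(ts)
  loc <- txData(m)$locus_id
  names(loc) <- txIds(m)
  expect_identical(loc[["a"]], loc[["b"]])   # share exactly 1 bp at 600
  expect_false(loc[["a"]] == loc[["c"]])     # same span, opposite strand
  expect_false(loc[["a"]] == loc[["d"]])     # singleton locus
  # min_overlap larger than the shared bp splits a and b
  m2 <- mergeLoci(ts, min_overlap = 2L)
  loc2 <- txData(m2)$locus_id
  names(loc2) <- txIds(m2)
  expect_false(loc2[["a"]] == loc2[["b"]])
})

test_that("locus partition matches the brute-force overlap oracle", {
  set.seed(42)
  for (rep in 1:4) {
    n <- 50L
    exon_list <- list(); strand <- character(n)
    grl <- list()
    for (i in seq_len(n)) {
      k <- sample(1:3, 1)
      st <- sort(sample(seq(1, 20000, by = 10), k))
      en <- st + sample(100:800, k)
      # enforce sorted non-overlapping chains
      for (j in seq_len(k - 1))
        if (k > 1 && en[j] >= st[j + 1]) en[j] <- st[j + 1] - 1
      exon_list[[i]] <- data.frame(start = st, end = en)
      strand[i] <- sample(c("+", "-"), 1)
      grl[[sprintf("t%02d", i)]] <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(st, en), strand[i])
    }
    ts <- TranscriptSet(GenomicRanges::GRangesList(grl))
    m <- mergeLoci(ts)
    got <- txData(m)$locus_id
    want <- oracleMergeLoci(exon_list, strand)
    # same partition: locus labels induce identical groupings
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
    # partition conservation: every transcript in exactly one locus
    expect_equal(length(got), n)
    expect_false(anyNA(got))
  }
})

test_that("locus merging is permutation-invariant and idempotent", {
  set.seed(9)
  st <- sample(seq(1, 30000, by = 500), 20)
  ts <- makeTxSet(sprintf("t%02d", 1:20), start = st, end = st + 700,
                  strand = sample(c("+", "-"), 20, replace = TRUE))
  m1 <- mergeLoci(ts)
  perm <- sample(20)
  m2 <- mergeLoci(ts[perm])
  loc1 <- stats::setNames(txData(m1)$locus_id, txIds(m1))
  loc2 <- stats::setNames(txData(m2)$locus_id, txIds(m2))
  expect_identical(loc1[sort(names(loc1))], loc2[sort(names(loc2))])
  expect_identical(txData(mergeLoci(m1))$locus_id, txData(m1)$locus_id)
})

test_that("representative transcript is the max-RPKM member with stated tie-breaks", {
  ts <- makeTxSet(c("A", "B"), start = c(100, 100), end = c(500, 900),
                  strand = "+")
  ts <- mergeLoci(ts)
  rpkm <- rbind(A = c(5, 1), B = c(3, 2))
  expect_equal(unname(selectRepresentative(ts, rpkm)), "A")
  # exact tie in max RPKM: longer spliced length wins (B is longer)
  rpkm2 <- rbind(A = c(5, 1), B = c(2, 5))
  expect_equal(unname(selectRepresentative(ts, rpkm2)), "B")
  # full tie: lexicographic transcript id
  tsEq <- makeTxSet(c("zz", "aa"), start = c(100, 100), end = c(500, 500),
                    strand = "+")
  tsEq <- mergeLoci(tsEq)
  rpkm3 <- rbind(zz = c(4, 4), aa = c(4, 4))
  expect_equal(unname(selectRepresentative(tsEq, rpkm3)), "aa")
})

test_that("representative selection equals the flattened argmax oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 20L
    st <- rep(1000L, n)
    ts <- makeTxSet(sprintf("m%02d", 1:n), start = st,
                    end = st + sample(300:4000, n), strand = "+")
    ts <- mergeLoci(ts)  # all overlap -> one locus
    rpkm <- matrix(stats::runif(n * 4, 0, 50), n,
                   dimnames = list(txIds(ts), paste0("c", 1:4)))
    got <- selectRepresentative(ts, rpkm)
    flat <- which(rpkm == max(rpkm), arr.ind = TRUE)
    expect_equal(unname(got), rownames(rpkm)[flat[1, "row"]])
  }
})

test_that("empty or unknown inputs raise errors", {
  ts <- makeTxSet("x", 1, 300, "+")
  expect_error(selectRepresentative(ts, rbind(y = 1)), "missing")
  expect_error(geneLoci(ts), "locus_id")
})
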