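smallCfg <- function(seed = 1L, ...) {
  simConfig(seed = seed, n_coding_genes = 12L,
            lnc_counts = c(distal = 4L, overlapping = 4L,
                           terminal_associated = 4L,
                           promoter_associated = 4L), ...)
}

test_that("generators are pure functions of the configuration seed", {
  a1 <- generateAnnotation(smallCfg(seed = 7))
  a2 <- generateAnnotation(smallCfg(seed = 7))
  expect_identical(txSpan(a1$lnc), txSpan(a2$lnc))
  expect_identical(a1$truth, a2$truth)
  c1 <- simulateCounts(smallCfg(seed = 7), a1)
  c2 <- simulateCounts(smallCfg(seed = 7), a2)
  expect_identical(c1$counts, c2$counts)
  p1 <- simulatePolysomeArrays(smallCfg(seed = 7))
  p2 <- simulatePolysomeArrays(smallCfg(seed = 7))
  expect_identical(SummarizedExperiment::assay(p1$pe, "intensity"),
                   SummarizedExperiment::assay(p2$pe, "intensity"))
})

test_that("different seeds move coordinates but keep the class design", {
  a1 <- generateAnnotation(smallCfg(seed = 1))
  a2 <- generateAnnotation(smallCfg(seed = 2))
  expect_false(identical(GenomicRanges::start(txSpan(a1$lnc)),
                         GenomicRanges::start(txSpan(a2$lnc))))
  expect_equal(table(a1$truth$klass), table(a2$truth$klass))
})

test_that("a zero-lncRNA configuration still yields a valid coding annotation", {
  cfg <- simConfig(seed = 3, n_coding_genes = 5,
                   lnc_counts = c(distal = 0, overlapping = 0,
                                  terminal_associated = 0,
                                  promoter_associated = 0))
  ann <- generateAnnotation(cfg)
  expect_equal(length(ann$lnc), 0L)
  expect_equal(length(ann$coding), 5L)
  expect_equal(nrow(ann$truth), 0L)
})

test_that("an infeasible chromosome length is rejected", {
  expect_error(generateAnnotation(simConfig(seed = 1, chrom_len = 1e4)),
               "too small")
  expect_error(simConfig(seed = 1, n_coding_genes = 2,
                         lnc_counts = c(distal = 0, overlapping = 5,
                                        terminal_associated = 0,
                                        promoter_associated = 0)),
               "at most one")
})

test_that("emitted files re-parse through the package readers", {
  outdir <- withr::local_tempdir()
  cfg <- smallCfg(seed = 11)
  expect_no_warning(simulateToFiles(cfg, outdir))
  coding <- readAnnotation(file.path(outdir, "coding.gtf"), format = "gtf",
                           biotype_rule = function(meta) "coding")
  expect_equal(length(coding), 12L)
  lnc <- readAnnotation(file.path(outdir, "lnc.bed"), format = "bed12")
  expect_equal(length(lnc), 16L)
  trk <- readBedGraph(file.path(outdir, "pol2_control.bedGraph"))
  expect_s4_class(trk, "CoverageTrack")
  pe <- readPolysomeMatrix(file.path(outdir, "polysome_matrix.tsv"),
                           file.path(outdir, "polysome_samples.tsv"),
                           file.path(outdir, "polysome_probes.tsv"))
  expect_s4_class(pe, "PolysomeExperiment")
  expect_equal(ncol(pe), 24L)
  # the written annotation matches the in-memory objects exactly
  ann <- generateAnnotation(cfg)
  expect_equal(unname(tss(lnc)[txIds(ann$lnc)]), unname(tss(ann$lnc)))
})

test_that("planted fold changes emerge in the low-dispersion limit", {
  cfg <- simConfig(seed = 21, n_coding_genes = 40,
                   lnc_counts = c(distal = 40, overlapping = 0,
                                  terminal_associated = 0,
                                  promoter_associated = 0),
                   nb_dispersion = 1e-4, depth = 1e8)
  ann <- generateAnnotation(cfg)
  cnt <- simulateCounts(cfg, ann)
  up <- ann$truth$lnc_id[ann$truth$de_direction == "up"]
  ratio <- sum(cnt$counts[up, "t30_nucleus"]) /
           sum(cnt$counts[up, "control_nucleus"])
  expect_equal(ratio, cfg$fc_up, tolerance = 0.01)
  unch <- ann$truth$lnc_id[ann$truth$de_direction == "unchanged"]
  ratio0 <- sum(cnt$counts[unch, "t30_nucleus"]) /
            sum(cnt$counts[unch, "control_nucleus"])
  expect_equal(ratio0, 1, tolerance = 0.01)
})

test_that("intron-up genes show the divergent intron/exon quadrant pattern", {
  cfg <- simConfig(seed = 31, n_coding_genes = 60,
                   lnc_counts = c(distal = 0, overlapping = 0,
                                  terminal_associated = 0,
                                  promoter_associated = 0),
                   nb_dispersion = 0.01)
  ann <- generateAnnotation(cfg)
  cnt <- simulateCounts(cfg, ann)
  f <- cnt$features
  gid <- f$feature_id[f$type == "exonic" & f$biotype == "coding"]
  iid <- paste0(gid, ":intron")
  has_int <- iid %in% f$feature_id
  gid <- gid[has_int]; iid <- iid[has_int]
  len <- stats::setNames(f$length_nt, f$feature_id)
  rp <- function(id, s) computeRpkm(cnt$counts[id, s], len[id], cfg$depth)
  q <- intronExonQuadrants(gid,
    rp(gid, "t30_nucleus"), rp(gid, "control_nucleus"),
    rp(iid, "t30_nucleus"), rp(iid, "control_nucleus"),
    intron_length = len[iid])
  truth <- ann$gene_truth[match(q$gene_id, ann$gene_truth$gene_id), ]
  # genes planted down with intron-up must land in quadrant II
  sel <- truth$intron_up & truth$de_direction == "down"
  expect_true(all(q$quadrant[sel] == "II"))
  expect_true(all(q$altered[sel]))
})

test_that("a unity pausing gain leaves traveling ratios indistinguishable", {
  cfg <- simConfig(seed = 41, n_coding_genes = 100,
                   lnc_counts = c(distal = 0, overlapping = 0,
                                  terminal_associated = 0,
                                  promoter_associated = 0),
                   pausing_gain = 1)
  ann <- generateAnnotation(cfg)
  covs <- simulateCoverage(cfg, ann)
  s <- stallingShift(travelingRatio(ann$coding, covs$control),
                     travelingRatio(ann$coding, covs$t30))
  expect_gt(s$p_ranksum, 0.05)
  expect_equal(s$median_ratio, 1, tolerance = 0.1)
})

test_that("the late time point reverts to the control coverage profile", {
  cfg <- smallCfg(seed = 51)
  ann <- generateAnnotation(cfg)
  covs <- simulateCoverage(cfg, ann)
  anchors <- data.frame(chrom = "chrS", pos = unname(tss(ann$coding)),
                        strand = unname(txStrand(ann$coding)))
  p0 <- metaProfile(anchors, covs$control, window_bp = 3000)
  p2 <- metaProfile(anchors, covs$t2h, window_bp = 3000)
  p30 <- metaProfile(anchors, covs$t30, window_bp = 3000)
  expect_gt(stats::cor(p0$mean_rpm, p2$mean_rpm), 0.95)
  # the 30-min profile carries extra promoter-proximal signal
  mid <- abs(p30$bin_center) < 1500
  expect_gt(mean(p30$mean_rpm[mid]), mean(p0$mean_rpm[mid]) * 1.3)
})

test_that("the 30-min metaprofile shows signal on both sides of the TSS", {
  cfg <- simConfig(seed = 61, n_coding_genes = 60,
                   lnc_counts = c(distal = 0, overlapping = 0,
                                  terminal_associated = 0,
                                  promoter_associated = 0))
  ann <- generateAnnotation(cfg)
  covs <- simulateCoverage(cfg, ann)
  anchors <- data.frame(chrom = "chrS", pos = unname(tss(ann$coding)),
                        strand = unname(txStrand(ann$coding)))
  p30 <- metaProfile(anchors, covs$t30, window_bp = 3000, bin_width = 50)
  base30 <- mean(p30$mean_rpm[p30$bin_center > 2000])
  up_lobe <- p30$mean_rpm[p30$bin_center > -1300 & p30$bin_center < -700]
  dn_peak <- p30$mean_rpm[p30$bin_center > 0 & p30$bin_center < 300]
  expect_gt(mean(up_lobe), base30 * 1.5)
  expect_gt(mean(dn_peak), base30 * 1.5)
})

test_that("null polysome arrays stay below the D-rule false-positive budget", {
  cfg <- simConfig(seed = 71, polysome = list(
    n_lnc = 150L, n_mrna = 150L,
    class_prop = list(
      noncoding = c(high = 0, low = 0, no_change = 1),
      coding = c(high = 0, low = 0, no_change = 1)),
    regulated_fraction = 0))
  poly <- simulatePolysomeArrays(cfg)
  pe <- normalizeArrays(poly$pe, method = "normexp")
  ct <- detectTranslationalShift(computeContrasts(pe))
  # with planted zero effects and sd 0.1 noise the D statistics live far
  # below the threshold of 1 log2 unit
  expect_lt(mean(ct$translationally_regulated), 0.01)
})
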