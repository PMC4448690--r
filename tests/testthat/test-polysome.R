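test_that("quantile normalization averages rank-aligned columns", {
  # log2 domain [1,2,3] and [2,4,6] must both become [1.5, 3.0, 4.5]
  m <- cbind(2^c(1, 2, 3), 2^c(2, 4, 6))
  pe <- normalizeArrays(mkPoly(m), method = "none", offset = 0,
                        floor = 1e-9)
  lg <- SummarizedExperiment::assay(pe, "log2norm")
  expect_equal(unname(lg[, 1]), c(1.5, 3.0, 4.5))
  expect_equal(unname(lg[, 2]), c(1.5, 3.0, 4.5))
  # identical columns are left unchanged
  m2 <- cbind(2^c(5, 1, 3), 2^c(5, 1, 3))
  lg2 <- SummarizedExperiment::assay(
    normalizeArrays(mkPoly(m2), method = "none", offset = 0, floor = 1e-9),
    "log2norm")
  expect_equal(unname(lg2[, 1]), c(5, 1, 3))
})

test_that("quantile normalization is idempotent with identical sorted columns", {
  set.seed(61)
  m <- matrix(2^stats::rnorm(400, 10, 1), 100, 4)
  pe <- normalizeArrays(mkPoly(m), method = "none", offset = 0)
  lg <- SummarizedExperiment::assay(pe, "log2norm")
  srt <- apply(lg, 2, sort)
  for (j in 2:4) expect_equal(srt[, j], srt[, 1])
  # re-normalizing the normalized values changes nothing
  pe2 <- mkPoly(2^lg)
  lg2 <- SummarizedExperiment::assay(
    normalizeArrays(pe2, method = "none", offset = 0), "log2norm")
  expect_equal(unname(lg2), unname(lg), tolerance = 1e-12)
})

test_that("normexp background correction recovers signal above background", {
  set.seed(77)
  true <- 2^stats::rnorm(500, 9, 1)
  obs <- true + stats::rexp(500, 1 / 40)
  m <- cbind(obs, true + stats::rexp(500, 1 / 40))
  pe <- normalizeArrays(mkPoly(m), method = "normexp")
  lg <- SummarizedExperiment::assay(pe, "log2norm")
  expect_true(all(is.finite(lg)))
  expect_gt(stats::cor(lg[, 1], log2(true)), 0.95)
})

test_that("anomalous replicates are detected by clustering and removed", {
  set.seed(81)
  base <- stats::rnorm(300, 10, 1.5)
  good <- sapply(1:3, function(i) base + stats::rnorm(300, 0, 0.05))
  outlier <- sample(base)  # permuted: uncorrelated with its siblings
  m <- 2^cbind(good, outlier)
  pe <- normalizeArrays(
    mkPoly(m, pools = rep("Total", 4), states = rep("control", 4),
           reps = 1:4),
    method = "none", offset = 0)
  qc <- qcReplicates(pe)
  expect_equal(S4Vectors::metadata(qc)$removed_replicates, "s4")
  expect_equal(ncol(qc), 3L)
  # identical replicates: nothing removed
  m2 <- 2^cbind(good, good[, 1])
  pe2 <- normalizeArrays(
    mkPoly(m2, pools = rep("Total", 4), states = rep("control", 4),
           reps = 1:4), method = "none", offset = 0)
  qc2 <- qcReplicates(pe2)
  expect_length(S4Vectors::metadata(qc2)$removed_replicates, 0)
  # two-replicate groups are skipped with a warning
  pe3 <- normalizeArrays(
    mkPoly(2^good[, 1:2], pools = rep("Total", 2),
           states = rep("control", 2), reps = 1:2),
    method = "none", offset = 0)
  expect_warning(qcReplicates(pe3), "<3 replicates")
})

test_that("pool contrasts measure the stress-minus-control log2 difference", {
  set.seed(91)
  n <- 200L
  pools <- rep(c("Total", "None", "Low", "High"), each = 6)
  states <- rep(rep(c("control", "stress"), each = 3), 4)
  base <- matrix(stats::rnorm(n * 24, 8, 1), n, 24)
  base[, states == "stress"] <- base[, states == "stress"] + 1.0
  pe <- mkPoly(2^base, pools = pools, states = states,
               reps = rep(1:3, 8))
  SummarizedExperiment::assay(pe, "log2norm", withDimnames = FALSE) <- base
  ct <- computeContrasts(pe)
  for (col in c("RT", "RN", "RL", "RH"))
    expect_equal(mean(ct[[col]]), 1.0, tolerance = 0.15)
  # exactly equal groups: zero contrast, p = 1
  eq <- matrix(stats::rnorm(n * 6, 8, 1), n, 6)
  peq <- mkPoly(2^cbind(eq, eq), pools = rep("Total", 12),
                states = rep(c("control", "stress"), each = 6),
                reps = rep(1:6, 2))
  SummarizedExperiment::assay(peq, "log2norm", withDimnames = FALSE) <- cbind(eq, eq)
  cteq <- computeContrasts(peq)
  expect_equal(cteq$RT, rep(0, n))
  expect_equal(cteq$p_total, rep(1, n))
  expect_true(all(is.na(cteq$RN)))  # pool absent -> NA contrast
})

test_that("simulated contrasts are unbiased within Monte-Carlo error", {
  set.seed(97)
  shift <- c(rep(0, 40), rep(1.5, 40), rep(-2, 20))
  sigma <- 0.3; nrep <- 3L
  ctrl <- matrix(stats::rnorm(100 * nrep, 8, sigma), 100, nrep)
  strs <- matrix(stats::rnorm(100 * nrep, 8 + shift, sigma), 100, nrep)
  pe <- mkPoly(2^cbind(ctrl, strs), pools = rep("Total", 6),
               states = rep(c("control", "stress"), each = 3),
               reps = rep(1:3, 2))
  SummarizedExperiment::assay(pe, "log2norm", withDimnames = FALSE) <- cbind(ctrl, strs)
  ct <- computeContrasts(pe)
  se <- sigma * sqrt(2 / nrep)
  expect_true(all(abs(ct$RT - shift) < 3.5 * se))
})

test_that("transcriptional classification applies the p and fold cuts", {
  ct <- data.frame(probe_id = c("a", "b", "c", "d"),
                   RT = c(1.0, -0.263, 1.585, -1.0),
                   RN = 0, RL = 0, RH = 0,
                   p_total = c(0.01, 0.01, 0.5, 0.05))
  cl <- classifyTranscription(ct)
  # 2-fold up, significant
  expect_equal(cl$transcriptional_class[1], "high")
  # -1.2-fold: inside the +/-1.5 band
  expect_equal(cl$transcriptional_class[2], "no_change")
  # 3-fold but p = 0.5: excluded entirely
  expect_true(is.na(cl$transcriptional_class[3]))
  expect_equal(cl$transcriptional_class[4], "low")
  # signed linear mode agrees at the boundary
  lin <- classifyTranscription(
    data.frame(probe_id = "x", RT = log2(1.5), RN = 0, RL = 0, RH = 0,
               p_total = 0.01), scale = "linear")
  expect_equal(lin$transcriptional_class, "high")
})

test_that("the D-rule flags shifts and assigns the highest-ratio pool", {
  ct <- data.frame(probe_id = c("a", "b"),
                   RN = c(0.2, 0), RL = c(0.5, 0), RH = c(1.6, 0))
  d <- detectTranslationalShift(ct)
  expect_equal(d$d1[1], 0.3)
  expect_equal(d$d2[1], 1.1)
  expect_equal(d$d3[1], 1.4)
  expect_true(d$translationally_regulated[1])
  expect_equal(d$trend[1], "High_pool")
  expect_false(d$translationally_regulated[2])
  expect_true(is.na(d$trend[2]))
  # boundary is non-strict: a spread of exactly 1 is regulated
  b <- detectTranslationalShift(
    data.frame(probe_id = "x", RN = 0, RL = 0, RH = 1))
  expect_true(b$translationally_regulated)
  # NA contrasts propagate to NA calls
  na <- detectTranslationalShift(
    data.frame(probe_id = "y", RN = NA_real_, RL = 0, RH = 2))
  expect_true(is.na(na$translationally_regulated))
})

test_that("permuting the pools permutes the D statistics consistently", {
  set.seed(12)
  for (i in 1:20) {
    v <- stats::runif(3, -2, 2)
    base <- detectTranslationalShift(
      data.frame(probe_id = "p", RN = v[1], RL = v[2], RH = v[3]))
    perm <- sample(3)
    sw <- detectTranslationalShift(
      data.frame(probe_id = "p", RN = v[perm[1]], RL = v[perm[2]],
                 RH = v[perm[3]]))
    expect_equal(sw$translationally_regulated,
                 base$translationally_regulated)
    expect_setequal(round(c(sw$d1, sw$d2, sw$d3), 12),
                    round(c(base$d1, base$d2, base$d3), 12))
  }
})

test_that("trend summaries count one cell per regulated probe", {
  calls <- data.frame(
    probe_id = c("a", "b", "c"),
    transcriptional_class = c("high", "high", NA),
    translationally_regulated = c(TRUE, FALSE, TRUE),
    trend = c("High_pool", NA, "None_pool"),
    stringsAsFactors = FALSE)
  cube <- trendSummary(calls, c("noncoding", "noncoding", "coding"))
  expect_equal(sum(cube), 1L)  # only probe a: regulated with a class
  expect_equal(cube["high", "noncoding", "High_pool"], 1L)
  none <- trendSummary(calls[2, ], "coding")
  expect_equal(sum(none), 0L)
})

test_that("fraction enrichment returns percentages summing to 100", {
  expect_equal(unname(fractionEnrichment(c(untranslated = 3, translated = 1))),
               c(75, 25))
  expect_equal(unname(fractionEnrichment(c(1, 1))), c(50, 50))
  set.seed(6)
  for (i in 1:10) {
    q <- stats::runif(sample(2:5, 1), 0, 10)
    expect_equal(sum(fractionEnrichment(q)), 100)
  }
  expect_error(fractionEnrichment(c(0, 0)), "all-zero|zero")
  expect_error(fractionEnrichment(c(-1, 2)), "non-negative")
})

test_that("probe pairs collapse to per-transcript medians", {
  ct <- data.frame(probe_id = paste0("p", 1:4),
                   RT = c(1, 3, 0, 0.5), RN = c(0, 2, 1, 1),
                   RL = c(1, 1, 0, 0), RH = c(2, 4, 0, 0),
                   p_total = c(0.2, 0.01, 0.5, 0.6))
  tx <- c("tA", "tA", "tB", "tB")
  cc <- collapseProbes(ct, tx)
  expect_equal(cc$RT[cc$transcript_id == "tA"], 2)
  expect_equal(cc$p_total[cc$transcript_id == "tA"], 0.01)
})
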