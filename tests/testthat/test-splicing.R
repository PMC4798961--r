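mkJunctions <- function(tab) {
  # tab: list(sample = c(Jup, Jdn, Jskip)) for one exon
  do.call(rbind, lapply(names(tab), function(s)
    data.frame(exonId = "E1", sample = s, Jup = tab[[s]][1],
               Jdn = tab[[s]][2], Jskip = tab[[s]][3],
               stringsAsFactors = FALSE)))
}

test_that("inclusion fractions pool counts per condition", {
  samples <- data.frame(sample = c("a", "b"), condition = c("c1", "c2"),
                        stringsAsFactors = FALSE)
  cj <- mkJunctions(list(a = c(90, 90, 10), b = c(90, 90, 10)))
  fr <- inclusionFraction(cj, samples)
  expect_equal(fr$I1, 0.9)         # inc = (90+90)/2 = 90, I = 90/100
  expect_equal(fr$deltaI, 0)
  # no skipping -> I = 1
  c2 <- mkJunctions(list(a = c(50, 50, 0), b = c(10, 10, 10)))
  fr2 <- inclusionFraction(c2, samples)
  expect_equal(fr2$I1, 1)
  # pooled I equals the count-weighted mean of per-sample fractions
  s3 <- data.frame(sample = c("a", "b", "c"),
                   condition = c("c1", "c1", "c2"), stringsAsFactors = FALSE)
  c3 <- mkJunctions(list(a = c(10, 10, 10), b = c(80, 80, 20), c = c(5, 5, 5)))
  fr3 <- inclusionFraction(c3, s3)
  # samples a and b: inc 10 and 80, totals 20 and 100
  expect_equal(fr3$I1, (10 + 80) / (20 + 100))
  wmean <- (20 * (10 / 20) + 100 * (80 / 100)) / 120
  expect_equal(fr3$I1, wmean)
  # all-zero condition is flagged undefined
  c4 <- mkJunctions(list(a = c(1, 1, 1), b = c(0, 0, 0)))
  expect_true(inclusionFraction(c4, samples)$undefined)
})

test_that("the junction filter requires both isoforms in every condition", {
  samples <- data.frame(sample = c("a", "b"), condition = c("c1", "c2"),
                        stringsAsFactors = FALSE)
  # inclusion 100, exclusion 0 in one condition -> removed
  c1 <- mkJunctions(list(a = c(100, 100, 0), b = c(50, 50, 50)))
  expect_length(junctionFilter(c1, samples, libSizes = c(a = 100, b = 100)), 0)
  # both isoforms >= 5 in both conditions -> kept
  c2 <- mkJunctions(list(a = c(20, 20, 10), b = c(20, 20, 10)))
  expect_equal(junctionFilter(c2, samples, libSizes = c(a = 100, b = 100)),
               "E1")
  # brute-force oracle on simulated exons
  sim <- simulateSplicingCounts(300, depthMean = 12, seed = 16)
  libs <- tapply(sim$counts$Jup + sim$counts$Jdn + sim$counts$Jskip,
                 sim$counts$sample, sum)
  keep <- junctionFilter(sim$counts, sim$samples, libSizes = libs,
                         minNormCov = 5)
  sc <- mean(libs) / libs
  brute <- vapply(unique(sim$counts$exonId), function(e) {
    sub <- sim$counts[sim$counts$exonId == e, ]
    ok <- TRUE
    for (cn in unique(sim$samples$condition)) {
      ss <- sim$samples$sample[sim$samples$condition == cn]
      rows <- sub[sub$sample %in% ss, ]
      f <- sc[rows$sample]
      ok <- ok && sum((rows$Jup + rows$Jdn) / 2 * f) >= 5 &&
        sum(rows$Jskip * f) >= 5
    }
    ok
  }, logical(1))
  expect_setequal(keep, unique(sim$counts$exonId)[brute])
})

test_that("the splicing LRT is null-calibrated and recovers planted effects", {
  samples <- data.frame(sample = c("a", "b"), condition = c("c1", "c2"),
                        stringsAsFactors = FALSE)
  cflat <- mkJunctions(list(a = c(40, 40, 40), b = c(40, 40, 40)))
  r <- splicingLRT(cflat, samples)
  expect_equal(r$deltaI, 0)
  expect_equal(r$p, 1)
  # modest null calibration run (full-size calibration in acceptance)
  s0 <- simulateSplicingCounts(400, effectLogit = 0, depthMean = 200,
                               affectedFraction = 0, nPerGroup = 4, seed = 17)
  r0 <- splicingLRT(s0$counts, s0$samples,
                    exons = junctionFilter(s0$counts, s0$samples))
  t1 <- mean(r0$p < 0.05)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.09)
  # planted effect: baseline 0, effect logit(0.9) -> true deltaI = -0.4
  eff <- stats::qlogis(0.9)
  s1 <- simulateSplicingCounts(150, baselineLogitSd = 0, effectLogit = eff,
                               affectedFraction = 0.3, depthMean = 200,
                               nPerGroup = 4, seed = 18)
  r1 <- splicingLRT(s1$counts, s1$samples)
  r1 <- classifySignificant(r1)
  tr <- s1$truth[match(r1$exonId, s1$truth$exonId), ]
  aff <- tr$affected
  expect_lt(abs(mean(r1$deltaI[aff]) - (-0.4)), 0.05)
  expect_gt(mean(r1$significant[aff]), 0.85)
  expect_lt(mean(r1$significant[!aff]), 0.1)
})

test_that("deltaI is antisymmetric under swapping condition labels", {
  sim <- simulateSplicingCounts(50, effectLogit = 1, affectedFraction = 1,
                                depthMean = 100, seed = 19)
  # reorder the sample sheet so the other condition becomes condition 1
  sw <- sim$samples[order(match(sim$samples$condition, c("case", "ctrl"))), ]
  f1 <- inclusionFraction(sim$counts, sim$samples)
  f2 <- inclusionFraction(sim$counts, sw)
  expect_equal(f1$deltaI, -f2$deltaI)
})

test_that("batch covariates absorb confounded batch structure", {
  # batches partially confounded with condition, as with brain cohorts
  sB <- simulateSplicingCounts(300, effectLogit = 0, affectedFraction = 0,
                               batchSd = 1, depthMean = 200, nPerGroup = 4,
                               batchAssign = c("B1", "B1", "B1", "B2",
                                               "B1", "B2", "B2", "B2"),
                               seed = 20)
  withB <- splicingLRT(sB$counts, sB$samples)
  noB <- splicingLRT(sB$counts, sB$samples[, c("sample", "condition")])
  expect_lt(mean(withB$p < 0.05), 0.1)
  # dropping the batch covariate mis-calibrates the test badly
  expect_gt(mean(noB$p < 0.05), 2 * mean(withB$p < 0.05))
})

test_that("significance classification applies both gates", {
  df <- data.frame(exonId = c("a", "b", "c"),
                   deltaI = c(0.05, 0.25, -0.3),
                   fdr = c(0.01, 0.04, 0.2))
  out <- classifySignificant(df)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE))
  expect_equal(out$direction[2], "increased")
  # brute-force recount of both gates on a simulated table
  set.seed(21)
  big <- data.frame(exonId = sprintf("e%d", 1:200),
                    deltaI = stats::runif(200, -0.5, 0.5),
                    fdr = stats::runif(200))
  o <- classifySignificant(big)
  expect_equal(sum(o$significant),
               sum(big$fdr < 0.05 & abs(big$deltaI) >= 0.1))
})

test_that("peak-exon association respects the flank and strand", {
  ex <- GenomicRanges::GRanges("chrS", IRanges::IRanges(10000, 10200),
                               strand = "+")
  mkP <- function(sm) {
    p <- GenomicRanges::GRanges("chrS", IRanges::IRanges(sm, sm + 1))
    p$summit <- sm
    p
  }
  # summit exactly 2501 nt away is outside the 2500 flank
  expect_equal(nrow(associatePeaksWithExons(ex, mkP(10000 - 2501))), 0)
  a <- associatePeaksWithExons(ex, mkP(10000 - 2500))
  expect_equal(nrow(a), 1)
  expect_equal(a$side, "upstream")
  # on a minus-strand exon a genomically-downstream peak is "upstream"
  exm <- ex
  GenomicRanges::strand(exm) <- "-"
  am <- associatePeaksWithExons(exm, mkP(10200 + 100))
  expect_equal(am$side, "upstream")
  # brute-force all-pairs distance oracle
  set.seed(22)
  exs <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(sample.int(50000, 50) + 5000, width = 150),
    strand = sample(c("+", "-"), 50, TRUE))
  pks <- do.call(c, lapply(sample.int(60000, 80), mkP))
  got <- associatePeaksWithExons(exs, pks, flank = 2500)
  cnt <- 0
  for (i in seq_along(exs)) for (j in seq_along(pks)) {
    if (pks$summit[j] >= GenomicRanges::start(exs)[i] - 2500 &&
        pks$summit[j] <= GenomicRanges::end(exs)[i] + 2500) cnt <- cnt + 1
  }
  expect_equal(nrow(got), cnt)
})
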