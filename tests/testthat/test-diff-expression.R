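test_that("TMM factors: identical, scaled, and contaminated libraries", {
  set.seed(7)
  base <- stats::rnbinom(2000, mu = 200, size = 10) + 1L
  m <- cbind(A = base, B = base)
  rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  expect_equal(unname(tmmFactors(m)), c(1, 1))
  # pure depth difference is absorbed by library size, factors stay 1
  m2 <- cbind(A = base, B = 2L * base)
  rownames(m2) <- rownames(m)
  expect_equal(unname(tmmFactors(m2)), c(1, 1), tolerance = 1e-8)
  # 5% of genes 10-fold inflated in B only: B's effective library must be
  # down-weighted (factor below A's) so that unaffected genes' M-values
  # re-center at 0
  m3 <- m
  idx <- seq_len(100)
  m3[idx, "B"] <- 10L * m3[idx, "B"]
  f <- tmmFactors(m3)
  expect_lt(f[["B"]] / f[["A"]], 1)
  effB <- colSums(m3)[["B"]] * f[["B"]]
  effA <- colSums(m3)[["A"]] * f[["A"]]
  Mun <- log2((m3[-idx, "B"] / effB) / (m3[-idx, "A"] / effA))
  expect_lt(abs(stats::median(Mun)), 0.05)
  expect_error(tmmFactors(m[, 1, drop = FALSE]), "two samples")
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulateExpressionCounts(3000, dispersion = 0.1, deFraction = 0.2,
                                  logfcSd = 2, libSizes = c(8e5, 1e6, 1.2e6,
                                                            9e5, 1.1e6, 1e6),
                                  seed = 8)
  keep <- rowSums(sim$counts) > 0
  f1 <- tmmFactors(sim$counts[keep, ])
  f2 <- edgeR::calcNormFactors(sim$counts[keep, ], method = "TMM")
  expect_lt(max(abs(log(f1 / f2))), 0.02)
})

test_that("dispersion estimation recovers Poisson and NB truths", {
  simP <- simulateExpressionCounts(3000, dispersion = 0, deFraction = 0,
                                   libSizes = rep(2e5, 8), seed = 9)
  expect_lt(estimateDispersion(simP$counts, simP$samples), 0.01)
  simN <- simulateExpressionCounts(3000, dispersion = 0.1, deFraction = 0,
                                   libSizes = rep(2e5, 8), seed = 10)
  phi <- estimateDispersion(simN$counts, simN$samples)
  expect_lt(abs(phi / 0.1 - 1), 0.2)
  # invariant to gene order
  set.seed(11)
  perm <- sample(nrow(simN$counts))
  expect_equal(estimateDispersion(simN$counts[perm, ], simN$samples), phi)
  expect_error(estimateDispersion(matrix(0L, 2, 4,
    dimnames = list(c("a", "b"), sprintf("S%d", 1:4))),
    data.frame(condition = rep(c("a", "b"), 2))), "all-zero")
})

test_that("the NB LRT flags planted fold changes and not flat features", {
  sim <- simulateExpressionCounts(2000, dispersion = 0.05, deFraction = 0.15,
                                  logfcSd = 1.5, libSizes = rep(3e5, 8),
                                  seed = 12)
  res <- nbLRT(sim$counts, sim$samples)
  tr <- sim$truth
  strong <- tr$de & abs(tr$log2FC) >= 1 &
    rowMeans(sim$counts) >= 50
  expect_gt(mean(res$significant[strong]), 0.8)
  fdrObs <- sum(res$significant & !tr$de) / max(1, sum(res$significant))
  expect_lt(fdrObs, 0.12)
  # a feature with identical counts in all samples: log2FC 0, p 1
  flat <- matrix(100L, 2, 8, dimnames = list(c("f1", "f2"),
                                             colnames(sim$counts)))
  resF <- nbLRT(flat, sim$samples, dispersion = 0.05)
  expect_equal(resF$log2FC, c(0, 0), tolerance = 1e-6)
  expect_equal(resF$p, c(1, 1))
  # log2FC recovery for well-measured planted changes
  good <- tr$de & abs(tr$log2FC) >= 0.8 & abs(tr$log2FC) <= 2 &
    rowMeans(sim$counts) >= 50
  expect_gt(stats::cor(res$log2FC[good], tr$log2FC[good]), 0.95)
  # at low dispersion the estimate is tight (biological scatter, not depth,
  # limits precision at phi = 0.05)
  simT <- simulateExpressionCounts(1500, dispersion = 0.01, deFraction = 0.2,
                                   logfcSd = 1, libSizes = rep(3e5, 8),
                                   seed = 121)
  resT <- nbLRT(simT$counts, simT$samples)
  trT <- simT$truth
  goodT <- trT$de & abs(trT$log2FC) >= 0.8 & abs(trT$log2FC) <= 1.2 &
    rowMeans(simT$counts) >= 50
  expect_lt(mean(abs(resT$log2FC[goodT] - trT$log2FC[goodT])), 0.15)
})

test_that("batch covariates are absorbed by the NB model", {
  sim <- simulateExpressionCounts(1500, dispersion = 0.05, deFraction = 0,
                                  libSizes = rep(2e5, 8), seed = 13)
  counts <- sim$counts
  # impose a multiplicative batch effect on half the samples
  batch <- rep(c("b1", "b2"), 4)
  set.seed(14)
  bump <- stats::rbinom(nrow(counts), 1, 0.3) == 1
  counts[bump, batch == "b2"] <-
    as.integer(round(counts[bump, batch == "b2"] * 2))
  samples <- cbind(sim$samples, batch = batch)
  res <- nbLRT(counts, samples)
  expect_lt(mean(res$p < 0.05), 0.08)
})

test_that("the robust cpm filter matches a brute-force row scan", {
  sim <- simulateExpressionCounts(500, libSizes = rep(5e4, 6), seed = 15)
  keep <- robustFeatureFilter(sim$counts, cpmThreshold = 1, minSamples = 4)
  cpm <- t(t(sim$counts) / colSums(sim$counts)) * 1e6
  brute <- rownames(sim$counts)[
    vapply(seq_len(nrow(cpm)), function(i) sum(cpm[i, ] > 1) >= 4, logical(1))]
  expect_identical(keep, brute)
  # all-zero feature is removed; boundary feature with cpm just above the
  # threshold in exactly minSamples samples is kept
  m <- rbind(z = rep(0L, 6), b = c(rep(200L, 4), 0L, 0L))
  colnames(m) <- sprintf("S%d", 1:6)
  m <- rbind(m, filler = rep(10000L, 6))
  expect_false("z" %in% robustFeatureFilter(m, 1, 4))
  expect_true("b" %in% robustFeatureFilter(m, 1, 4))
})
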