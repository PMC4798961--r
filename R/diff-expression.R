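## Differential analysis of gene counts and peak heights: TMM normalization,
## common-dispersion negative binomial GLM with batch covariates, likelihood
## ratio tests, and q-value FDR. This is a deliberately simplified
## re-implementation of the edgeR-style analysis (common dispersion, no
## empirical-Bayes shrinkage); calibration is validated by simulation.

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference column,
#' log-ratios (M) and average log-intensities (A) are computed over genes
#' with nonzero counts in both; the most extreme 30 percent of M and 5
#' percent of A are trimmed and the remaining M-values averaged with
#' inverse-variance (delta-method) weights. Factors are rescaled so their
#' geometric mean is one.
#'
#' @param counts gene-by-sample integer matrix (at least two samples).
#' @param reference column index of the reference sample, or "auto" (the
#'   sample whose upper quartile of scaled counts is closest to the mean
#'   upper quartile).
#' @param trimM,trimA two-sided trim fractions for M and A.
#' @return Named numeric vector of normalization factors (geometric mean 1).
#' @export
tmmFactors <- function(counts, reference = "auto", trimM = 0.3, trimA = 0.05) {
  .checkCounts(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size")
  if (identical(reference, "auto")) {
    uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0] / sum(x), 0.75))
    reference <- which.min(abs(uq - mean(uq)))
  }
  refC <- counts[, reference]
  refN <- libs[reference]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == reference) return(1)
    x <- counts[, j]; N <- libs[j]
    keep <- x > 0 & refC > 0
    if (!any(keep)) stop("sample ", j, " shares no expressed genes with the reference")
    xr <- x[keep] / N
    rr <- refC[keep] / refN
    M <- log2(xr / rr)
    A <- 0.5 * log2(xr * rr)
    # pure depth scaling gives M identically 0 -> factor 1
    if (max(abs(M)) < 1e-10) return(1)
    w <- 1 / ((N - x[keep]) / (N * x[keep]) +
                (refN - refC[keep]) / (refN * refC[keep]))
    loM <- stats::quantile(M, trimM, names = FALSE)
    hiM <- stats::quantile(M, 1 - trimM, names = FALSE)
    loA <- stats::quantile(A, trimA, names = FALSE)
    hiA <- stats::quantile(A, 1 - trimA, names = FALSE)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2)) keep2 <- rep(TRUE, length(M))
    2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

.designMatrix <- function(samples, withCondition = TRUE) {
  # baseline = first-appearing condition level, so the condition coefficient
  # is condition-2 relative to condition-1
  if (!is.null(samples$condition))
    samples$condition <- factor(samples$condition,
                                levels = unique(samples$condition))
  if (!is.null(samples$batch))
    samples$batch <- factor(samples$batch)
  if (withCondition && length(unique(samples$condition)) > 1) {
    if (!is.null(samples$batch) && length(unique(samples$batch)) > 1)
      stats::model.matrix(~ condition + batch, samples)
    else stats::model.matrix(~ condition, samples)
  } else {
    if (!is.null(samples$batch) && length(unique(samples$batch)) > 1)
      stats::model.matrix(~ batch, samples)
    else stats::model.matrix(~ 1, samples)
  }
}

#' Common NB dispersion by adjusted profile likelihood
#'
#' Fitted means are taken from per-gene Poisson GLM fits (which share the
#' mean structure of the NB model); the common dispersion then maximizes
#' the summed NB log-likelihood with a Cox-Reid adjustment
#' \eqn{-\tfrac12 \log\det(X^T W X)} per gene.
#'
#' @param counts gene-by-sample integer matrix.
#' @param samples data.frame with \code{condition} and optional \code{batch}.
#' @param normFactors optional TMM factors (effective library sizes are
#'   \code{factor * libsize}).
#' @return The estimated dispersion (phi, \code{>= 0}).
#' @export
estimateDispersion <- function(counts, samples, normFactors = NULL) {
  .checkCounts(counts)
  if (all(counts == 0)) stop("all-zero count matrix")
  X <- .designMatrix(samples)
  if (nrow(X) - ncol(X) < 2) stop("need at least 2 residual degrees of freedom")
  libs <- colSums(counts)
  eff <- if (is.null(normFactors)) libs else libs * normFactors
  off <- log(eff)
  keep <- rowSums(counts) > 0
  y <- counts[keep, , drop = FALSE]
  mu <- matrix(0, nrow(y), ncol(y))
  for (g in seq_len(nrow(y))) {
    fit <- suppressWarnings(stats::glm.fit(X, y[g, ], family = stats::poisson(),
                                           offset = off))
    mu[g, ] <- fit$fitted.values
  }
  mu <- pmax(mu, 1e-8)
  apl <- function(logPhi) {
    phi <- exp(logPhi)
    ll <- sum(stats::dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
    cr <- 0
    for (g in seq_len(nrow(y))) {
      W <- mu[g, ] / (1 + phi * mu[g, ])
      cr <- cr + 0.5 * determinant(crossprod(X * sqrt(W)),
                                   logarithm = TRUE)$modulus
    }
    ll - as.numeric(cr)
  }
  opt <- stats::optimize(apl, interval = log(c(1e-6, 5)), maximum = TRUE)
  phi <- exp(opt$maximum)
  # profile out the boundary: if the optimum sits at the lower end, call it 0
  if (phi <= 1.5e-6) phi <- 0
  phi
}

.nbFamily <- function(phi) {
  if (phi <= 0) stats::poisson() else MASS::negative.binomial(theta = 1 / phi)
}

#' Negative binomial GLM likelihood-ratio tests
#'
#' Per-feature NB GLM with log link and offset log(effective library size);
#' the condition effect is tested by the deviance difference between the
#' full model (condition + batch) and the reduced model (batch only)
#' against a chi-square null. FDR is controlled with q-values.
#'
#' @param counts feature-by-sample integer matrix.
#' @param samples data.frame with \code{condition} (2 levels) and optional
#'   \code{batch}.
#' @param normFactors optional TMM factors.
#' @param dispersion common NB dispersion; estimated if \code{NULL}.
#' @return data.frame(featureId, log2FC, lrt, p, fdr, significant) plus the
#'   dispersion used as attribute \code{"dispersion"}.
#' @export
nbLRT <- function(counts, samples, normFactors = NULL, dispersion = NULL) {
  .checkCounts(counts)
  if (length(unique(samples$condition)) != 2)
    stop("'condition' must have exactly two levels")
  if (is.null(dispersion))
    dispersion <- estimateDispersion(counts, samples, normFactors)
  libs <- colSums(counts)
  eff <- if (is.null(normFactors)) libs else libs * normFactors
  off <- log(eff)
  Xf <- .designMatrix(samples, withCondition = TRUE)
  Xr <- .designMatrix(samples, withCondition = FALSE)
  df <- ncol(Xf) - ncol(Xr)
  fam <- .nbFamily(dispersion)
  condCol <- grep("^condition", colnames(Xf))
  n <- nrow(counts)
  lfc <- p <- lrt <- rep(NA_real_, n)
  for (g in seq_len(n)) {
    y <- counts[g, ]
    if (all(y == 0)) { lfc[g] <- 0; lrt[g] <- 0; p[g] <- 1; next }
    ff <- suppressWarnings(stats::glm.fit(Xf, y, family = fam, offset = off))
    fr <- suppressWarnings(stats::glm.fit(Xr, y, family = fam, offset = off))
    lrt[g] <- max(0, fr$deviance - ff$deviance)
    p[g] <- stats::pchisq(lrt[g], df = df, lower.tail = FALSE)
    lfc[g] <- ff$coefficients[condCol[1]] / log(2)
  }
  # identical counts across samples with equal offsets give a numerically
  # tiny but nonzero deviance difference; clamp
  p[lrt < 1e-10] <- 1
  qv <- qvalues(p)
  out <- data.frame(featureId = rownames(counts), log2FC = lfc, lrt = lrt,
                    p = p, fdr = qv$qvalues,
                    significant = qv$qvalues < 0.05,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  attr(out, "pi0") <- qv$pi0
  out
}

#' Robust feature filter on cpm
#'
#' Keeps features with cpm above \code{cpmThreshold} in at least
#' \code{minSamples} samples — the "robustly bound" / "expressed" rule used
#' before differential testing to reduce multiple testing.
#'
#' @param counts feature-by-sample integer matrix.
#' @param cpmThreshold cpm cut-off (default 1).
#' @param minSamples required number of samples above the cut-off.
#' @return Character vector of retained feature identifiers.
#' @export
robustFeatureFilter <- function(counts, cpmThreshold = 1, minSamples = 5L) {
  .checkCounts(counts)
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  rownames(counts)[rowSums(cpm > cpmThreshold) >= minSamples]
}
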