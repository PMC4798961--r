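## Cassette-exon inclusion quantification and testing: inclusion fractions,
## the isoform-coverage filter, the logit-link GLM likelihood-ratio test,
## the FDR + deltaI significance rule, and peak-exon association.

# long junction table -> list of matrices (inc averaged from the two
# inclusion junctions, skip) with exons as rows, samples as columns
.junctionMatrices <- function(counts) {
  need <- c("exonId", "sample", "Jup", "Jdn", "Jskip")
  if (!all(need %in% names(counts)))
    stop("junction table needs columns: ", paste(need, collapse = ", "))
  inc <- (counts$Jup + counts$Jdn) / 2
  exons <- unique(counts$exonId)
  samples <- unique(counts$sample)
  mk <- function(v) {
    m <- matrix(0, length(exons), length(samples),
                dimnames = list(exons, samples))
    m[cbind(match(counts$exonId, exons), match(counts$sample, samples))] <- v
    m
  }
  list(inc = mk(inc), skip = mk(counts$Jskip))
}

#' Condition-wise inclusion fractions and deltaI
#'
#' Per sample, the inclusion read count is the average of the two inclusion
#' junctions, \code{(Jup + Jdn) / 2}. Per condition, the pooled inclusion
#' fraction is \eqn{I = \sum inc / \sum (inc + skip)}, and
#' \eqn{\Delta I = I(\mathrm{cond1}) - I(\mathrm{cond2})} (conditions in
#' the order of their first appearance).
#'
#' @param counts long junction data.frame (exonId, sample, Jup, Jdn, Jskip).
#' @param samples data.frame with \code{sample} and \code{condition}.
#' @return data.frame(exonId, I1, I2, deltaI, undefined); exons with an
#'   all-zero condition are flagged undefined.
#' @export
inclusionFraction <- function(counts, samples) {
  jm <- .junctionMatrices(counts)
  cond <- samples$condition[match(colnames(jm$inc), samples$sample)]
  lev <- unique(samples$condition)
  if (length(lev) != 2) stop("exactly two conditions are required")
  iSum <- matrix(vapply(lev, function(cn)
    rowSums(jm$inc[, cond == cn, drop = FALSE]), numeric(nrow(jm$inc))),
    ncol = 2)
  tSum <- matrix(vapply(lev, function(cn)
    rowSums((jm$inc + jm$skip)[, cond == cn, drop = FALSE]),
    numeric(nrow(jm$inc))), ncol = 2)
  undefined <- tSum[, 1] == 0 | tSum[, 2] == 0
  I1 <- ifelse(tSum[, 1] > 0, iSum[, 1] / tSum[, 1], NA_real_)
  I2 <- ifelse(tSum[, 2] > 0, iSum[, 2] / tSum[, 2], NA_real_)
  data.frame(exonId = rownames(jm$inc), I1 = I1, I2 = I2,
             deltaI = I1 - I2, undefined = undefined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Junction-coverage filter
#'
#' Keeps an exon only if, in every condition, the library-size-normalized
#' pooled reads of each isoform (inclusion and exclusion separately) reach
#' \code{minNormCov}. Counts are rescaled to the mean library size before
#' pooling.
#'
#' @param counts long junction data.frame.
#' @param samples data.frame with \code{sample} and \code{condition}.
#' @param libSizes named per-sample library sizes; defaults to the total
#'   junction reads per sample.
#' @param minNormCov required normalized pooled coverage per isoform and
#'   condition (default 5).
#' @return Character vector of retained exon identifiers.
#' @export
junctionFilter <- function(counts, samples, libSizes = NULL, minNormCov = 5) {
  jm <- .junctionMatrices(counts)
  if (is.null(libSizes)) {
    libSizes <- colSums(jm$inc + jm$skip)
  } else {
    libSizes <- as.numeric(libSizes[colnames(jm$inc)])
  }
  sc <- mean(libSizes) / libSizes
  incN <- t(t(jm$inc) * sc)
  skipN <- t(t(jm$skip) * sc)
  cond <- samples$condition[match(colnames(jm$inc), samples$sample)]
  ok <- rep(TRUE, nrow(incN))
  for (cn in unique(cond)) {
    sel <- cond == cn
    ok <- ok & rowSums(incN[, sel, drop = FALSE]) >= minNormCov &
      rowSums(skipN[, sel, drop = FALSE]) >= minNormCov
  }
  rownames(incN)[ok]
}

#' Splicing likelihood-ratio test per cassette exon
#'
#' Fits a binomial GLM with logit link to the (rounded) inclusion and
#' exclusion counts of each exon, with condition and optional batch in the
#' linear predictor, and tests the condition effect by the deviance
#' likelihood-ratio against \eqn{\chi^2_1}. deltaI comes from the pooled
#' condition fractions (not the fitted coefficients). Complete separation
#' (a condition entirely at 0 or 1) triggers a Haldane-style fallback (0.5
#' added to both isoform counts of every sample) and a flag. FDR across
#' exons uses q-values.
#'
#' @param counts long junction data.frame.
#' @param samples data.frame with \code{sample}, \code{condition}, optional
#'   \code{batch}.
#' @param exons optional subset of exon identifiers to test (e.g. the
#'   output of \code{\link{junctionFilter}}).
#' @return data.frame(exonId, I1, I2, deltaI, lrt, p, fdr, separation).
#' @export
splicingLRT <- function(counts, samples, exons = NULL) {
  jm <- .junctionMatrices(counts)
  if (!is.null(exons)) {
    jm$inc <- jm$inc[rownames(jm$inc) %in% exons, , drop = FALSE]
    jm$skip <- jm$skip[rownames(jm$skip) %in% exons, , drop = FALSE]
  }
  ord <- match(colnames(jm$inc), samples$sample)
  sm <- samples[ord, , drop = FALSE]
  Xf <- .designMatrix(sm, withCondition = TRUE)
  Xr <- .designMatrix(sm, withCondition = FALSE)
  fam <- stats::binomial()
  cond <- sm$condition
  lev <- unique(samples$condition)
  n <- nrow(jm$inc)
  lrt <- p <- rep(NA_real_, n)
  sepFlag <- logical(n)
  for (g in seq_len(n)) {
    inc <- round(jm$inc[g, ])   # round-half-to-even on the .5 averages
    skp <- round(jm$skip[g, ])
    tot <- inc + skp
    if (all(tot == 0)) { lrt[g] <- 0; p[g] <- 1; next }
    sep <- any(vapply(lev, function(cn) {
      sel <- cond == cn & tot > 0
      any(sel) && (all(inc[sel] == 0) || all(skp[sel] == 0))
    }, logical(1)))
    if (sep) {
      sepFlag[g] <- TRUE
      inc <- inc + 0.5
      skp <- skp + 0.5
      tot <- inc + skp
    }
    use <- tot > 0
    yy <- inc[use] / tot[use]
    ww <- tot[use]
    ff <- suppressWarnings(stats::glm.fit(Xf[use, , drop = FALSE], yy,
                                          weights = ww, family = fam))
    fr <- suppressWarnings(stats::glm.fit(Xr[use, , drop = FALSE], yy,
                                          weights = ww, family = fam))
    lrt[g] <- max(0, fr$deviance - ff$deviance)
    p[g] <- stats::pchisq(lrt[g], df = ncol(Xf) - ncol(Xr), lower.tail = FALSE)
  }
  p[lrt < 1e-10] <- 1
  longSub <- counts[counts$exonId %in% rownames(jm$inc), , drop = FALSE]
  frac <- inclusionFraction(longSub, samples)
  frac <- frac[match(rownames(jm$inc), frac$exonId), ]
  qv <- qvalues(p)
  data.frame(exonId = rownames(jm$inc), I1 = frac$I1, I2 = frac$I2,
             deltaI = frac$deltaI, lrt = lrt, p = p, fdr = qv$qvalues,
             separation = sepFlag, stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the significance rule to splicing results
#'
#' An exon is significant when \code{fdr < fdrThreshold} and
#' \code{|deltaI| >= diThreshold}; the direction label records whether
#' inclusion increased or decreased in condition 1 relative to condition 2.
#'
#' @param results output of \code{\link{splicingLRT}}.
#' @param fdrThreshold FDR cut-off (default 0.05).
#' @param diThreshold minimum absolute deltaI (default 0.1).
#' @return \code{results} with added \code{significant} and
#'   \code{direction} columns.
#' @export
classifySignificant <- function(results, fdrThreshold = 0.05,
                                diThreshold = 0.1) {
  sig <- !is.na(results$fdr) & results$fdr < fdrThreshold &
    !is.na(results$deltaI) & abs(results$deltaI) >= diThreshold
  results$significant <- sig
  results$direction <- ifelse(!sig, NA_character_,
                              ifelse(results$deltaI > 0, "increased",
                                     "decreased"))
  results
}

#' Associate regulated exons with nearby intronic peaks
#'
#' An exon is associated when at least one intronic peak summit lies within
#' \code{flank} nt of the exon (from its 5' boundary minus flank to its 3'
#' boundary plus flank). The side label is in transcript orientation:
#' peaks before the exon's 5' boundary are "upstream" regardless of genomic
#' strand.
#'
#' @param exons \code{GRanges} of cassette exons.
#' @param peaks intronic peak \code{GRanges} with a \code{summit} column.
#' @param flank association window in nt (default 2500).
#' @return data.frame(exon, peak, side) of index pairs; exons with no peak
#'   in range are absent.
#' @export
associatePeaksWithExons <- function(exons, peaks, flank = 2500L) {
  stopifnot(is(exons, "GRanges"), is(peaks, "GRanges"))
  if (length(exons) == 0 || length(peaks) == 0)
    return(data.frame(exon = integer(0), peak = integer(0),
                      side = character(0)))
  if (is.null(peaks$summit)) stop("peaks need a 'summit' column")
  sm <- GRanges(seqnames(peaks), IRanges(peaks$summit, width = 1L),
                strand = strand(peaks))
  win <- GRanges(seqnames(exons),
                 IRanges(pmax(1L, start(exons) - flank), end(exons) + flank),
                 strand = strand(exons))
  ov <- findOverlaps(sm, win, ignore.strand = TRUE)
  if (length(ov) == 0)
    return(data.frame(exon = integer(0), peak = integer(0),
                      side = character(0)))
  ex <- subjectHits(ov)
  pk <- queryHits(ov)
  minus <- as.character(strand(exons))[ex] == "-"
  before5 <- ifelse(minus, peaks$summit[pk] > end(exons)[ex],
                    peaks$summit[pk] < start(exons)[ex])
  after3 <- ifelse(minus, peaks$summit[pk] < start(exons)[ex],
                   peaks$summit[pk] > end(exons)[ex])
  side <- ifelse(before5, "upstream", ifelse(after3, "downstream", "within"))
  data.frame(exon = ex, peak = pk, side = side, stringsAsFactors = FALSE)
}
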