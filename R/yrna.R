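## Y RNA analysis: tag counting with a unique-mapping policy, the bound-Y
## definition, motif enrichment among bound Y RNAs, condition comparison
## (binding remodeling), library fractions, and subject grouping.

#' Count tags per Y RNA
#'
#' A tag is counted for a Y RNA when their intervals overlap. Under the
#' default unique-only policy, tags overlapping more than one Y RNA are
#' discarded; under "best-match" they are assigned to the Y RNA that
#' already has the highest unambiguous count (ties broken by Y RNA
#' identifier).
#'
#' @param tags \code{GRanges} with a \code{sample} column.
#' @param yrnas \code{GRanges} of Y RNA loci, named by Y RNA identifier.
#' @param policy "unique" (default) or "best".
#' @return Y-by-sample integer matrix.
#' @export
countTagsPerYRNA <- function(tags, yrnas, policy = c("unique", "best")) {
  policy <- match.arg(policy)
  stopifnot(is(tags, "GRanges"), is(yrnas, "GRanges"))
  ids <- names(yrnas)
  if (is.null(ids)) stop("'yrnas' must be named")
  samples <- unique(tags$sample)
  m <- matrix(0L, length(yrnas), length(samples),
              dimnames = list(ids, samples))
  if (length(tags) == 0) return(m)
  ov <- findOverlaps(tags, yrnas, ignore.strand = FALSE)
  nhit <- tabulate(queryHits(ov), nbins = length(tags))
  uniq <- ov[nhit[queryHits(ov)] == 1]
  addCounts <- function(hits) {
    tb <- table(factor(ids[subjectHits(hits)], levels = ids),
                factor(tags$sample[queryHits(hits)], levels = samples))
    m + as.integer(tb)
  }
  m <- m + addCounts(uniq)
  if (policy == "best") {
    multi <- ov[nhit[queryHits(ov)] > 1]
    if (length(multi)) {
      base <- rowSums(m)
      qh <- queryHits(multi)
      for (q in unique(qh)) {
        cand <- subjectHits(multi)[qh == q]
        best <- cand[order(-base[cand], ids[cand])][1]
        m[best, tags$sample[q]] <- m[best, tags$sample[q]] + 1L
      }
    }
  }
  m
}

#' Bound-Y definition
#'
#' A Y RNA is called bound when it has a nonzero tag count in at least
#' \code{minSamples} samples (default 2), counted across all samples.
#'
#' @param counts Y-by-sample count matrix.
#' @param minSamples required number of samples with tags.
#' @return Named logical vector.
#' @export
defineBound <- function(counts, minSamples = 2L) {
  stats::setNames(rowSums(counts > 0) >= minSamples, rownames(counts))
}

#' Motif enrichment among bound Y RNAs
#'
#' Builds the 2x2 table of bound/unbound by motif-positive/negative and
#' tests enrichment of the motif among bound Y RNAs with a one-sided
#' Fisher's exact test.
#'
#' @param motif named logical vector (motif status per Y RNA), e.g. from
#'   \code{\link{motifScan}} applied to the panel sequences.
#' @param bound named logical vector from \code{\link{defineBound}}.
#' @return list(table, p, degenerate).
#' @export
motifEnrichment <- function(motif, bound) {
  ids <- intersect(names(motif), names(bound))
  if (length(ids) == 0) stop("no shared Y RNA identifiers")
  tab <- matrix(c(sum(motif[ids] & bound[ids]), sum(!motif[ids] & bound[ids]),
                  sum(motif[ids] & !bound[ids]), sum(!motif[ids] & !bound[ids])),
                2, 2,
                dimnames = list(motif = c("motif+", "motif-"),
                                bound = c("bound", "unbound")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, p = 1, degenerate = TRUE))
  ft <- fisherExact(tab, alternative = "greater")
  list(table = tab, p = ft$p, degenerate = FALSE)
}

#' Compare Y RNA binding between conditions
#'
#' Counts are cpm-normalized per sample against the full CLIP library sizes
#' (Y RNA tags are a small fraction of a CLIP library, so these totals are
#' the right scale; when no sizes are supplied, samples are treated as
#' equal-depth and counts are used as-is), averaged within condition per
#' Y RNA, and compared by a paired one-sided Wilcoxon signed-rank test for
#' an increase in condition 2. Per-Y log2 fold changes use a 0.5
#' pseudocount.
#'
#' @param counts Y-by-sample matrix (bound Y RNAs only, typically).
#' @param samples data.frame with \code{sample}, \code{condition} (the
#'   first condition level encountered is the baseline).
#' @param libSizes optional named per-sample full-library sizes for cpm.
#' @return list(meanCpm (Y x 2), log2FC, p, statistic).
#' @export
compareConditions <- function(counts, samples, libSizes = NULL) {
  if (nrow(counts) < 5)
    warning("fewer than 5 bound Y RNAs; the paired test has little power")
  if (is.null(libSizes))
    libSizes <- stats::setNames(rep(1e6, ncol(counts)), colnames(counts))
  libSizes <- libSizes[colnames(counts)]
  cpm <- t(t(counts) / libSizes) * 1e6
  cond <- samples$condition[match(colnames(counts), samples$sample)]
  lev <- unique(samples$condition)
  if (length(lev) < 2) stop("need at least two conditions")
  m1 <- rowMeans(cpm[, cond == lev[1], drop = FALSE])
  m2 <- rowMeans(cpm[, cond == lev[2], drop = FALSE])
  wt <- wilcoxonPaired(m1, m2, alternative = "greater")
  list(meanCpm = cbind(stats::setNames(m1, rownames(counts)), m2),
       log2FC = log2((m2 + 0.5) / (m1 + 0.5)),
       p = wt$p, statistic = wt$statistic)
}

#' Per-sample fraction of tags on Y RNAs
#'
#' @param tags \code{GRanges} with a \code{sample} column (all tags of each
#'   library).
#' @param yrnas \code{GRanges} of Y RNA loci.
#' @return Named numeric vector, percent of each sample's tags overlapping
#'   any Y RNA (0-100).
#' @export
libraryFraction <- function(tags, yrnas) {
  stopifnot(is(tags, "GRanges"))
  tot <- table(tags$sample)
  if (any(tot == 0)) stop("sample with zero tags")
  onY <- countOverlaps(tags, yrnas, ignore.strand = FALSE) > 0
  hit <- table(factor(tags$sample[onY], levels = names(tot)))
  stats::setNames(100 * as.numeric(hit) / as.numeric(tot), names(tot))
}

#' Group subjects by total Y RNA binding
#'
#' Splits subjects into low and high Y RNA binding groups by exhaustive
#' 1-dimensional 2-means on log10 total Y cpm (the split minimizing the
#' within-group sum of squares). Deterministic; ties broken by subject
#' identifier. If all totals are equal a single group is returned with a
#' warning.
#'
#' @param counts Y-by-sample matrix.
#' @param libSizes optional per-sample library sizes for cpm.
#' @return Named character vector, "lowY"/"highY" per subject.
#' @export
groupSubjects <- function(counts, libSizes = NULL) {
  if (ncol(counts) < 2) stop("need at least two subjects")
  if (is.null(libSizes))
    libSizes <- stats::setNames(rep(1e6, ncol(counts)), colnames(counts))
  libSizes <- pmax(libSizes[colnames(counts)], 1)
  tot <- log10(colSums(counts) / libSizes * 1e6 + 1)
  if (max(tot) - min(tot) < 1e-12) {
    warning("identical Y RNA totals; returning a single group")
    return(stats::setNames(rep("lowY", ncol(counts)), colnames(counts)))
  }
  o <- order(tot, colnames(counts))
  x <- tot[o]
  n <- length(x)
  wss <- vapply(seq_len(n - 1), function(s) {
    a <- x[1:s]; b <- x[(s + 1):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  s <- which.min(wss)
  lab <- rep("highY", n)
  lab[1:s] <- "lowY"
  stats::setNames(lab[order(o)], colnames(counts))
}
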