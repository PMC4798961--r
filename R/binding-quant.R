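## Peak annotation, genomic distributions, binding normalization by library
## size and mRNA abundance, target ranking, meta-exon binding maps, and
## point-feature overlap.

#' Per-gene expression summary (cpm, rpkm, expressed flag)
#'
#' cpm is counts per million mapped reads; rpkm additionally divides by the
#' constitutive-exon length in kb. A gene is flagged expressed when its cpm
#' exceeds \code{cpmThreshold} in at least \code{minSamples} samples.
#'
#' @param counts gene-by-sample integer matrix.
#' @param annotation a \linkS4class{GeneAnnotation}; supplies the
#'   constitutive-exon lengths.
#' @param cpmThreshold cpm cut-off (default 1).
#' @param minSamples number of samples that must exceed the cut-off.
#' @return data.frame with geneId, meanCpm, meanRpkm, expressed, plus the
#'   per-sample cpm and rpkm matrices as attributes \code{"cpm"} and
#'   \code{"rpkm"}.
#' @export
computeExpression <- function(counts, annotation, cpmThreshold = 1,
                              minSamples = 5L) {
  .checkCounts(counts)
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size in count matrix")
  len <- constitutiveLength(annotation)
  miss <- setdiff(rownames(counts), names(len))
  if (length(miss)) stop("genes absent from annotation: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  cpm <- t(t(counts) / libs) * 1e6
  rpkm <- cpm / (len[rownames(counts)] / 1e3)
  expressed <- rowSums(cpm > cpmThreshold) >= minSamples
  out <- data.frame(geneId = rownames(counts),
                    meanCpm = rowMeans(cpm),
                    meanRpkm = rowMeans(rpkm),
                    expressed = expressed,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cpm") <- cpm
  attr(out, "rpkm") <- rpkm
  out
}

#' Annotate peaks with a genomic category
#'
#' The category is decided by the peak summit with precedence
#' 3'UTR > 5'UTR > CDS > noncoding-exon > intron; summits outside any
#' annotated feature of their gene get "other". The 3'UTR-first precedence
#' prevents double counting where isoform structures overlap.
#'
#' @param peaks \code{GRanges} with \code{summit} and \code{geneId} columns
#'   (as returned by \code{\link{callPeaks}}).
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @return \code{peaks} with a \code{category} metadata column.
#' @export
annotatePeaks <- function(peaks, annotation) {
  stopifnot(is(peaks, "GRanges"))
  if (length(peaks) == 0) {
    mcols(peaks)$category <- character(0)
    return(peaks)
  }
  if (is.null(peaks$summit)) stop("peaks need a 'summit' metadata column")
  sm <- GRanges(seqnames(peaks), IRanges(peaks$summit, width = 1L),
                strand = strand(peaks))
  cat <- rep("other", length(peaks))
  cdsAll <- unlist(cdsByGene(annotation))
  hasCds <- names(cdsByGene(annotation))[
    vapply(cdsByGene(annotation), function(x) length(x) > 0, logical(1))]
  layers <- list(
    intron = unlist(intronsByGene(annotation)),
    cds = cdsAll,
    `5'UTR` = unlist(utr5ByGene(annotation)),
    `3'UTR` = unlist(utr3ByGene(annotation)))
  # noncoding-exon: exons of genes without CDS
  ncGenes <- setdiff(names(exonsByGene(annotation)), hasCds)
  if (length(ncGenes)) {
    layers <- c(list(`noncoding-exon` =
                       unlist(exonsByGene(annotation)[ncGenes])), layers)
    layers <- layers[c("intron", "noncoding-exon", "cds", "5'UTR", "3'UTR")]
  }
  # ascending precedence: later layers overwrite earlier ones
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    if (length(lay) == 0) next
    hit <- unique(queryHits(findOverlaps(sm, lay, ignore.strand = FALSE)))
    cat[hit] <- if (nm == "cds") "CDS" else nm
  }
  mcols(peaks)$category <- cat
  peaks
}

#' Genomic distribution of peaks by category
#'
#' In raw mode, the fraction of peaks per category. In normalized mode,
#' per-category peak counts are divided by the total genomic length of the
#' category and rescaled to sum to one, so categories are compared per
#' nucleotide of annotation.
#'
#' @param peaks annotated peaks (with a \code{category} column).
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param normalizeByLength logical; divide by category length first.
#' @return Named numeric vector of fractions summing to 1.
#' @export
genomicDistribution <- function(peaks, annotation, normalizeByLength = FALSE) {
  if (is.null(peaks$category)) stop("peaks are not annotated")
  cats <- c("3'UTR", "5'UTR", "CDS", "noncoding-exon", "intron", "other")
  cnt <- table(factor(peaks$category, levels = cats))
  if (!normalizeByLength) {
    fr <- cnt / sum(cnt)
    return(stats::setNames(as.numeric(fr), cats))
  }
  lens <- c(
    `3'UTR` = sum(width(unlist(utr3ByGene(annotation)))),
    `5'UTR` = sum(width(unlist(utr5ByGene(annotation)))),
    CDS = sum(width(unlist(cdsByGene(annotation)))),
    `noncoding-exon` = 1,
    intron = sum(width(unlist(intronsByGene(annotation)))),
    other = 1)
  dens <- as.numeric(cnt) / pmax(lens[cats], 1)
  dens[as.numeric(cnt) == 0] <- 0
  stats::setNames(if (sum(dens) > 0) dens / sum(dens) else dens, cats)
}

#' Normalize peak heights by library size and mRNA abundance
#'
#' \code{phCpm} is the pooled-library cpm of the peak height; \code{normPH}
#' divides it by the gene's mean rpkm, removing the contribution of mRNA
#' abundance so that binding can be compared across genes. Peaks on genes
#' without measurable expression get \code{NA} and are flagged.
#'
#' @param peaks peak \code{GRanges} with \code{peakHeight} and \code{geneId}.
#' @param librarySizes named vector of per-sample unique-tag counts; the
#'   pooled total is used.
#' @param expression result of \code{\link{computeExpression}}.
#' @return \code{peaks} with added \code{phCpm}, \code{normPH} and
#'   \code{normUndefined} columns.
#' @export
normalizePeakHeights <- function(peaks, librarySizes, expression) {
  stopifnot(is(peaks, "GRanges"))
  pooled <- sum(librarySizes)
  if (pooled <= 0) stop("pooled library size must be positive")
  rpkm <- stats::setNames(expression$meanRpkm, expression$geneId)
  phCpm <- peaks$peakHeight * 1e6 / pooled
  denom <- unname(rpkm[peaks$geneId])
  undef <- is.na(denom) | denom <= 0
  normPH <- ifelse(undef, NA_real_, phCpm / denom)
  mcols(peaks)$phCpm <- phCpm
  mcols(peaks)$normPH <- normPH
  mcols(peaks)$normUndefined <- undef
  peaks
}

#' Summarize binding per gene and rank top targets
#'
#' Binding is the per-gene sum of peak heights; normalized binding the sum
#' of normalized peak heights, optionally restricted to one annotation
#' category (e.g. 3'UTR peaks only). Genes are ranked by descending
#' normalized binding with ties broken by gene identifier, and the top
#' \code{nTop} flagged.
#'
#' @param peaks annotated, normalized peaks.
#' @param nTop number of genes to flag as top targets (default 1000).
#' @param region "all" or "3'UTR" or "intron": restrict summed peaks.
#' @return data.frame(geneId, binding, normBinding, rank, topTarget) sorted
#'   by rank.
#' @export
rankTopTargets <- function(peaks, nTop = 1000L, region = c("all", "3'UTR",
                                                           "intron")) {
  region <- match.arg(region)
  stopifnot(is(peaks, "GRanges"))
  if (region != "all") {
    if (is.null(peaks$category)) stop("peaks are not annotated")
    peaks <- peaks[peaks$category == region]
  }
  ok <- !is.na(peaks$normPH)
  df <- data.frame(geneId = peaks$geneId,
                   ph = peaks$peakHeight,
                   nph = ifelse(ok, peaks$normPH, 0))
  agg <- stats::aggregate(cbind(ph, nph) ~ geneId, df, sum)
  agg <- agg[order(-agg$nph, agg$geneId), ]
  if (nTop > nrow(agg)) {
    warning("fewer genes than 'nTop'; returning all")
    nTop <- nrow(agg)
  }
  data.frame(geneId = agg$geneId, binding = agg$ph, normBinding = agg$nph,
             rank = seq_len(nrow(agg)),
             topTarget = seq_len(nrow(agg)) <= nTop,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap peaks with point features
#'
#' Reports every (peak, feature) pair whose feature position falls inside
#' the peak interval (start inclusive, end inclusive on the GRanges
#' convention; width-1 features such as SNPs are the intended input).
#'
#' @param peaks peak \code{GRanges}.
#' @param features \code{GRanges} of width-1 positions.
#' @return data.frame(peak, feature) of index pairs.
#' @export
intervalOverlap <- function(peaks, features) {
  ov <- findOverlaps(features, peaks, ignore.strand = TRUE)
  data.frame(peak = subjectHits(ov), feature = queryHits(ov))
}

#' Meta-exon binding map
#'
#' Aggregates normalized peak heights of peaks near regulated cassette
#' exons into distance bins around the exon boundaries, in transcript
#' orientation (negative distances upstream of the 5' boundary, positive
#' downstream of the 3' boundary), separately for inclusion-associated and
#' exclusion-associated exon sets.
#'
#' @param peaks normalized peaks (with \code{summit}, \code{normPH}).
#' @param exons \code{GRanges} of regulated exons with a \code{direction}
#'   column ("increased" or "decreased" inclusion).
#' @param flank window around each boundary in nt (default 2500).
#' @param binWidth bin width in nt.
#' @return data.frame(boundary, binStart (relative), direction, value).
#' @export
metaExonMap <- function(peaks, exons, flank = 2500L, binWidth = 100L) {
  stopifnot(is(peaks, "GRanges"), is(exons, "GRanges"))
  edges <- seq(-flank, flank, by = binWidth)
  mids <- utils::head(edges, -1)
  grid <- expand.grid(boundary = c("5p", "3p"), binStart = mids,
                      direction = c("increased", "decreased"),
                      stringsAsFactors = FALSE)
  grid$value <- 0
  if (length(peaks) == 0 || length(exons) == 0) return(grid)
  if (is.null(exons$direction)) stop("exons need a 'direction' column")
  sm <- peaks$summit
  nph <- ifelse(is.na(peaks$normPH), 0, peaks$normPH)
  for (i in seq_along(exons)) {
    minus <- as.character(strand(exons))[i] == "-"
    b5 <- if (minus) end(exons)[i] else start(exons)[i]
    b3 <- if (minus) start(exons)[i] else end(exons)[i]
    near <- which(as.character(seqnames(peaks)) ==
                    as.character(seqnames(exons))[i])
    for (j in near) {
      for (bd in c("5p", "3p")) {
        bpos <- if (bd == "5p") b5 else b3
        d <- if (minus) bpos - sm[j] else sm[j] - bpos
        if (d < -flank || d >= flank) next
        bin <- mids[findInterval(d, edges, rightmost.closed = FALSE)]
        sel <- grid$boundary == bd & grid$binStart == bin &
          grid$direction == exons$direction[i]
        grid$value[sel] <- grid$value[sel] + nph[j]
      }
    }
  }
  grid
}
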