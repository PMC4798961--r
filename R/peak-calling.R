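## Peak calling: tag clustering, scan-statistic significance under the
## uniform per-gene background, Bonferroni control, and the cross-sample
## biological-complexity (BC) filter.

# assign tags to genes by same-strand overlap; first gene wins (genes are
# disjoint in the intended annotations)
.assignTags <- function(tags, annotation) {
  genes <- geneRanges(annotation)
  ov <- findOverlaps(tags, genes, ignore.strand = FALSE)
  ov <- ov[!duplicated(queryHits(ov))]
  gid <- rep(NA_character_, length(tags))
  gid[queryHits(ov)] <- names(genes)[subjectHits(ov)]
  gid
}

#' Cluster tags of one gene
#'
#' Clusters are maximal runs of positions covered by at least one tag; every
#' tag belongs to exactly one cluster. For each cluster the peak height (PH,
#' maximum tag coverage), the leftmost maximal-coverage run, and its summit
#' are reported.
#'
#' @param tags \code{GRanges} of (pooled) tags lying within \code{gene}.
#' @param gene a length-1 \code{GRanges} with the gene span.
#' @return \code{GRanges} of clusters with metadata columns
#'   \code{peakHeight}, \code{nTags}, \code{peakStart}, \code{peakEnd} (the
#'   leftmost maximal run) and \code{summit}.
#' @export
clusterTags <- function(tags, gene) {
  stopifnot(is(gene, "GRanges"), length(gene) == 1)
  if (length(tags) == 0) {
    gr <- GRanges()
    mcols(gr)$peakHeight <- integer(0)
    return(gr)
  }
  if (any(start(tags) < start(gene) | end(tags) > end(gene)))
    stop("tag outside the gene span")
  ir <- ranges(tags)
  cl <- reduce(ir)
  cov <- coverage(ir, shift = -min(start(ir)) + 1)
  loc <- IRanges::shift(cl, -min(start(ir)) + 1)
  vw <- Views(cov, loc)
  ph <- viewMaxs(vw)
  # leftmost maximal run within each cluster
  pkStart <- pkEnd <- integer(length(cl))
  for (i in seq_along(cl)) {
    v <- cov[loc[i]]
    r <- slice(v, lower = ph[i])
    pkStart[i] <- start(r)[1] + start(cl)[i] - 1L
    pkEnd[i] <- end(r)[1] + start(cl)[i] - 1L
  }
  out <- GRanges(seqnames(gene), cl, strand = strand(gene))
  mcols(out)$peakHeight <- as.integer(ph)
  mcols(out)$nTags <- countOverlaps(out, tags)
  mcols(out)$peakStart <- pkStart
  mcols(out)$peakEnd <- pkEnd
  mcols(out)$summit <- pkStart
  out
}

#' Biological complexity of peaks
#'
#' BC is the number of samples contributing at least one tag overlapping the
#' peak interval — the reproducibility filter applied on top of statistical
#' significance.
#'
#' @param peaks \code{GRanges} of peak intervals.
#' @param tags \code{GRanges} of per-sample tags (with a \code{sample}
#'   column).
#' @return Integer vector of BC values, one per peak.
#' @export
biologicalComplexity <- function(peaks, tags) {
  stopifnot(is(peaks, "GRanges"), is(tags, "GRanges"))
  if (length(peaks) == 0) return(integer(0))
  if (length(tags) == 0) return(rep(0L, length(peaks)))
  samples <- unique(tags$sample)
  bc <- rep(0L, length(peaks))
  for (s in samples) {
    bc <- bc + as.integer(countOverlaps(peaks, tags[tags$sample == s]) > 0)
  }
  bc
}

#' Call peaks from multi-sample CLIP tags
#'
#' Tags are pooled across samples within each gene and clustered; each
#' cluster's peak height is referred to the scan-statistic null with
#' \code{n} = pooled tag starts in the gene, \code{L} = gene span and
#' \code{w} = the median tag length. Bonferroni correction uses the total
#' number of clusters tested. Retained peaks satisfy \code{pAdj < alpha}
#' and \code{BC >= minBC}.
#'
#' @param tags \code{GRanges} of collapsed tags from all samples, with a
#'   \code{sample} metadata column.
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param alpha significance threshold on the Bonferroni-adjusted p-value.
#' @param minBC minimum biological complexity (samples with presence).
#' @param tagLength scan window width; defaults to the median tag width.
#' @return \code{GRanges} of all tested clusters (peak intervals are the
#'   leftmost maximal-coverage runs) with metadata \code{geneId},
#'   \code{peakHeight}, \code{nTags}, \code{summit}, \code{pRaw},
#'   \code{pAdj}, \code{bc} and \code{retained}.
#' @export
callPeaks <- function(tags, annotation, alpha = 0.01, minBC = 5L,
                      tagLength = NULL) {
  stopifnot(is(annotation, "GeneAnnotation"))
  if (length(annotation) == 0) stop("empty annotation")
  if (is.null(tags$sample)) stop("tags need a 'sample' metadata column")
  if (is.null(tagLength)) {
    tagLength <- if (length(tags)) stats::median(width(tags)) else 50L
  }
  gid <- if (!is.null(tags$geneId)) tags$geneId else .assignTags(tags, annotation)
  keep <- !is.na(gid)
  tags <- tags[keep]
  gid <- gid[keep]
  if (length(tags) == 0) {
    out <- GRanges()
    mcols(out)$retained <- logical(0)
    return(out)
  }
  genes <- geneRanges(annotation)
  # genes are disjoint, so clusters and coverage can be taken genome-wide
  cl <- reduce(granges(tags), ignore.strand = FALSE)
  cov <- coverage(tags)
  phv <- integer(length(cl))
  runS <- runE <- integer(length(cl))
  for (ch in unique(as.character(seqnames(cl)))) {
    sel <- which(as.character(seqnames(cl)) == ch)
    v <- Views(cov[[ch]], ranges(cl)[sel])
    phv[sel] <- as.integer(viewMaxs(v))
    rr <- IRanges::viewRangeMaxs(v)  # leftmost maximal-coverage run
    runS[sel] <- start(rr)
    runE[sel] <- end(rr)
  }
  ovg <- findOverlaps(cl, genes, ignore.strand = FALSE)
  ovg <- ovg[!duplicated(queryHits(ovg))]
  clGene <- rep(NA_character_, length(cl))
  clGene[queryHits(ovg)] <- names(genes)[subjectHits(ovg)]
  ok <- !is.na(clGene)
  cl <- cl[ok]; phv <- phv[ok]; runS <- runS[ok]; runE <- runE[ok]
  clGene <- clGene[ok]
  nPerGene <- table(gid)
  Lg <- stats::setNames(width(genes), names(genes))
  pr <- numeric(length(cl))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(cl)) {
    g <- clGene[i]
    n <- as.integer(nPerGene[[g]])
    L <- Lg[[g]]
    w <- min(tagLength, L)
    key <- paste(n, L, phv[i], sep = "_")
    p <- cache[[key]]
    if (is.null(p)) {
      p <- scanPvalue(n, L, w, phv[i])
      cache[[key]] <- p
    }
    pr[i] <- p
  }
  out <- GRanges(seqnames(cl), IRanges(runS, runE), strand = strand(cl))
  mcols(out)$geneId <- clGene
  mcols(out)$clusterStart <- start(cl)
  mcols(out)$clusterEnd <- end(cl)
  mcols(out)$peakHeight <- phv
  mcols(out)$nTags <- countOverlaps(cl, tags)
  mcols(out)$summit <- runS
  mcols(out)$pRaw <- pr
  mcols(out)$bc <- biologicalComplexity(out, tags)
  mcols(out)$pAdj <- bonferroni(out$pRaw, length(out))
  mcols(out)$retained <- out$pAdj < alpha & out$bc >= minBC
  sort(out)
}
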