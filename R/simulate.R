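## Synthetic-data generators.
##
## These emulate the statistical structure the downstream analyses assume:
## CLIP tags uniform within genes except at implanted enriched windows;
## binomial inclusion/exclusion junction counts with logit-scale condition
## and batch effects; negative binomial gene counts; and a Y RNA panel with
## a controllable motif-bearing fraction and condition-dependent binding.

# split `total` into `m` integer parts, each >= minv (requires total >= m*minv)
.splitParts <- function(total, m, minv) {
  if (m == 1) return(total)
  extra <- total - m * minv
  as.integer(minv + stats::rmultinom(1, extra, rep(1, m))[, 1])
}

#' Simulate non-overlapping gene models
#'
#' Lays out \code{nGenes} single-isoform gene models on one synthetic
#' chromosome, each with at least two exons (hence at least one intron), a
#' short 5'UTR, a coding region, and a terminal 3'UTR occupying roughly
#' \code{utr3Fraction} of the gene span. Genes are disjoint, sorted, and
#' strands alternate between genes. Output is byte-identical for a fixed
#' seed.
#'
#' @param nGenes number of genes (\code{>= 0}).
#' @param geneLengthRange integer length-2 vector, min/max gene span (nt);
#'   minimum must be at least 300 so every gene fits an intron and a 3'UTR.
#' @param nExonsRange integer length-2 vector, min/max exons per gene
#'   (minimum 2).
#' @param utr3Fraction fraction of the gene span assigned to the 3'UTR.
#' @param seed integer random seed.
#' @return A \linkS4class{GeneAnnotation}.
#' @examples
#' ann <- simulateGeneModels(5, seed = 1)
#' geneRanges(ann)
#' @export
simulateGeneModels <- function(nGenes, geneLengthRange = c(2000L, 10000L),
                               nExonsRange = c(2L, 8L), utr3Fraction = 0.15,
                               seed = 1L) {
  if (nGenes < 0) stop("'nGenes' must be non-negative")
  if (min(geneLengthRange) < 300)
    stop("minimum gene length must be at least 300 nt")
  if (min(nExonsRange) < 2) stop("genes need at least 2 exons")
  if (utr3Fraction <= 0 || utr3Fraction >= 0.8)
    stop("'utr3Fraction' must lie in (0, 0.8)")
  empty <- GRanges()
  if (nGenes == 0) {
    gl <- GenomicRanges::GRangesList()
    return(new("GeneAnnotation", genes = empty, exons = gl, introns = gl,
               cds = gl, utr5 = gl, utr3 = gl, constitutiveLength = numeric(0)))
  }
  set.seed(seed)
  ids <- sprintf("G%04d", seq_len(nGenes))
  spans <- as.integer(round(stats::runif(nGenes, geneLengthRange[1],
                                         geneLengthRange[2])))
  nex <- as.integer(round(stats::runif(nGenes, nExonsRange[1], nExonsRange[2])))
  gaps <- as.integer(round(stats::runif(nGenes, 2000, 5000)))
  starts <- cumsum(c(1L, (spans + gaps)[-nGenes]))
  strands <- rep(c("+", "-"), length.out = nGenes)

  exL <- inL <- cdsL <- u5L <- u3L <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    Lg <- spans[i]; E <- nex[i]
    utr3len <- max(30L, as.integer(round(utr3Fraction * Lg)))
    exmin <- utr3len + 20L + E * 30L
    itMin <- (E - 1L) * 50L
    if (exmin + itMin >= Lg) { E <- 2L; exmin <- utr3len + 20L + E * 30L }
    it <- as.integer(round(stats::runif(1, itMin, max(itMin, Lg - exmin))))
    et <- Lg - it
    cdsParts <- .splitParts(et - utr3len - 20L, E, 30L)
    exW <- cdsParts
    exW[1] <- exW[1] + 20L         # 5'UTR on the first exon
    exW[E] <- exW[E] + utr3len     # 3'UTR on the last exon
    inW <- .splitParts(it, E - 1L, 50L)
    # transcript order -> genomic order
    widths <- integer(2L * E - 1L)
    widths[seq(1, 2 * E - 1, by = 2)] <- exW
    if (E > 1) widths[seq(2, 2 * E - 2, by = 2)] <- inW
    if (strands[i] == "-") widths <- rev(widths)
    offs <- cumsum(c(0L, widths[-length(widths)]))
    gstart <- starts[i]
    feat <- GRanges("chrS",
                    IRanges(gstart + offs, width = widths),
                    strand = strands[i])
    isExon <- rep(c(TRUE, FALSE), length.out = 2 * E - 1)
    exg <- feat[isExon]
    ing <- feat[!isExon]
    # UTRs in transcript sense
    firstEx <- if (strands[i] == "+") exg[1] else exg[length(exg)]
    lastEx  <- if (strands[i] == "+") exg[length(exg)] else exg[1]
    u5 <- resize(firstEx, 20L, fix = "start")
    u3 <- resize(lastEx, utr3len, fix = "end")
    cds <- GenomicRanges::setdiff(exg, c(u5, u3), ignore.strand = FALSE)
    exL[[i]] <- exg; inL[[i]] <- ing; cdsL[[i]] <- cds
    u5L[[i]] <- u5; u3L[[i]] <- u3
  }
  genes <- GRanges("chrS", IRanges(starts, width = spans), strand = strands)
  names(genes) <- ids
  mcols(genes)$gene_id <- ids
  mk <- function(lst) {
    names(lst) <- ids
    GenomicRanges::GRangesList(lst)
  }
  new("GeneAnnotation",
      genes = genes, exons = mk(exL), introns = mk(inL), cds = mk(cdsL),
      utr5 = mk(u5L), utr3 = mk(u3L),
      constitutiveLength = stats::setNames(vapply(exL, function(g)
        sum(width(g)), numeric(1)), ids))
}

#' Simulate one CLIP sample's tags
#'
#' Draws \code{depth} tag start positions across genes. Within a gene, start
#' positions are uniform except inside implanted peak windows, where the
#' density is multiplied by the window's enrichment; a window of width
#' \eqn{w} and enrichment \eqn{e} therefore receives tag mass proportional
#' to \eqn{e w} against \eqn{L - w} of background. Genes receive tags in
#' proportion to their total (enrichment-weighted) mass.
#'
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param depth total number of tags to draw (\code{>= 0}).
#' @param peaks \code{NULL} or a data.frame with columns \code{geneId},
#'   \code{offset} (nt from the gene's genomic left edge), \code{width}, and
#'   \code{enrichment} (fold over uniform, \code{>= 1}).
#' @param tagLength tag length in nt (fixed per sample).
#' @param sampleId sample identifier stored in the \code{sample} column.
#' @param seed integer random seed.
#' @return A \code{GRanges} of tags with metadata columns \code{sample} and
#'   \code{geneId}, sorted by position.
#' @examples
#' ann <- simulateGeneModels(3, seed = 1)
#' tags <- simulateClipTags(ann, depth = 100, seed = 2)
#' @export
simulateClipTags <- function(annotation, depth, peaks = NULL, tagLength = 50L,
                             sampleId = "S1", seed = 1L) {
  stopifnot(is(annotation, "GeneAnnotation"))
  if (depth < 0) stop("'depth' must be non-negative")
  genes <- geneRanges(annotation)
  ids <- names(genes)
  Lg <- width(genes)
  names(Lg) <- ids
  if (!is.null(peaks) && nrow(peaks)) {
    bad <- !peaks$geneId %in% ids
    if (any(bad)) stop("peak spec references unknown gene(s): ",
                       paste(unique(peaks$geneId[bad]), collapse = ", "))
    if (any(peaks$enrichment < 1)) stop("peak enrichment must be >= 1")
    if (any(peaks$offset < 0 | peaks$offset + peaks$width > Lg[peaks$geneId]))
      stop("peak window extends outside its gene")
  }
  set.seed(seed)
  wgt <- stats::setNames(as.numeric(Lg), ids)
  if (!is.null(peaks) && nrow(peaks)) {
    extra <- tapply((peaks$enrichment - 1) * peaks$width, peaks$geneId, sum)
    wgt[names(extra)] <- wgt[names(extra)] + as.numeric(extra)
  }
  if (depth == 0 || length(genes) == 0) {
    gr <- GRanges()
    mcols(gr)$sample <- character(0)
    mcols(gr)$geneId <- character(0)
    return(gr)
  }
  nper <- as.integer(stats::rmultinom(1, depth, wgt)[, 1])
  allSt <- integer(depth)
  allGene <- integer(depth)
  pos <- 0L
  hasPeak <- if (is.null(peaks)) character(0) else unique(peaks$geneId)
  for (i in seq_along(genes)) {
    ni <- nper[i]
    if (ni == 0) next
    gid <- ids[i]
    if (!gid %in% hasPeak) {
      offs <- floor(stats::runif(ni, 0, Lg[i]))
    } else {
      # piecewise-uniform: segments between/inside windows
      pk <- peaks[peaks$geneId == gid, , drop = FALSE]
      bnd <- sort(unique(c(0, pk$offset, pk$offset + pk$width, Lg[i])))
      segW <- diff(bnd)
      segE <- rep(1, length(segW))
      for (j in seq_len(nrow(pk))) {
        inside <- bnd[-length(bnd)] >= pk$offset[j] &
          bnd[-1] <= pk$offset[j] + pk$width[j]
        segE[inside] <- segE[inside] * pk$enrichment[j]
      }
      seg <- sample.int(length(segW), ni, replace = TRUE, prob = segW * segE)
      offs <- floor(bnd[seg] + stats::runif(ni) * segW[seg])
    }
    idx <- pos + seq_len(ni)
    allSt[idx] <- start(genes)[i] + as.integer(offs)
    allGene[idx] <- i
    pos <- pos + ni
  }
  allSt <- allSt[seq_len(pos)]
  allGene <- allGene[seq_len(pos)]
  res <- GRanges(seqnames(genes)[allGene],
                 IRanges(allSt, pmin(allSt + tagLength - 1L,
                                     end(genes)[allGene])),
                 strand = strand(genes)[allGene])
  mcols(res)$sample <- sampleId
  mcols(res)$geneId <- ids[allGene]
  sort(res)
}

#' Simulate cassette-exon junction counts
#'
#' For each exon and sample, the total junction depth is Poisson and the
#' inclusion reads are binomial with success probability
#' \eqn{logistic(\eta)}, \eqn{\eta} = baseline + condition effect + batch
#' offset. The two inclusion junctions are generated so that their average
#' equals the binomial inclusion count. A truth table of affected exons is
#' returned alongside.
#'
#' @param nExons number of cassette exons.
#' @param baselineLogitMean,baselineLogitSd baseline inclusion on the logit
#'   scale (per-exon normal draw).
#' @param affectedFraction fraction of exons with a nonzero condition effect.
#' @param effectLogit condition effect (logit scale) applied to group 2 of
#'   affected exons.
#' @param batchSd standard deviation of per-exon, per-batch logit offsets.
#' @param depthMean expected junction reads per exon per sample.
#' @param nPerGroup samples per condition.
#' @param nBatches number of batches (samples are assigned round-robin,
#'   balanced across conditions).
#' @param batchAssign optional character vector overriding the batch label
#'   per sample (length \code{2 * nPerGroup}), e.g. to emulate batches
#'   partially confounded with condition.
#' @param seed integer random seed.
#' @return A list with \code{counts} (long data.frame: exonId, sample, Jup,
#'   Jdn, Jskip), \code{samples} (sample, condition, batch), and
#'   \code{truth} (exonId, affected, baselineLogit, effectLogit,
#'   trueDeltaI).
#' @examples
#' sim <- simulateSplicingCounts(10, seed = 1)
#' head(sim$counts)
#' @export
simulateSplicingCounts <- function(nExons, baselineLogitMean = 0,
                                   baselineLogitSd = 1, affectedFraction = 0.1,
                                   effectLogit = 1, batchSd = 0,
                                   depthMean = 50, nPerGroup = 4,
                                   nBatches = 2, batchAssign = NULL,
                                   seed = 1L) {
  if (affectedFraction < 0 || affectedFraction > 1)
    stop("'affectedFraction' must lie in [0, 1]")
  if (depthMean <= 0) stop("'depthMean' must be positive")
  set.seed(seed)
  ns <- 2L * nPerGroup
  batches <- if (is.null(batchAssign))
    paste0("B", rep_len(seq_len(nBatches), ns)) else batchAssign
  if (length(batches) != ns) stop("'batchAssign' must name every sample")
  samples <- data.frame(
    sample = sprintf("S%02d", seq_len(ns)),
    condition = rep(c("ctrl", "case"), each = nPerGroup),
    batch = batches,
    stringsAsFactors = FALSE)
  exonId <- sprintf("E%05d", seq_len(nExons))
  base <- stats::rnorm(nExons, baselineLogitMean, baselineLogitSd)
  nAff <- round(affectedFraction * nExons)
  affected <- seq_len(nExons) %in% sample.int(nExons, nAff)
  eff <- ifelse(affected, effectLogit, 0)
  blevels <- unique(samples$batch)
  batchEff <- matrix(stats::rnorm(nExons * length(blevels), 0, batchSd),
                     nExons, length(blevels), dimnames = list(NULL, blevels))
  rows <- vector("list", ns)
  for (j in seq_len(ns)) {
    isCase <- samples$condition[j] == "case"
    eta <- base + (if (isCase) eff else 0) + batchEff[, samples$batch[j]]
    p <- stats::plogis(eta)
    tot <- stats::rpois(nExons, depthMean)
    inc <- stats::rbinom(nExons, tot, p)
    jup <- stats::rbinom(nExons, 2L * inc, 0.5)
    rows[[j]] <- data.frame(exonId = exonId, sample = samples$sample[j],
                            Jup = jup, Jdn = 2L * inc - jup,
                            Jskip = tot - inc, stringsAsFactors = FALSE)
  }
  truth <- data.frame(
    exonId = exonId, affected = affected, baselineLogit = base,
    effectLogit = eff,
    trueDeltaI = stats::plogis(base) - stats::plogis(base + eff),
    stringsAsFactors = FALSE)
  list(counts = do.call(rbind, rows), samples = samples, truth = truth)
}

#' Simulate a gene-count matrix with negative binomial noise
#'
#' Counts follow \eqn{NB(\mu, \phi)} with
#' \eqn{\mu = N_j \pi_g 2^{logFC_g \cdot group_j}}, where \eqn{\pi_g} are
#' relative abundances and a fraction of genes carry true log2 fold changes
#' drawn from \eqn{N(0, logfcSd^2)}.
#'
#' @param nGenes number of genes.
#' @param dispersion NB dispersion \eqn{\phi \ge 0} (0 gives Poisson).
#' @param deFraction fraction of genes that are differential.
#' @param logfcSd SD of true log2 fold changes for differential genes.
#' @param libSizes numeric vector of library sizes, one per sample; the
#'   first half of the samples form group 1, the rest group 2.
#' @param log2FC optional numeric vector (length \code{nGenes}) of true
#'   log2 fold changes, overriding the \code{deFraction}/\code{logfcSd}
#'   draw — e.g. to implant predominantly decreasing binding sites.
#' @param seed integer random seed.
#' @return A list with \code{counts} (gene x sample integer matrix),
#'   \code{samples} (sample, condition), and \code{truth} (geneId, de,
#'   log2FC).
#' @examples
#' sim <- simulateExpressionCounts(100, libSizes = rep(1e5, 6), seed = 1)
#' dim(sim$counts)
#' @export
simulateExpressionCounts <- function(nGenes, dispersion = 0.1,
                                     deFraction = 0.1, logfcSd = 1,
                                     libSizes = rep(1e6, 8), log2FC = NULL,
                                     seed = 1L) {
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (any(libSizes <= 0)) stop("library sizes must be positive")
  set.seed(seed)
  ns <- length(libSizes)
  grp <- rep(c(0, 1), c(ceiling(ns / 2), floor(ns / 2)))
  pi0 <- exp(stats::rnorm(nGenes, 0, 1.5))
  pi0 <- pi0 / sum(pi0)
  if (is.null(log2FC)) {
    nDe <- round(deFraction * nGenes)
    de <- seq_len(nGenes) %in% sample.int(nGenes, nDe)
    lfc <- ifelse(de, stats::rnorm(nGenes, 0, logfcSd), 0)
  } else {
    if (length(log2FC) != nGenes) stop("'log2FC' must have one value per gene")
    lfc <- log2FC
    de <- lfc != 0
  }
  counts <- matrix(0L, nGenes, ns,
                   dimnames = list(sprintf("G%05d", seq_len(nGenes)),
                                   sprintf("S%02d", seq_len(ns))))
  for (j in seq_len(ns)) {
    mu <- libSizes[j] * pi0 * 2^(lfc * grp[j])
    counts[, j] <- if (dispersion == 0) stats::rpois(nGenes, mu)
    else stats::rnbinom(nGenes, mu = mu, size = 1 / dispersion)
  }
  storage.mode(counts) <- "integer"
  list(counts = counts,
       samples = data.frame(sample = colnames(counts),
                            condition = ifelse(grp == 0, "ctrl", "case"),
                            stringsAsFactors = FALSE),
       truth = data.frame(geneId = rownames(counts), de = de, log2FC = lfc,
                          stringsAsFactors = FALSE))
}

#' Simulate a Y RNA panel
#'
#' Generates ~100-nt Y RNA sequences of which a controllable fraction carry
#' the U-rich binding element (a T hexamer with at most one G substitution),
#' plus a tag-count table across two conditions in which motif-positive
#' Y RNAs gain a multiplicative binding increase in condition 2.
#'
#' @param nYrna number of Y RNAs.
#' @param length sequence length in nt (Y RNAs are ~100 nt).
#' @param motifFraction fraction of sequences carrying the motif.
#' @param baseRate expected tags per Y RNA per sample in condition 1.
#' @param shift multiplicative binding increase in condition 2 for
#'   motif-positive Y RNAs (\code{>= 1}).
#' @param nPerGroup samples per condition.
#' @param seed integer random seed.
#' @return A list with \code{sequences} (\code{DNAStringSet}), \code{counts}
#'   (Y x sample matrix), \code{samples} (sample, condition), and
#'   \code{truth} (yrnaId, motif).
#' @examples
#' panel <- simulateYRNAPanel(20, seed = 1)
#' panel$truth$motif[1:5]
#' @export
simulateYRNAPanel <- function(nYrna, length = 100L, motifFraction = 0.3,
                              baseRate = 10, shift = 4, nPerGroup = 8,
                              seed = 1L) {
  if (motifFraction < 0 || motifFraction > 1)
    stop("'motifFraction' must lie in [0, 1]")
  if (shift < 1) stop("'shift' must be >= 1")
  set.seed(seed)
  ids <- sprintf("Y%03d", seq_len(nYrna))
  nPos <- round(motifFraction * nYrna)
  motif <- seq_len(nYrna) %in% seq_len(nPos)
  hex <- motifHexamers()
  seqs <- character(nYrna)
  for (i in seq_len(nYrna)) {
    s <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c(0.3, 0.3, 0.2, 0.2))
    # scrub any accidental motif occurrence
    repeat {
      hits <- motifScan(paste(s, collapse = ""))
      if (length(hits) == 0) break
      s[hits[1] + sample.int(6, 1) - 1L] <- sample(c("A", "C"), 1)
    }
    if (motif[i]) {
      pos <- sample.int(length - 5L, 1)
      s[pos:(pos + 5L)] <- strsplit(sample(hex, 1), "")[[1]]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  ns <- 2L * nPerGroup
  cond <- rep(c("ctrl", "case"), each = nPerGroup)
  counts <- matrix(0L, nYrna, ns,
                   dimnames = list(ids, sprintf("S%02d", seq_len(ns))))
  for (j in seq_len(ns)) {
    rate <- if (cond[j] == "case") ifelse(motif, shift * baseRate, baseRate)
    else rep(baseRate, nYrna)
    counts[, j] <- stats::rpois(nYrna, rate)
  }
  list(sequences = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
       counts = counts,
       samples = data.frame(sample = colnames(counts), condition = cond,
                            stringsAsFactors = FALSE),
       truth = data.frame(yrnaId = ids, motif = motif,
                          stringsAsFactors = FALSE))
}
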