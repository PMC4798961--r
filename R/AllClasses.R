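#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames strand start end width findOverlaps countOverlaps reduce coverage shift resize
#' @importFrom IRanges IRanges ranges Views slice viewWhichMaxs viewMaxs subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue DataFrame
NULL

#' Gene annotation bundle
#'
#' Holds one gene model per gene: the gene span, its exons, derived introns,
#' coding region and both UTRs, plus the constitutive-exon length used for
#' rpkm. All intervals of one gene share chromosome and strand; introns are
#' the within-span complement of the exons.
#'
#' @slot genes \linkS4class{GRanges} of gene spans, one per gene, named by
#'   gene identifier.
#' @slot exons,introns,cds,utr5,utr3 \code{GRangesList} keyed by gene
#'   identifier.
#' @slot constitutiveLength named numeric, total exonic length (nt) per gene.
#' @export
setClass("GeneAnnotation",
  representation(
    genes = "GRanges",
    exons = "GRangesList",
    introns = "GRangesList",
    cds = "GRangesList",
    utr5 = "GRangesList",
    utr3 = "GRangesList",
    constitutiveLength = "numeric"
  )
)

setValidity("GeneAnnotation", function(object) {
  ids <- names(object@genes)
  if (is.null(ids) && length(object@genes) > 0)
    return("genes must be named by gene identifier")
  if (anyDuplicated(ids)) return("gene identifiers must be unique")
  for (sl in c("exons", "introns", "cds", "utr5", "utr3")) {
    nm <- names(slot(object, sl))
    if (!all(nm %in% c(ids, character(0))))
      return(sprintf("'%s' contains gene ids absent from 'genes'", sl))
  }
  if (length(ids) && !all(names(object@constitutiveLength) %in% ids))
    return("constitutiveLength names must match gene ids")
  if (length(object@constitutiveLength) &&
      any(object@constitutiveLength <= 0))
    return("constitutive-exon length must be positive for every gene")
  ex <- object@exons
  for (g in names(ex)) {
    if (length(unique(as.character(seqnames(ex[[g]])))) > 1)
      return(sprintf("exons of gene '%s' span multiple chromosomes", g))
  }
  TRUE
})

#' @describeIn GeneAnnotation number of genes
#' @param x,object a \code{GeneAnnotation}
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@genes))

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "sequence(s)\n")
  if (length(object@genes)) {
    cat("  span: ", min(start(object@genes)), "-", max(end(object@genes)),
        "; median gene length ", stats::median(width(object@genes)), " nt\n",
        sep = "")
    cat("  median constitutive-exon length:",
        stats::median(object@constitutiveLength), "nt\n")
  }
})

#' @describeIn GeneAnnotation gene spans as a named \code{GRanges}
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GeneAnnotation exons per gene
#' @export
exonsByGene <- function(x) x@exons

#' @describeIn GeneAnnotation derived introns per gene
#' @export
intronsByGene <- function(x) x@introns

#' @describeIn GeneAnnotation coding regions per gene
#' @export
cdsByGene <- function(x) x@cds

#' @describeIn GeneAnnotation 5' untranslated regions per gene
#' @export
utr5ByGene <- function(x) x@utr5

#' @describeIn GeneAnnotation 3' untranslated regions per gene
#' @export
utr3ByGene <- function(x) x@utr3

#' @describeIn GeneAnnotation constitutive-exon length (nt) per gene
#' @export
constitutiveLength <- function(x) x@constitutiveLength
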