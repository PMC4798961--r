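## Readers and writers for the standard formats the pipeline touches.
## GTF (1-based, closed) and BED (0-based, half-open) conversion is delegated
## to rtracklayer so that only one coordinate convention (GRanges) exists
## inside the package.

#' Write a gene annotation to GTF
#'
#' Emits gene, exon, CDS and UTR features with \code{gene_id} and
#' \code{transcript_id} attributes (one transcript per gene).
#'
#' @param annotation a \linkS4class{GeneAnnotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  stopifnot(is(annotation, "GeneAnnotation"))
  feats <- list(gene = geneRanges(annotation),
                exon = unlist(exonsByGene(annotation)),
                CDS = unlist(cdsByGene(annotation)),
                five_prime_utr = unlist(utr5ByGene(annotation)),
                three_prime_utr = unlist(utr3ByGene(annotation)))
  grl <- lapply(names(feats), function(ty) {
    gr <- feats[[ty]]
    if (length(gr) == 0) return(NULL)
    ids <- if (ty == "gene") names(gr) else names(gr)
    mcols(gr) <- NULL
    mcols(gr)$type <- ty
    mcols(gr)$gene_id <- ids
    mcols(gr)$transcript_id <- paste0(ids, ".1")
    if (ty == "CDS") mcols(gr)$phase <- 0L
    names(gr) <- NULL
    gr
  })
  out <- sort(do.call(c, grl[!vapply(grl, is.null, logical(1))]),
              ignore.strand = TRUE)
  rtracklayer::export(out, path, format = "gtf")
  invisible(path)
}

#' Read a gene annotation from GTF
#'
#' Parses a GTF with \code{gene_id} attributes, derives introns as the
#' within-span complement of the exons, and computes the constitutive-exon
#' length per gene. Gene ordering is deterministic (by position).
#'
#' @param path GTF file path.
#' @return A \linkS4class{GeneAnnotation}.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gtf <- tryCatch(rtracklayer::import(path, format = "gtf"),
                  error = function(e) stop("GTF parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(gtf$gene_id)) stop("GTF lacks gene_id attributes: ", path)
  ty <- as.character(gtf$type)
  byType <- function(t) {
    gr <- gtf[ty == t]
    S4Vectors::split(granges(gr), gr$gene_id)
  }
  genes <- gtf[ty == "gene"]
  genes <- sort(genes, ignore.strand = TRUE)
  ids <- genes$gene_id
  g <- granges(genes)
  names(g) <- ids
  mcols(g)$gene_id <- ids
  exons <- byType("exon")[ids]
  introns <- GenomicRanges::psetdiff(g, exons[ids])
  toGRL <- function(x, t) {
    grl <- byType(t)
    miss <- setdiff(ids, names(grl))
    if (length(miss)) {
      emp <- S4Vectors::split(GRanges(), factor(character(0)))
      grl <- c(grl, GenomicRanges::GRangesList(
        stats::setNames(rep(list(GRanges()), length(miss)), miss)))
    }
    grl[ids]
  }
  new("GeneAnnotation",
      genes = g, exons = exons, introns = introns,
      cds = toGRL(gtf, "CDS"),
      utr5 = toGRL(gtf, "five_prime_utr"),
      utr3 = toGRL(gtf, "three_prime_utr"),
      constitutiveLength = stats::setNames(
        vapply(exons[ids], function(e) sum(width(e)), numeric(1)), ids))
}

#' Read / write CLIP tags as BED6
#'
#' Tags are stored with the sample identifier in the BED name column and the
#' tag count (always 1 before collapsing) in the score column. Round-trips
#' are identities after canonical position sort.
#'
#' @param tags a \code{GRanges} with a \code{sample} metadata column.
#' @param path file path.
#' @return \code{writeTags}: \code{path} invisibly; \code{readTags}: a
#'   sorted \code{GRanges} with a \code{sample} column.
#' @export
writeTags <- function(tags, path) {
  stopifnot(is(tags, "GRanges"))
  out <- granges(tags)
  mcols(out)$name <- if (!is.null(tags$sample)) tags$sample else "."
  mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' @rdname writeTags
#' @export
readTags <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    gr <- GRanges()
    mcols(gr)$sample <- character(0)
    return(gr)
  }
  bed <- tryCatch(rtracklayer::import(path, format = "bed"),
                  error = function(e) stop("BED parse error in '", path,
                                           "': ", conditionMessage(e)))
  gr <- granges(bed)
  mcols(gr)$sample <- if (!is.null(bed$name)) bed$name else NA_character_
  sort(gr)
}

#' Read / write count matrices as TSV
#'
#' Rectangular feature-by-sample tables with a header row and feature
#' identifiers in the first column. Cells must be non-negative integers and
#' feature identifiers unique.
#'
#' @param counts integer matrix with row and column names.
#' @param path file path.
#' @return \code{writeCounts}: \code{path} invisibly; \code{readCounts}: an
#'   integer matrix.
#' @export
writeCounts <- function(counts, path) {
  .checkCounts(counts)
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a feature column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table: ", path)
  rownames(m) <- df[[1]]
  .checkCounts(m)
  storage.mode(m) <- "integer"
  m
}

.checkCounts <- function(m) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("feature identifiers must be present and unique")
  if (any(is.na(m))) stop("count table contains missing cells")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m))) stop("counts must be integers")
  invisible(TRUE)
}
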