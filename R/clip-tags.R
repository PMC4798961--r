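## CLIP read/tag preprocessing: quality filtering, PCR-duplicate collapsing,
## unique-tag derivation and per-sample library sizes.

#' Filter raw reads on base quality
#'
#' A read is kept when every base of its degenerate linker (barcode) region
#' has quality at least \code{minQ} and the mean quality of the remaining
#' bases is at least \code{minQ}.
#'
#' @param reads data.frame with columns \code{sequence} and \code{qualities}
#'   (Phred+33-encoded string, same length as the sequence).
#' @param minQ minimum quality (default 20).
#' @param barcodeLen number of degenerate linker bases at the read start.
#' @return The subset of \code{reads} passing the filter.
#' @export
filterReadsByQuality <- function(reads, minQ = 20, barcodeLen = 5L) {
  stopifnot(is.data.frame(reads))
  if (is.null(reads$qualities) || any(is.na(reads$qualities)))
    stop("reads lack quality strings")
  if (any(nchar(reads$qualities) != nchar(reads$sequence)))
    stop("quality string length differs from sequence length")
  if (any(barcodeLen >= nchar(reads$sequence)))
    stop("'barcodeLen' must be shorter than every read")
  keep <- vapply(reads$qualities, function(q) {
    ph <- utf8ToInt(q) - 33L
    all(ph[seq_len(barcodeLen)] >= minQ) &&
      mean(ph[-seq_len(barcodeLen)]) >= minQ
  }, logical(1), USE.NAMES = FALSE)
  reads[keep, , drop = FALSE]
}

#' Collapse exact duplicate sequences
#'
#' PCR duplicates are removed by keeping one representative per distinct
#' full-length sequence, degenerate barcode included: reads identical except
#' in the barcode are independent captures and are NOT collapsed.
#'
#' @param reads data.frame with a \code{sequence} column.
#' @return De-duplicated reads; the number removed is attached as attribute
#'   \code{"removed"}.
#' @export
collapseExactSequences <- function(reads) {
  stopifnot(is.data.frame(reads), !is.null(reads$sequence))
  keep <- !duplicated(reads$sequence)
  out <- reads[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

# 5'-most genomic position of a tag (crosslink-proximal end)
.fivePrimePos <- function(tags) {
  ifelse(as.character(strand(tags)) == "-", end(tags), start(tags))
}

#' Collapse mapped tags sharing a start position
#'
#' Within each sample, tags with the same chromosome, strand and 5'-most
#' position (the crosslink-proximal end: interval start on \code{+},
#' interval end on \code{-}) are collapsed to one unique tag. Collapsing is
#' idempotent and never performed across samples, which would destroy the
#' biological-complexity statistic.
#'
#' @param tags \code{GRanges} with a \code{sample} metadata column.
#' @return The unique tags, sorted.
#' @export
collapseByStart <- function(tags) {
  stopifnot(is(tags, "GRanges"))
  if (length(tags) == 0) return(tags)
  if (is.null(tags$sample)) stop("tags need a 'sample' metadata column")
  tags <- sort(tags)
  key <- paste(tags$sample, seqnames(tags), strand(tags),
               .fivePrimePos(tags), sep = "\r")
  tags[!duplicated(key)]
}

#' Per-sample unique-tag counts
#'
#' @param tags collapsed tag \code{GRanges} with a \code{sample} column, or
#'   a list of such objects (one per sample).
#' @return Named integer vector of unique-tag counts per sample.
#' @export
librarySizes <- function(tags) {
  if (is.list(tags)) tags <- do.call(c, unname(tags))
  stopifnot(is(tags, "GRanges"))
  if (length(tags) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(tags$sample)
  stats::setNames(as.integer(tab), names(tab))
}
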