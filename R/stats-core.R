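## Enrichment and distributional statistics used throughout the pipeline,
## plus the degenerate U-rich motif scanner.

#' Hypergeometric upper-tail probability
#'
#' Computes \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(population
#' \code{N}, successes \code{K}, draws \code{n}), evaluated in log space so
#' that tails far below double underflow of intermediate terms (p down to
#' ~1e-300) remain accurate.
#'
#' @param k observed overlap (\code{0 <= k <= min(K, n)}).
#' @param N population size.
#' @param K number of successes in the population.
#' @param n number of draws.
#' @param log10p return log10 of the p-value instead.
#' @return The upper-tail probability (or its log10).
#' @examples
#' hypergeomTail(4, 10, 5, 4)   # 5/210
#' @export
hypergeomTail <- function(k, N, K, n, log10p = FALSE) {
  if (K > N || n > N) stop("'K' and 'n' cannot exceed 'N'")
  if (k < 0 || k > min(K, n)) stop("'k' must lie in [0, min(K, n)]")
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Overlap of two gene lists against a population
#'
#' Builds the hypergeometric overlap specification \eqn{(N, K, n, k)} with
#' \code{k = |A} \eqn{\cap} \code{B|}, \code{K = |B|}, \code{n = |A|},
#' \code{N = |population|} and returns the upper-tail p-value.
#'
#' @param listA,listB character vectors of identifiers, subsets of
#'   \code{population}.
#' @param population character vector of all eligible identifiers.
#' @return A list with \code{N}, \code{K}, \code{n}, \code{k}, and \code{p}.
#' @export
hypergeomOverlapReport <- function(listA, listB, population) {
  listA <- unique(listA); listB <- unique(listB)
  population <- unique(population)
  out <- setdiff(c(listA, listB), population)
  if (length(out)) stop("identifiers outside the population: ",
                        paste(utils::head(out, 5), collapse = ", "))
  k <- length(intersect(listA, listB))
  res <- list(N = length(population), K = length(listB), n = length(listA),
              k = k)
  res$p <- hypergeomTail(k, res$N, res$K, res$n)
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around \code{\link[stats]{fisher.test}} returning the
#' package's common test-result shape. One-sided tests use
#' \code{alternative = "greater"} on the [1,1] cell, matching the
#' enrichment direction convention of the overlap statistics.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @param alternative "two.sided", "greater" or "less".
#' @return list(method, estimate (odds ratio), p, sidedness).
#' @export
fisherExact <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must be a 2x2 non-negative integer table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(method = "fisher", estimate = NA_real_, p = 1,
                sidedness = alternative))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(method = "fisher", estimate = unname(ft$estimate), p = ft$p.value,
       sidedness = alternative)
}

#' Paired one-sided Wilcoxon signed-rank test
#'
#' The pairing makes this a signed-rank test on the within-pair differences
#' (a rank-sum test cannot be paired); zero differences are dropped and ties
#' mid-ranked, with an exact null distribution for 25 or fewer informative
#' pairs and a tie-corrected normal approximation above.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative "greater" tests whether \code{y} exceeds \code{x}.
#' @return list(method, statistic, p, sidedness, degenerate).
#' @export
wilcoxonPaired <- function(x, y, alternative = c("greater", "less",
                                                 "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  d <- y - x
  if (all(d == 0)) {
    return(list(method = "wilcoxon-signed-rank", statistic = NA_real_,
                p = 1, sidedness = alternative, degenerate = TRUE))
  }
  dn <- d[d != 0]
  r <- rank(abs(dn))               # mid-ranks for ties
  V <- sum(r[dn > 0])
  n <- length(dn)
  if (n <= 25) {
    # exact null by convolution over doubled (integer) ranks, valid with ties
    r2 <- as.integer(round(2 * r))
    f <- 1
    for (s in r2) {
      g <- numeric(length(f) + s)
      g[seq_along(f)] <- f
      g[seq_along(f) + s] <- g[seq_along(f) + s] + f
      f <- g
    }
    f <- f / sum(f)
    v2 <- as.integer(round(2 * V))
    pg <- sum(f[(v2 + 1):length(f)])           # P(V >= obs)
    pl <- sum(f[seq_len(v2 + 1)])              # P(V <= obs)
    p <- switch(alternative, greater = pg, less = pl,
                two.sided = min(1, 2 * min(pg, pl)))
  } else {
    ex <- sum(r) / 2
    vr <- sum(r^2) / 4
    z <- (V - ex) / sqrt(vr)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
  }
  list(method = "wilcoxon-signed-rank", statistic = V, p = min(1, p),
       sidedness = alternative, degenerate = FALSE)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the ECDF of \code{x} exceeds that of \code{y}
#' (\eqn{D^+ = \max_t \hat F_x(t) - \hat F_y(t)}), i.e. whether \code{x} is
#' stochastically smaller.
#'
#' @param x,y numeric samples.
#' @return list(method, statistic (D+), p, sidedness).
#' @export
ksOneSided <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, alternative = "greater"))
  list(method = "ks-one-sided", statistic = unname(kt$statistic),
       p = kt$p.value, sidedness = "greater")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Step-up adjusted values.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\pi_0} from the flat right tail of the
#' p-value histogram over a lambda grid (cubic smoothing spline, evaluated
#' at the largest lambda), then rescales BH-style step-up values. Returns
#' monotone q-values bounded by 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda grid of tuning values in (0, 1).
#' @return list(qvalues, pi0).
#' @export
qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(list(qvalues = numeric(0), pi0 = NA_real_))
  pi0l <- vapply(lambda, function(l) mean(p > l, na.rm = TRUE) / (1 - l),
                 numeric(1))
  pi0 <- if (length(lambda) >= 4) {
    sp <- stats::smooth.spline(lambda, pi0l, df = 3)
    stats::predict(sp, x = max(lambda))$y
  } else pi0l[length(pi0l)]
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * pmin(1, cummin(p[o] * m / rank(p, ties.method = "max")[o]))[ro]
  list(qvalues = pmin(q, 1), pi0 = pi0)
}

#' Degenerate U-rich motif scanner
#'
#' Scans a nucleotide sequence for windows equal to a homopolymer of the
#' base symbol (default \code{T}, i.e. U on the RNA strand) of the given
#' length, allowing at most \code{maxSub} positions to be replaced by the
#' allowed substitution symbol (default \code{G}). With the defaults this
#' accepts exactly the 7 hexamers TTTTTT plus its six single-G variants.
#' \code{N} never matches; \code{U} is treated as \code{T}.
#'
#' @param sequence character string or \code{DNAString}/\code{RNAString}.
#' @param length motif length (default 6; 5 gives the relaxed pentamer mode).
#' @param base the repeated base symbol.
#' @param allowed the permitted substitution symbol (e.g. "G", or "A"/"C"
#'   for the relaxed modes).
#' @param maxSub maximum number of substituted positions.
#' @return Integer vector of 1-based match start positions.
#' @examples
#' motifScan("AATTTTTTGC")      # matches at 3
#' motifScan("TTTGTT")          # one G: match
#' motifScan("TTGGTT")          # two Gs: no match
#' @export
motifScan <- function(sequence, length = 6L, base = "T", allowed = "G",
                      maxSub = 1L) {
  if (maxSub > length) stop("'maxSub' cannot exceed the motif length")
  s <- toupper(as.character(sequence))
  s <- chartr("U", "T", s)
  n <- nchar(s)
  if (n < length) return(integer(0))
  ch <- strsplit(s, "")[[1]]
  isBase <- ch == base
  isSub <- ch == allowed
  okRun <- isBase | isSub
  # windows where all positions are base/sub and #sub <= maxSub
  cs <- cumsum(c(0L, !okRun))
  csSub <- cumsum(c(0L, isSub))
  starts <- seq_len(n - length + 1L)
  hit <- (cs[starts + length] - cs[starts]) == 0L &
    (csSub[starts + length] - csSub[starts]) <= maxSub
  starts[hit]
}

#' Enumerate the k-mers accepted by the motif scanner
#'
#' @inheritParams motifScan
#' @return Character vector of accepted k-mers.
#' @export
motifHexamers <- function(length = 6L, base = "T", allowed = "G",
                          maxSub = 1L) {
  alph <- c("A", "C", "G", "T")
  km <- do.call(expand.grid, rep(list(alph), length))
  kmers <- do.call(paste0, km)
  keep <- vapply(kmers, function(x) length(motifScan(x, length = length,
                                                     base = base,
                                                     allowed = allowed,
                                                     maxSub = maxSub)) > 0,
                 logical(1), USE.NAMES = FALSE)
  sort(kmers[keep])
}
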