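## Scan statistic under the uniform per-gene background.
##
## The null model: n tag starts iid uniform on (0, L); the statistic is the
## maximum number of starts falling in any window of width w. PeakHeight is
## referred to this null. For small n the distribution is computed exactly by
## a cell/run decomposition (see vignette); for larger n a Naus-style product
## approximation over exact two- and three-window blocks is used.

.scanCache <- new.env(parent = emptyenv())

#' Scan-statistic p-value for a peak height
#'
#' Computes \eqn{P(S \ge k)} where \eqn{S} is the maximum number of tag start
#' positions covered by any sliding window of width \code{w}, given \code{n}
#' start positions dropped independently and uniformly on a region of length
#' \code{L}. This is the null probability used to score candidate CLIP peaks:
#' \code{k} is the observed peak height and the region is the gene span.
#'
#' The computation is exact for \code{k <= 2}, for \code{L <= 2w}, and for
#' \code{n <= 10} at any \code{L/w} (lattice-path enumeration over window
#' cells). For larger \code{n} a product approximation in the style of Naus
#' is used, built from exact joint probabilities of two and three consecutive
#' windows; its accuracy in the small-p regime relevant to peak calling is
#' validated against Monte Carlo in the package tests.
#'
#' @param n number of tag starts in the region (non-negative integer).
#' @param L region length in nucleotides; must satisfy \code{L >= w}.
#' @param w scan window width in nucleotides (positive).
#' @param k peak height to score (integer, \code{k >= 0}).
#' @return A single probability in \code{[0, 1]}, non-increasing in \code{k}
#'   and non-decreasing in \code{n}.
#' @examples
#' scanPvalue(2, 100, 10, 2)  # closed form 1 - ((L-w)/L)^2 = 0.19
#' scanPvalue(10, 1000, 50, 5)
#' @export
scanPvalue <- function(n, L, w, k) {
  stopifnot(length(n) == 1, length(L) == 1, length(w) == 1, length(k) == 1)
  if (w <= 0 || L <= 0) stop("'w' and 'L' must be positive")
  if (w > L) stop("window width 'w' exceeds region length 'L'")
  n <- as.integer(round(n)); k <- as.integer(round(k))
  if (n < 0) stop("'n' must be non-negative")
  if (k > n) return(0)
  if (k <= 0) return(1)
  if (k == 1) return(as.numeric(n >= 1))
  v <- w / L
  if (k == 2) {
    # P(min spacing > w) = (1 - (n-1)w/L)^n : classical spacings result
    return(1 - max(0, 1 - (n - 1) * v)^n)
  }
  if (L <= 2 * w) return(min(1, max(0, .pScanWide(n, L, w, k))))
  if (n <= 10) return(.exactScanSmallN(n, L, w, k))
  .pScanProduct(n, L, w, k)
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of raw p-values.
#' @param m number of tests; must be at least \code{length(p)}.
#' @return \code{pmin(1, p * m)}.
#' @examples bonferroni(c(0.001, 0.5), 10)
#' @export
bonferroni <- function(p, m) {
  if (length(m) != 1 || is.na(m) || m <= 0) stop("'m' must be a positive count")
  if (m < length(p)) stop("'m' must be at least the number of p-values")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

## ---- internal machinery -------------------------------------------------

# probability that a shuffled walk (x down-steps, y up-steps, starting at
# x + off) ever reaches level k; ballot problem via reflection
.hitProb <- function(x, y, k, off = 0) {
  kk <- k - off
  if (x >= kk || y >= kk) return(1)
  if (x + y < kk) return(0)
  exp(lchoose(x + y, kk) - lchoose(x + y, y))
}

.dmn <- function(n, counts, probs) {
  rest <- n - sum(counts)
  prest <- 1 - sum(probs)
  if (rest < 0) return(0)
  if (rest > 0 && prest <= 0) return(0)
  exp(lfactorial(n) - sum(lfactorial(counts)) - lfactorial(rest) +
        sum(ifelse(counts > 0, counts * log(probs), 0)) +
        (if (rest > 0) rest * log(prest) else 0))
}

# exact for w < L <= 2w: single sliding phase; middle zone never leaves window
.pScanWide <- function(n, L, w, k) {
  d <- L - w
  pa <- d / L
  pm <- (w - d) / L
  tot <- 0
  for (a in 0:n) for (m0 in 0:(n - a)) {
    c0 <- n - a - m0
    hp <- .hitProb(a, c0, k, off = m0)
    if (hp == 0) next
    tot <- tot + .dmn(n, c(a, m0, c0), c(pa, pm, pa)) * hp
  }
  tot
}

.posComps <- function(smax, k) {
  key <- paste0("C", smax, "_", k)
  val <- .scanCache[[key]]
  if (!is.null(val)) return(val)
  out <- list()
  gen <- function(prefix, rem) {
    for (e in 1:min(k - 1, rem)) {
      vv <- c(prefix, e)
      out[[length(out) + 1L]] <<- vv
      if (rem - e >= 1) gen(vv, rem - e)
    }
  }
  if (smax >= 1 && k >= 2) gen(integer(0), smax)
  .scanCache[[key]] <- out
  out
}

.runFrac <- function(v, k) {
  key <- paste0("R", paste(v, collapse = "."), "_", k)
  val <- .scanCache[[key]]
  if (!is.null(val)) return(val)
  val <- .run_frac_cpp(as.integer(v), as.integer(k))
  .scanCache[[key]] <- val
  val
}

# exact p-value for n <= 10 at arbitrary L/w via run assembly over cells
.exactScanSmallN <- function(n, L, w, k) {
  M <- as.integer(ceiling(L / w - 1e-12))
  rp <- L - (M - 1) * w
  q <- rp / w
  pw <- w / L
  pM <- rp / L
  comps <- .posComps(n, k)
  WW <- matrix(0, n, n)
  for (vv in comps) {
    fr <- .runFrac(vv, k)
    if (fr > 0) {
      WW[length(vv), sum(vv)] <-
        WW[length(vv), sum(vv)] + fr / exp(sum(lfactorial(vv)))
    }
  }
  # assembly: g[b+1, s+1] = weight of prefixes of b cells ending in an empty
  # cell with s points used; h[., .] same but cell b closes an interior run
  g <- matrix(0, M + 1, n + 1)
  h <- matrix(0, M + 1, n + 1)
  g[1, 1] <- 1
  for (b in seq_len(max(M - 2, 0))) {
    g[b + 1, ] <- g[b, ] + h[b, ]
    for (s in 1:n) {
      acc <- 0
      for (r in 1:min(b, s)) for (sv in r:s) {
        if (WW[r, sv] == 0) next
        prev <- if (b - r == 0) as.numeric(s - sv == 0) else g[b - r + 1, s - sv + 1]
        acc <- acc + prev * WW[r, sv] * pw^sv
      }
      h[b + 1, s + 1] <- acc
    }
  }
  fany <- function(b, s) {
    if (b == 0) return(as.numeric(s == 0))
    g[b + 1, s + 1] + h[b + 1, s + 1]
  }
  gmSafe <- function(b, s) {
    if (s < 0) return(0)
    if (b == 0) return(as.numeric(s == 0))
    if (b == M - 1) return(fany(M - 2, s))
    g[b + 1, s + 1]
  }
  tot <- fany(M - 2, n)  # last two cells empty
  for (vv in comps) {
    r <- length(vv)
    sv <- sum(vv)
    if (sv > n) next
    if (r <= M - 1) {  # terminal run ending at cell M-1, final cell empty
      fr <- .runFrac(vv, k)
      if (fr > 0) {
        tot <- tot + gmSafe(M - 1 - r, n - sv) * fr * pw^sv /
          exp(sum(lfactorial(vv)))
      }
    }
    if (r <= M) {      # terminal run ending at the (possibly truncated) cell M
      fr <- .term_frac_cpp(as.integer(vv), as.integer(k), q)
      if (fr > 0) {
        wgt <- pw^(sv - vv[r]) * pM^(vv[r]) / exp(sum(lfactorial(vv)))
        tot <- tot + gmSafe(M - r, n - sv) * fr * wgt
      }
    }
  }
  min(1, max(0, 1 - tot * exp(lfactorial(n))))
}

# vectorized ballot hit probabilities over a grid (below-k entries only)
.hitProbMat <- function(av, bv, k) {
  H <- outer(av, bv, function(x, y) {
    h <- exp(lchoose(x + y, k) - lchoose(x + y, y))
    h[x + y < k] <- 0
    h
  })
  pmin(H, 1)
}

# joint pmf of two multinomial cells with probability psi each, over a grid
.pairPmf <- function(n, psi, av, bv) {
  pa <- dbinom(av, n, psi)
  P <- outer(seq_along(av), seq_along(bv), function(i, j)
    pa[i] * dbinom(bv[j], n - av[i], psi / (1 - psi)))
  P[outer(av, bv, "+") > n] <- 0
  P
}

# P(hit within a block of two consecutive windows), exact
.eps2 <- function(n, psi, k) {
  lo <- max(0, qbinom(1e-14, n, psi))
  hi <- min(k - 1, qbinom(1 - 1e-14, n, psi) + 2)
  e <- 0
  if (hi >= lo) {
    ab <- lo:hi
    e <- sum(.pairPmf(n, psi, ab, ab) * .hitProbMat(ab, ab, k))
  }
  pk <- pbinom(k - 1, n, psi, lower.tail = FALSE)
  min(1, e + 2 * pk - .pPairTail(n, psi, k))
}

# P(cell1 >= k and cell2 >= k) for two multinomial cells of probability psi
.pPairTail <- function(n, psi, k) {
  if (2 * k > n) return(0)
  a <- k:(n - k)
  sum(dbinom(a, n, psi) *
        pbinom(k - 1, n - a, psi / (1 - psi), lower.tail = FALSE))
}

# P(all three cells >= k) for three multinomial cells of probability psi
.pTripleTail <- function(n, psi, k) {
  if (3 * k > n) return(0)
  tot <- 0
  for (a in k:(n - 2 * k)) {
    b <- k:(n - a - k)
    tot <- tot + dbinom(a, n, psi) *
      sum(dbinom(b, n - a, psi / (1 - psi)) *
            pbinom(k - 1, n - a - b, psi / (1 - 2 * psi), lower.tail = FALSE))
  }
  tot
}

# P(hit within a block of three consecutive windows); exact joint ordering
# for moderate k, independent-walk approximation for large k
.eps3 <- function(n, psi, k) {
  exactDep <- k <= 25
  lo <- max(0, qbinom(1e-14, n, psi))
  hi <- min(k - 1, qbinom(1 - 1e-14, n, psi) + 2)
  # P(any of the three cells >= k) by inclusion-exclusion on binomial margins
  e <- 3 * pbinom(k - 1, n, psi, lower.tail = FALSE) -
    3 * .pPairTail(n, psi, k) + .pTripleTail(n, psi, k)
  if (hi < lo) return(min(1, max(0, e)))
  rng <- lo:hi
  if (exactDep) {
    for (a in rng) {
      if (n - a < lo) next
      for (b in lo:min(hi, n - a)) {
        if (n - a - b < lo) next
        for (cc in lo:min(hi, n - a - b)) {
          p <- .dmn(n, c(a, b, cc), c(psi, psi, psi))
          if (p < 1e-17) next
          nh <- .runFrac(c(a, b, cc), k)
          if (nh < 1) e <- e + p * (1 - nh)
        }
      }
    }
  } else {
    # independent-walk approximation, vectorized:
    # E[1-(1-h1)(1-h2)] over cells below k = E[h1] + E[h2] - E[h1 h2]
    H <- .hitProbMat(rng, rng, k)
    Eh <- sum(.pairPmf(n, psi, rng, rng) * H)  # = E[h2] by symmetry
    q2c <- psi / (1 - psi)
    q3c <- psi / (1 - 2 * psi)
    eh1h2 <- 0
    pb <- dbinom(rng, n, psi)
    for (bi in seq_along(rng)) {
      b <- rng[bi]
      if (pb[bi] < 1e-17) next
      av <- rng[rng <= n - b]
      if (!length(av)) next
      pa <- dbinom(av, n - b, q2c)
      inner <- vapply(seq_along(av), function(ai) {
        a <- av[ai]
        cv <- rng[rng <= n - a - b]
        if (!length(cv)) return(0)
        sum(dbinom(cv, n - a - b, q3c) * H[bi, seq_along(cv)])
      }, numeric(1))
      eh1h2 <- eh1h2 + pb[bi] * sum(pa * H[seq_along(av), bi] * inner)
    }
    e <- e + 2 * Eh - eh1h2
  }
  min(1, max(0, e))
}

# Naus-style product approximation for n > 10
.pScanProduct <- function(n, L, w, k) {
  psi <- w / L
  m <- L / w
  e2 <- .eps2(n, psi, k)
  # deep in the significant tail the block-overlap correction is negligible
  if (e2 * (m - 1) < 1e-8) return(max(0, e2 * (m - 1)))
  q2 <- 1 - e2
  q3 <- 1 - .eps3(n, psi, k)
  if (q2 <= 0 || q3 <= 0) return(1)
  lq <- log(q2) + (m - 2) * (log(q3) - log(q2))
  min(1, max(0, -expm1(lq)))
}
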