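# shared helpers for the test suite; all fixtures are generated in code

# Monte-Carlo distribution of the scan maximum: P(S >= k) for each k,
# n iid uniform starts on (0, L), window w
mcScanTail <- function(n, L, w, ks, reps = 1e5, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::runif(reps * n, 0, L), reps, n)
  mx <- integer(reps)
  for (j in seq_len(n)) {
    cnt <- integer(reps)
    for (i in seq_len(n)) cnt <- cnt + (X[, i] >= X[, j] & X[, i] < X[, j] + w)
    mx <- pmax(mx, cnt)
  }
  vapply(ks, function(kk) mean(mx >= kk), numeric(1))
}

# tiny annotation reused across tests
tinyAnnotation <- function(nGenes = 6, seed = 11) {
  simulateGeneModels(nGenes, geneLengthRange = c(2000, 6000), seed = seed)
}

# multi-sample tag set with optional planted peaks
multiSampleTags <- function(ann, nSamples = 8, depthPer = 300, peaks = NULL,
                            seed = 100) {
  tl <- lapply(seq_len(nSamples), function(i) {
    simulateClipTags(ann, depthPer, peaks = peaks,
                     sampleId = sprintf("S%d", i), seed = seed + i)
  })
  collapseByStart(do.call(c, tl))
}
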