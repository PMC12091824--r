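# Fixtures built in code: random probability matrices, label vectors and
# aligned bundles, all deterministic per seed.

randomProbMatrix <- function(n, C) {
  G <- matrix(rgamma(n * C, shape = 1), n, C)
  G / rowSums(G)
}

randomPredictionSet <- function(n = 10, C = 3, id = "clf",
                                sampleIds = sprintf("s%03d", seq_len(n))) {
  PredictionSet(id, sampleIds, randomProbMatrix(n, C))
}

randomLabels <- function(n = 10, C = 3,
                         sampleIds = sprintf("s%03d", seq_len(n))) {
  LabelVector(sampleIds, sample.int(C, n, replace = TRUE) - 1L, C)
}

randomBundle <- function(k = 3, n = 10, C = 3) {
  PredictionBundle(lapply(seq_len(k), function(i)
    randomPredictionSet(n, C, id = paste0("clf_", i))))
}

# ChiSquareReport with prescribed chi2 values (for weight-contract tests).
reportFromChi2 <- function(chi2, belowChance = rep(FALSE, length(chi2)),
                           n = 100L) {
  k <- length(chi2)
  new("ChiSquareReport",
      classifierIds = paste0("clf_", seq_len(k)),
      nCorrect = rep(50L, k), nIncorrect = rep(n - 50L, k),
      expectedCorrect = rep(40, k), expectedIncorrect = rep(n - 40, k),
      chi2 = as.numeric(chi2), belowChance = belowChance)
}

# Brute-force pairwise AUC: fraction of positive-negative pairs ranked
# correctly, ties counting one half.
pairwiseAuc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
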