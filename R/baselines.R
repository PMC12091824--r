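## Comparison ensemblers: softmax (unweighted) averaging, majority voting
## over hard labels, and weighted averaging with externally supplied weights.

#' Softmax averaging baseline
#'
#' Unweighted mean of the members' probability matrices; identical to
#' [cweBlend()] with uniform weights.
#'
#' @param bundle A [PredictionBundle-class].
#' @param nodeId Classifier id recorded on the output.
#' @return A [PredictionSet-class].
#' @export
softmaxAverage <- function(bundle, nodeId = "softmax_avg") {
  stopifnot(is(bundle, "PredictionBundle"))
  k <- length(members(bundle))
  cweBlend(bundle, WeightVector(classifierIds(bundle), rep(1 / k, k)),
           nodeId = nodeId)
}

#' Majority voting baseline
#'
#' Each member casts one vote (its argmax class) per sample; the output row
#' holds the vote fractions. When classes tie on votes, the tie is resolved
#' toward the tied class with the highest mean probability across members
#' (then lowest index): the winner receives a vanishing vote bonus (1e-6 of
#' a vote) so the output row's argmax reflects the resolution while
#' remaining a valid probability distribution.
#'
#' @param bundle A [PredictionBundle-class].
#' @param nodeId Classifier id recorded on the output.
#' @return A [PredictionSet-class] of vote-share rows.
#' @export
majorityVote <- function(bundle, nodeId = "majority_vote") {
  stopifnot(is(bundle, "PredictionBundle"))
  mem <- members(bundle)
  n <- nSamples(bundle)
  C <- nClasses(bundle)
  votes <- matrix(0, n, C)
  meanP <- matrix(0, n, C)
  for (m in mem) {
    hl <- max.col(m@P, ties.method = "first")
    votes[cbind(seq_len(n), hl)] <- votes[cbind(seq_len(n), hl)] + 1
    meanP <- meanP + m@P
  }
  meanP <- meanP / length(mem)
  out <- votes
  top <- apply(votes, 1L, max)
  for (j in seq_len(n)) {
    tied <- which(votes[j, ] == top[j])
    if (length(tied) > 1L) {
      # highest mean probability among tied classes, then lowest index
      winner <- tied[which.max(meanP[j, tied])]
      out[j, winner] <- out[j, winner] + 1e-6
    }
  }
  out <- out / rowSums(out)
  colnames(out) <- classNames(mem[[1L]])
  PredictionSet(nodeId, sampleIds(bundle), out)
}

#' Weighted averaging baseline
#'
#' Blends with externally supplied weights (for example random or
#' rank-based); the contract is identical to [cweBlend()], but the weights
#' are not derived from chi-square scoring.
#'
#' @param bundle A [PredictionBundle-class].
#' @param weights A [WeightVector-class] over the bundle's classifier ids.
#' @param nodeId Classifier id recorded on the output.
#' @return A [PredictionSet-class].
#' @export
weightedAverage <- function(bundle, weights, nodeId = "weighted_avg") {
  cweBlend(bundle, weights, nodeId = nodeId)
}
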