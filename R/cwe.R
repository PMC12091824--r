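## Core chi-square weighted ensembling: score each classifier by a two-cell
## goodness-of-fit statistic on its correct/incorrect counts, convert the
## statistics to sum-to-one weights, and blend the probability matrices.

#' Hard class labels of a prediction set
#'
#' Argmax per row, with ties broken toward the lowest class index.
#'
#' @param pred A [PredictionSet-class].
#' @return Integer vector of 0-based predicted class indices, named by
#'   sample id.
#' @export
hardLabels <- function(pred) {
  stopifnot(is(pred, "PredictionSet"))
  stats::setNames(max.col(pred@P, ties.method = "first") - 1L,
                  pred@sampleIds)
}

#' Correctness indicator vector
#'
#' Marks each sample 1 when the predicted class equals the true class and 0
#' otherwise; this binary recoding is what the chi-square scoring operates
#' on.
#'
#' @param predLabels Integer vector of predicted 0-based class indices.
#' @param labels A [LabelVector-class] (or integer vector) of true classes.
#' @return Integer 0/1 vector.
#' @export
correctnessVector <- function(predLabels, labels) {
  y <- if (is(labels, "LabelVector")) labels@y else as.integer(labels)
  if (length(predLabels) != length(y))
    stop("predicted and true label vectors differ in length")
  as.integer(as.integer(predLabels) == y)
}

#' Expected correct/incorrect counts under a chance null
#'
#' The default null is label-marginal chance agreement: a predictor drawing
#' classes from the empirical label distribution independently of the truth
#' is correct with probability `sum(pi_c^2)`, so
#' `expectedCorrect = n * sum(pi_c^2)`. The `"uniform"` null instead uses
#' `n / C` (a predictor drawing classes uniformly).
#'
#' @param labels A [LabelVector-class].
#' @param null `"marginal"` (default) or `"uniform"`.
#' @return Named numeric vector with `expectedCorrect` and
#'   `expectedIncorrect` (summing to n).
#' @examples
#' lab <- LabelVector(paste0("s", 1:100), rep(c(0L, 1L), c(80, 20)), 2L)
#' expectedFrequencies(lab)  # 100 * (0.64 + 0.04) = 68 correct
#' @export
expectedFrequencies <- function(labels, null = c("marginal", "uniform")) {
  stopifnot(is(labels, "LabelVector"))
  null <- match.arg(null)
  n <- nSamples(labels)
  if (n < 1L) stop("labels must contain at least one sample")
  if (null == "uniform") {
    ec <- n / labels@nClasses
  } else {
    pi_c <- tabulate(labels@y + 1L, nbins = labels@nClasses) / n
    q <- sum(pi_c^2)
    if (q >= 1)
      stop("all labels identical: chance accuracy is 1 and the expected ",
           "incorrect count is 0; supply class priors or use the uniform ",
           "null")
    ec <- n * q
  }
  c(expectedCorrect = ec, expectedIncorrect = n - ec)
}

#' Two-cell chi-square goodness-of-fit statistic
#'
#' `sum((O - E)^2 / E)` over the correct and incorrect cells.
#'
#' @param observed Numeric length-2 vector of observed (correct, incorrect)
#'   counts.
#' @param expected Numeric length-2 vector of expected counts; both cells
#'   must be positive.
#' @return Nonnegative numeric scalar; zero iff observed equals expected.
#' @examples
#' chiSquareStatistic(c(70, 30), c(50, 50))  # 16
#' @export
chiSquareStatistic <- function(observed, expected) {
  if (length(observed) != 2L || length(expected) != 2L)
    stop("observed and expected must each have two cells")
  if (any(expected <= 0)) stop("expected cell counts must be positive")
  sum((observed - expected)^2 / expected)
}

#' Convert a chi-square report to ensembling weights
#'
#' In the default `one_sided` mode a classifier whose correct count falls
#' below the expected count (a below-chance classifier) contributes an
#' effective chi-square of zero, so a strongly wrong classifier is not
#' rewarded for its large discrepancy; `raw` mode normalizes the statistics
#' verbatim. When every effective statistic is zero, uniform weights are
#' returned with a warning.
#'
#' @param report A [ChiSquareReport-class].
#' @param mode `"one_sided"` (default) or `"raw"`.
#' @return A [WeightVector-class] (nonnegative, sum-to-one).
#' @export
computeWeights <- function(report, mode = c("one_sided", "raw")) {
  stopifnot(is(report, "ChiSquareReport"))
  mode <- match.arg(mode)
  eff <- report@chi2
  if (mode == "one_sided") eff[report@belowChance] <- 0
  total <- sum(eff)
  if (total <= 0) {
    warning("total chi-square is zero; falling back to uniform weights")
    eff <- rep(1, length(eff))
    total <- length(eff)
  }
  WeightVector(report@classifierIds, eff / total)
}

#' Score each bundle member by its chi-square statistic
#'
#' Runs the full scoring pipeline on calibration labels: hard labels,
#' correctness recoding, expected frequencies under the chance null, and the
#' two-cell chi-square statistic per classifier, then converts the
#' statistics to weights.
#'
#' @param bundle A [PredictionBundle-class] aligned to `labels`.
#' @param labels A [LabelVector-class] over the bundle's samples (or a
#'   subset of them, e.g. a calibration split).
#' @param mode Weighting mode passed to [computeWeights()].
#' @param null Chance null passed to [expectedFrequencies()].
#' @return List with elements `report` ([ChiSquareReport-class]) and
#'   `weights` ([WeightVector-class]).
#' @examples
#' lab <- LabelVector(c("a", "b", "c"), c(0L, 1L, 1L), 2L)
#' good <- PredictionSet("good", c("a", "b", "c"),
#'                       matrix(c(.9, .1, .2, .1, .9, .8), 3))
#' coin <- PredictionSet("coin", c("a", "b", "c"),
#'                       matrix(0.5, 3, 2))
#' fitCwe(PredictionBundle(list(good, coin)), lab)$weights
#' @export
fitCwe <- function(bundle, labels, mode = c("one_sided", "raw"),
                   null = c("marginal", "uniform")) {
  stopifnot(is(bundle, "PredictionBundle"), is(labels, "LabelVector"))
  mode <- match.arg(mode)
  null <- match.arg(null)
  bsamples <- sampleIds(bundle)
  if (!all(labels@sampleIds %in% bsamples))
    stop("labels contain sample ids absent from the bundle")
  sel <- match(labels@sampleIds, bsamples)
  ef <- expectedFrequencies(labels, null = null)
  n <- nSamples(labels)
  ids <- classifierIds(bundle)
  nCorrect <- integer(length(ids))
  chi2 <- numeric(length(ids))
  for (i in seq_along(ids)) {
    hl <- hardLabels(members(bundle)[[i]])[sel]
    correct <- correctnessVector(hl, labels)
    nCorrect[i] <- sum(correct)
    chi2[i] <- chiSquareStatistic(c(nCorrect[i], n - nCorrect[i]), ef)
  }
  report <- new("ChiSquareReport",
    classifierIds = ids,
    nCorrect = nCorrect,
    nIncorrect = n - nCorrect,
    expectedCorrect = rep(ef[["expectedCorrect"]], length(ids)),
    expectedIncorrect = rep(ef[["expectedIncorrect"]], length(ids)),
    chi2 = chi2,
    belowChance = nCorrect < ef[["expectedCorrect"]])
  list(report = report, weights = computeWeights(report, mode = mode))
}

#' Blend a bundle with chi-square-derived (or any sum-to-one) weights
#'
#' Output row j is the weighted mean `sum_i w_i * p_ij` of the members'
#' probability rows, so the result is itself a valid probability matrix.
#'
#' @param bundle A [PredictionBundle-class].
#' @param weights A [WeightVector-class] covering exactly the bundle's
#'   classifier ids.
#' @param nodeId Classifier id recorded on the blended output.
#' @return A [PredictionSet-class].
#' @export
cweBlend <- function(bundle, weights, nodeId = "cwe") {
  stopifnot(is(bundle, "PredictionBundle"), is(weights, "WeightVector"))
  ids <- classifierIds(bundle)
  if (!setequal(ids, weights@classifierIds) ||
      length(ids) != length(weights@classifierIds))
    stop("weights do not match the bundle's classifier ids")
  w <- weights@w[match(ids, weights@classifierIds)]
  out <- matrix(0, nSamples(bundle), nClasses(bundle))
  for (i in seq_along(ids))
    out <- out + w[i] * members(bundle)[[i]]@P
  colnames(out) <- classNames(members(bundle)[[1L]])
  PredictionSet(nodeId, sampleIds(bundle), out)
}
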