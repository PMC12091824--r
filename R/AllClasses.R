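## Central S4 data objects. Class indices are 0-based throughout, matching
## the on-disk column convention p_0 .. p_{C-1}.

#' True class labels for a set of samples
#'
#' Holds the ground-truth class index (0-based, in `[0, C)`) for each sample,
#' together with the canonical sample order that prediction matrices are
#' aligned to.
#'
#' @slot sampleIds Character vector of unique sample identifiers.
#' @slot y Integer vector of 0-based class indices, one per sample.
#' @slot nClasses Integer scalar, the number of classes C (at least 2).
#' @slot classNames Character vector of length C with class names, or
#'   `character(0)` when unnamed.
#'
#' @seealso [LabelVector()], [readLabels()]
#' @export
setClass("LabelVector",
  slots = c(
    sampleIds = "character",
    y = "integer",
    nClasses = "integer",
    classNames = "character"
  )
)

setValidity("LabelVector", function(object) {
  msg <- character(0)
  if (length(object@nClasses) != 1L || is.na(object@nClasses) ||
      object@nClasses < 2L)
    msg <- c(msg, "nClasses must be a single integer >= 2")
  if (length(object@y) != length(object@sampleIds))
    msg <- c(msg, "y and sampleIds must have equal length")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (length(object@y) &&
      (anyNA(object@y) || min(object@y) < 0L ||
       max(object@y) >= object@nClasses))
    msg <- c(msg, sprintf("class indices must lie in [0, %d)",
                          object@nClasses))
  if (length(object@classNames) &&
      length(object@classNames) != object@nClasses)
    msg <- c(msg, "classNames must have length nClasses (or be empty)")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVector
#'
#' @param sampleIds Character vector of unique sample identifiers.
#' @param y Integer vector of 0-based class indices.
#' @param nClasses Number of classes C; defaults to `max(y) + 1` (or the
#'   number of `classNames` when given).
#' @param classNames Optional ordered class names of length C.
#' @return A [LabelVector-class] object.
#' @examples
#' LabelVector(c("s1", "s2", "s3"), c(0L, 1L, 0L), nClasses = 2L)
#' @export
LabelVector <- function(sampleIds, y, nClasses = NULL, classNames = NULL) {
  y <- as.integer(y)
  if (is.null(classNames)) classNames <- character(0)
  if (is.null(nClasses)) {
    nClasses <- if (length(classNames)) length(classNames)
                else max(y, 1L) + 1L
  }
  new("LabelVector", sampleIds = as.character(sampleIds), y = y,
      nClasses = as.integer(nClasses), classNames = as.character(classNames))
}

#' One classifier's class-probability matrix
#'
#' An N x C matrix of class probabilities produced by a single classifier,
#' keyed by sample identifiers. Every entry lies in `[0, 1]` and every row
#' sums to one (within 1e-6).
#'
#' @slot classifierId Length-one character identifier of the classifier.
#' @slot sampleIds Character vector of N sample identifiers.
#' @slot P Numeric N x C matrix of class probabilities.
#'
#' @seealso [PredictionSet()], [readPredictions()], [hardLabels()]
#' @export
setClass("PredictionSet",
  slots = c(
    classifierId = "character",
    sampleIds = "character",
    P = "matrix"
  )
)

setValidity("PredictionSet", function(object) {
  msg <- character(0)
  if (length(object@classifierId) != 1L || !nzchar(object@classifierId))
    msg <- c(msg, "classifierId must be a single non-empty string")
  if (nrow(object@P) != length(object@sampleIds))
    msg <- c(msg, "P must have one row per sample id")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (nrow(object@P) == 0L)
    msg <- c(msg, "PredictionSet must contain at least one sample")
  if (ncol(object@P) < 2L)
    msg <- c(msg, "P must have at least 2 class columns")
  if (!is.numeric(object@P) || anyNA(object@P))
    msg <- c(msg, "P must be numeric without missing values")
  else if (length(object@P)) {
    if (min(object@P) < -1e-12 || max(object@P) > 1 + 1e-12)
      msg <- c(msg, "probabilities must lie in [0, 1]")
    rs <- rowSums(object@P)
    if (max(abs(rs - 1)) > 1e-6)
      msg <- c(msg, "every row of P must sum to 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionSet
#'
#' @param classifierId Single string naming the classifier.
#' @param sampleIds Character vector of N sample identifiers.
#' @param P Numeric N x C matrix of class probabilities (rows sum to 1).
#' @return A [PredictionSet-class] object.
#' @export
PredictionSet <- function(classifierId, sampleIds, P) {
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  rownames(P) <- as.character(sampleIds)
  new("PredictionSet", classifierId = as.character(classifierId),
      sampleIds = as.character(sampleIds), P = P)
}

#' An aligned collection of prediction sets
#'
#' A bundle holds one [PredictionSet-class] per classifier, all sharing the
#' same sample order and class count, ready for ensembling.
#'
#' @slot members Named list of [PredictionSet-class] objects, keyed by
#'   classifier id.
#'
#' @seealso [alignBundle()], [cweBlend()], [fitCwe()]
#' @export
setClass("PredictionBundle", slots = c(members = "list"))

setValidity("PredictionBundle", function(object) {
  msg <- character(0)
  mem <- object@members
  if (!length(mem))
    return("bundle must contain at least one member")
  if (!all(vapply(mem, is, logical(1), "PredictionSet")))
    return("all members must be PredictionSet objects")
  ids <- vapply(mem, function(m) m@classifierId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "classifier ids must be unique")
  if (!identical(unname(names(mem)), unname(ids)))
    msg <- c(msg, "members must be named by their classifier ids")
  ref <- mem[[1L]]
  same <- vapply(mem, function(m)
    identical(m@sampleIds, ref@sampleIds) && ncol(m@P) == ncol(ref@P),
    logical(1))
  if (!all(same))
    msg <- c(msg, "all members must share sample order and class count")
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionBundle from member prediction sets
#'
#' Members must already be aligned (same sample ids in the same order, same
#' number of classes); use [alignBundle()] to align raw members to a
#' [LabelVector-class] first.
#'
#' @param members List of [PredictionSet-class] objects.
#' @return A [PredictionBundle-class].
#' @export
PredictionBundle <- function(members) {
  if (is(members, "PredictionSet")) members <- list(members)
  names(members) <- vapply(members, function(m) m@classifierId, character(1))
  new("PredictionBundle", members = members)
}

#' Per-classifier chi-square goodness-of-fit summary
#'
#' For each classifier, the observed correct/incorrect counts on a labelled
#' sample set, the counts expected under the chance-agreement null, the
#' two-cell chi-square statistic, and whether the classifier fell below
#' chance (fewer correct than expected).
#'
#' @slot classifierIds Character vector of classifier ids.
#' @slot nCorrect Integer vector of observed correct counts O1.
#' @slot nIncorrect Integer vector of observed incorrect counts O2.
#' @slot expectedCorrect Numeric vector of expected correct counts E1.
#' @slot expectedIncorrect Numeric vector of expected incorrect counts E2.
#' @slot chi2 Numeric vector of chi-square statistics (nonnegative).
#' @slot belowChance Logical vector, `TRUE` when `nCorrect < expectedCorrect`.
#'
#' @seealso [fitCwe()], [computeWeights()]
#' @export
setClass("ChiSquareReport",
  slots = c(
    classifierIds = "character",
    nCorrect = "integer",
    nIncorrect = "integer",
    expectedCorrect = "numeric",
    expectedIncorrect = "numeric",
    chi2 = "numeric",
    belowChance = "logical"
  )
)

setValidity("ChiSquareReport", function(object) {
  msg <- character(0)
  k <- length(object@classifierIds)
  lens <- c(length(object@nCorrect), length(object@nIncorrect),
            length(object@expectedCorrect), length(object@expectedIncorrect),
            length(object@chi2), length(object@belowChance))
  if (!all(lens == k))
    return("all slots must have one entry per classifier")
  if (k == 0L)
    return("report must cover at least one classifier")
  n <- object@nCorrect + object@nIncorrect
  if (length(unique(n)) > 1L)
    msg <- c(msg, "all classifiers must be scored on the same sample count")
  if (any(abs(object@expectedCorrect + object@expectedIncorrect - n) > 1e-9))
    msg <- c(msg, "expected counts must sum to n within 1e-9")
  if (any(object@chi2 < 0))
    msg <- c(msg, "chi2 must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Nonnegative, sum-to-one ensembling weights
#'
#' @slot classifierIds Character vector of classifier ids.
#' @slot w Numeric vector of weights; all nonnegative, summing to one within
#'   1e-12.
#'
#' @seealso [computeWeights()], [cweBlend()], [weightedAverage()]
#' @export
setClass("WeightVector",
  slots = c(classifierIds = "character", w = "numeric")
)

setValidity("WeightVector", function(object) {
  msg <- character(0)
  if (length(object@w) != length(object@classifierIds))
    msg <- c(msg, "w and classifierIds must have equal length")
  if (!length(object@w))
    msg <- c(msg, "weight vector must not be empty")
  else {
    if (min(object@w) < -1e-12)
      msg <- c(msg, "weights must be nonnegative")
    if (abs(sum(object@w) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1")
  }
  if (anyDuplicated(object@classifierIds))
    msg <- c(msg, "classifier ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightVector
#'
#' @param classifierIds Character vector of classifier ids.
#' @param w Numeric weights; must be nonnegative and sum to one (exact
#'   renormalization is applied to absorb floating-point error).
#' @return A [WeightVector-class].
#' @export
WeightVector <- function(classifierIds, w) {
  w <- as.numeric(w)
  s <- sum(w)
  if (is.finite(s) && s > 0) w <- w / s
  new("WeightVector", classifierIds = as.character(classifierIds), w = w)
}

#' One node of an ensemble topology
#'
#' @slot nodeId Length-one character node identifier.
#' @slot layer Integer layer index (>= 1).
#' @slot method One of `"cwe"`, `"softmax_avg"`, `"majority_vote"`,
#'   `"weighted_avg"`.
#' @slot inputIds Character vector of leaf classifier ids or lower-layer
#'   node ids feeding this node.
#' @slot fixedWeights A [WeightVector-class] for `"weighted_avg"` nodes, or
#'   `NULL`.
#' @export
setClass("TopologyNode",
  slots = c(
    nodeId = "character",
    layer = "integer",
    method = "character",
    inputIds = "character",
    fixedWeights = "ANY"
  )
)

setValidity("TopologyNode", function(object) {
  msg <- character(0)
  if (length(object@nodeId) != 1L || !nzchar(object@nodeId))
    msg <- c(msg, "nodeId must be a single non-empty string")
  if (length(object@layer) != 1L || object@layer < 1L)
    msg <- c(msg, "layer must be a positive integer")
  if (!object@method %in% c("cwe", "softmax_avg", "majority_vote",
                            "weighted_avg"))
    msg <- c(msg, "unknown ensembling method")
  if (!length(object@inputIds))
    msg <- c(msg, "node must have at least one input")
  if (!is.null(object@fixedWeights) &&
      !is(object@fixedWeights, "WeightVector"))
    msg <- c(msg, "fixedWeights must be NULL or a WeightVector")
  if (length(msg)) msg else TRUE
})

#' Construct a TopologyNode
#'
#' @param nodeId Node identifier.
#' @param layer Positive integer layer index; inputs must resolve to leaves
#'   or nodes in strictly lower layers.
#' @param method Ensembling method applied at this node.
#' @param inputIds Ids of the leaf classifiers or upstream nodes to combine.
#' @param fixedWeights Optional [WeightVector-class] (only for
#'   `method = "weighted_avg"`).
#' @return A [TopologyNode-class].
#' @export
TopologyNode <- function(nodeId, layer, method, inputIds,
                         fixedWeights = NULL) {
  new("TopologyNode", nodeId = as.character(nodeId),
      layer = as.integer(layer), method = as.character(method),
      inputIds = as.character(inputIds), fixedWeights = fixedWeights)
}

#' A DAG of ensemble nodes
#'
#' Describes how leaf classifiers are progressively combined: each node
#' ensembles leaves or strictly lower-layer nodes, and a single terminal node
#' produces the final prediction.
#'
#' @slot leafIds Character vector of leaf classifier ids expected in the
#'   bundle.
#' @slot nodes Named list of [TopologyNode-class] objects.
#' @slot terminalId Id of the terminal node.
#'
#' @seealso [buildLayeredTopology()], [validateTopology()],
#'   [executeTopology()]
#' @export
setClass("EnsembleTopology",
  slots = c(leafIds = "character", nodes = "list", terminalId = "character")
)

#' Construct an EnsembleTopology
#'
#' @param leafIds Leaf classifier ids.
#' @param nodes List of [TopologyNode-class] objects.
#' @param terminalId Id of the terminal node. Defaults to the unique node no
#'   other node consumes.
#' @return A validated [EnsembleTopology-class].
#' @export
EnsembleTopology <- function(leafIds, nodes, terminalId = NULL) {
  names(nodes) <- vapply(nodes, function(n) n@nodeId, character(1))
  if (is.null(terminalId)) {
    consumed <- unique(unlist(lapply(nodes, function(n) n@inputIds)))
    terminals <- setdiff(names(nodes), consumed)
    if (length(terminals) != 1L)
      stop("topology must have exactly one terminal node, found ",
           length(terminals))
    terminalId <- terminals
  }
  topo <- new("EnsembleTopology", leafIds = as.character(leafIds),
              nodes = nodes, terminalId = as.character(terminalId))
  validateTopology(topo)
  topo
}

#' Classification quality summary
#'
#' Accuracy, per-class one-vs-rest precision/recall/F1/specificity (and AUC
#' when probabilities are available), and their support-weighted aggregates.
#' Support weighting makes the weighted recall equal the overall accuracy.
#'
#' @slot accuracy Numeric scalar in `[0, 1]`.
#' @slot perClass `data.frame` with one row per class: `class`, `support`,
#'   `precision`, `recall`, `f1`, `specificity`, `auc`.
#' @slot weighted Named numeric vector with support-weighted `precision`,
#'   `recall`, `f1`, `specificity`.
#' @slot macroAuc Numeric scalar (mean of defined per-class AUCs) or `NA`.
#'
#' @seealso [classificationMetrics()], [metricReport()], [rocAucOvr()]
#' @export
setClass("MetricReport",
  slots = c(
    accuracy = "numeric",
    perClass = "data.frame",
    weighted = "numeric",
    macroAuc = "numeric"
  )
)

setValidity("MetricReport", function(object) {
  msg <- character(0)
  vals <- c(object@accuracy, object@weighted)
  if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "metric values must lie in [0, 1]")
  if (abs(object@weighted[["recall"]] - object@accuracy) > 1e-12)
    msg <- c(msg, "support-weighted recall must equal accuracy")
  if (length(msg)) msg else TRUE
})
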