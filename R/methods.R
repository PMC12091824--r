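#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn LabelVector-class Sample identifiers.
#' @param x Object.
#' @export
setMethod("sampleIds", "LabelVector", function(x) x@sampleIds)

#' @describeIn PredictionSet-class Sample identifiers.
#' @param x Object.
#' @export
setMethod("sampleIds", "PredictionSet", function(x) x@sampleIds)

#' @describeIn PredictionBundle-class Shared sample identifiers.
#' @param x Object.
#' @export
setMethod("sampleIds", "PredictionBundle",
          function(x) x@members[[1L]]@sampleIds)

#' @describeIn PredictionSet-class The classifier id.
#' @export
setMethod("classifierIds", "PredictionSet", function(x) x@classifierId)

#' @describeIn PredictionBundle-class Member classifier ids.
#' @export
setMethod("classifierIds", "PredictionBundle", function(x) names(x@members))

#' @describeIn ChiSquareReport-class Classifier ids covered by the report.
#' @param x Object.
#' @export
setMethod("classifierIds", "ChiSquareReport", function(x) x@classifierIds)

#' @describeIn WeightVector-class Classifier ids the weights refer to.
#' @param x Object.
#' @export
setMethod("classifierIds", "WeightVector", function(x) x@classifierIds)

#' @describeIn LabelVector-class Number of classes.
#' @export
setMethod("nClasses", "LabelVector", function(x) x@nClasses)

#' @describeIn PredictionSet-class Number of class columns.
#' @export
setMethod("nClasses", "PredictionSet", function(x) ncol(x@P))

#' @describeIn PredictionBundle-class Number of class columns.
#' @export
setMethod("nClasses", "PredictionBundle",
          function(x) ncol(x@members[[1L]]@P))

#' @describeIn LabelVector-class Number of samples.
#' @export
setMethod("nSamples", "LabelVector", function(x) length(x@y))

#' @describeIn PredictionSet-class Number of samples (rows).
#' @export
setMethod("nSamples", "PredictionSet", function(x) nrow(x@P))

#' @describeIn PredictionBundle-class Number of samples (rows).
#' @export
setMethod("nSamples", "PredictionBundle",
          function(x) nrow(x@members[[1L]]@P))

#' @describeIn LabelVector-class Class names (possibly empty).
#' @export
setMethod("classNames", "LabelVector", function(x) x@classNames)

#' @describeIn PredictionSet-class Column (class) names, possibly `NULL`.
#' @export
setMethod("classNames", "PredictionSet", function(x) colnames(x@P))

#' @describeIn PredictionSet-class The probability matrix.
#' @export
setMethod("probMatrix", "PredictionSet", function(x) x@P)

#' @describeIn PredictionBundle-class The member list.
#' @export
setMethod("members", "PredictionBundle", function(x) x@members)

#' @describeIn WeightVector-class Weights as a named numeric vector.
#' @export
setMethod("ensembleWeights", "WeightVector",
          function(x) stats::setNames(x@w, x@classifierIds))

#' Extract the true label vector as integers
#'
#' @param labels A [LabelVector-class].
#' @return Integer vector of 0-based class indices named by sample id.
#' @export
trueLabels <- function(labels) {
  stopifnot(is(labels, "LabelVector"))
  stats::setNames(labels@y, labels@sampleIds)
}

setMethod("show", "LabelVector", function(object) {
  cat(sprintf("LabelVector: %d samples, %d classes\n",
              nSamples(object), nClasses(object)))
  if (length(object@classNames))
    cat("  classes:", paste(object@classNames, collapse = ", "), "\n")
  tab <- tabulate(object@y + 1L, nbins = object@nClasses)
  cat("  counts: ", paste(tab, collapse = " "), "\n")
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet '%s': %d samples x %d classes\n",
              object@classifierId, nSamples(object), nClasses(object)))
})

setMethod("show", "PredictionBundle", function(object) {
  cat(sprintf("PredictionBundle: %d classifiers, %d samples, %d classes\n",
              length(object@members), nSamples(object), nClasses(object)))
  ids <- classifierIds(object)
  if (length(ids) > 6L) ids <- c(ids[1:6], "...")
  cat("  members:", paste(ids, collapse = ", "), "\n")
})

setMethod("show", "ChiSquareReport", function(object) {
  cat(sprintf("ChiSquareReport: %d classifiers on %d samples\n",
              length(object@classifierIds),
              object@nCorrect[1L] + object@nIncorrect[1L]))
  df <- as.data.frame(object)
  print(utils::head(df, 10L))
  if (nrow(df) > 10L) cat("  ...\n")
})

setMethod("show", "WeightVector", function(object) {
  cat(sprintf("WeightVector over %d classifiers\n", length(object@w)))
  print(round(ensembleWeights(object), 4))
})

setMethod("show", "EnsembleTopology", function(object) {
  layers <- vapply(object@nodes, function(n) n@layer, integer(1))
  cat(sprintf("EnsembleTopology: %d leaves, %d nodes, terminal '%s'\n",
              length(object@leafIds), length(object@nodes),
              object@terminalId))
  tab <- table(layers)
  cat("  nodes per layer:",
      paste(sprintf("L%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport: accuracy %.4f\n", object@accuracy))
  cat(sprintf("  weighted: precision %.4f recall %.4f f1 %.4f specificity %.4f\n",
              object@weighted[["precision"]], object@weighted[["recall"]],
              object@weighted[["f1"]], object@weighted[["specificity"]]))
  if (!is.na(object@macroAuc))
    cat(sprintf("  macro AUC %.4f\n", object@macroAuc))
})

#' Coerce a ChiSquareReport to a data.frame
#'
#' @param x A [ChiSquareReport-class].
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return `data.frame` with one row per classifier.
#' @export
as.data.frame.ChiSquareReport <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(
    classifier_id = x@classifierIds,
    n_correct = x@nCorrect,
    n_incorrect = x@nIncorrect,
    expected_correct = x@expectedCorrect,
    expected_incorrect = x@expectedIncorrect,
    chi2 = x@chi2,
    below_chance = x@belowChance,
    stringsAsFactors = FALSE
  )
}

#' @export
setMethod("toJson", "WeightVector", function(x) {
  jsonlite::toJSON(as.list(stats::setNames(x@w, x@classifierIds)),
                   auto_unbox = TRUE, digits = NA)
})

#' @export
setMethod("toJson", "ChiSquareReport", function(x) {
  rows <- lapply(seq_along(x@classifierIds), function(i) {
    list(n_correct = x@nCorrect[i], n_incorrect = x@nIncorrect[i],
         expected_correct = x@expectedCorrect[i],
         expected_incorrect = x@expectedIncorrect[i],
         chi2 = x@chi2[i], below_chance = x@belowChance[i])
  })
  names(rows) <- x@classifierIds
  jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA)
})

#' @export
setMethod("toJson", "MetricReport", function(x) {
  jsonlite::toJSON(list(
    accuracy = x@accuracy,
    weighted = as.list(x@weighted),
    macro_auc = if (is.na(x@macroAuc)) NULL else x@macroAuc,
    per_class = x@perClass
  ), auto_unbox = TRUE, digits = NA, na = "null")
})
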