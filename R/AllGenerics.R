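#' @include AllClasses.R
NULL

#' Sample identifiers of an object
#'
#' @param x A [LabelVector-class], [PredictionSet-class] or
#'   [PredictionBundle-class].
#' @return Character vector of sample identifiers, in canonical order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Classifier identifiers of an object
#'
#' @param x A [PredictionSet-class], [PredictionBundle-class],
#'   [ChiSquareReport-class] or [WeightVector-class].
#' @return Character vector of classifier identifiers.
#' @export
setGeneric("classifierIds", function(x) standardGeneric("classifierIds"))

#' Number of classes represented by an object
#'
#' @param x A [LabelVector-class], [PredictionSet-class] or
#'   [PredictionBundle-class].
#' @return Integer scalar, the number of classes C.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' Number of samples represented by an object
#'
#' @param x A [LabelVector-class], [PredictionSet-class] or
#'   [PredictionBundle-class].
#' @return Integer scalar.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Class names of an object
#'
#' @param x A [LabelVector-class] or [PredictionSet-class].
#' @return Character vector of class names (possibly `character(0)` when the
#'   object carries none).
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' Class-probability matrix of a prediction set
#'
#' @param x A [PredictionSet-class].
#' @return Numeric N x C matrix; rows are samples (named by sample id),
#'   columns are classes.
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' Member prediction sets of a bundle
#'
#' @param x A [PredictionBundle-class].
#' @return Named list of [PredictionSet-class] objects, keyed by classifier id.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Ensembling weights as a named numeric vector
#'
#' @param x A [WeightVector-class].
#' @return Named numeric vector of weights, nonnegative, summing to one.
#' @export
setGeneric("ensembleWeights", function(x) standardGeneric("ensembleWeights"))

#' Serialize an object to a JSON string
#'
#' Produces a compact JSON representation with deterministic field order,
#' keyed by classifier id where applicable.
#'
#' @param x A [WeightVector-class], [ChiSquareReport-class] or
#'   [MetricReport-class].
#' @return A length-one character vector containing JSON.
#' @export
setGeneric("toJson", function(x) standardGeneric("toJson"))
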