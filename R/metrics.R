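## Confusion-matrix metrics with support-weighted one-vs-rest aggregation,
## and rank-statistic one-vs-rest ROC-AUC.

#' Confusion matrix from paired label vectors
#'
#' @param yTrue,yPred Integer vectors of 0-based class indices (equal
#'   length, values in `[0, C)`).
#' @param nClasses Number of classes C.
#' @param classNames Optional class names used as dimnames.
#' @return Integer C x C matrix; rows are true classes, columns predicted.
#' @export
confusionMatrix <- function(yTrue, yPred, nClasses,
                            classNames = NULL) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred differ in length")
  if (!length(yTrue)) stop("empty label vectors")
  if (min(c(yTrue, yPred)) < 0L || max(c(yTrue, yPred)) >= nClasses)
    stop("class indices out of range [0, ", nClasses, ")")
  lev <- 0:(nClasses - 1L)
  M <- table(factor(yTrue, levels = lev), factor(yPred, levels = lev))
  M <- matrix(as.integer(M), nClasses, nClasses)
  if (is.null(classNames)) classNames <- paste0("class_", lev)
  dimnames(M) <- list(true = classNames, predicted = classNames)
  M
}

#' Write a confusion matrix to CSV with class-name headers
#'
#' @param cm Matrix from [confusionMatrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeConfusionMatrix <- function(cm, path) {
  utils::write.csv(as.data.frame(cm[, , drop = FALSE]), path)
  invisible(path)
}

#' Metrics derived from a confusion matrix
#'
#' Treats each class one-vs-rest: `TP = M[c,c]`, `FN = rowsum - TP`,
#' `FP = colsum - TP`, `TN = total - TP - FP - FN`; per-class precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1, and specificity `TN/(TN+FP)`,
#' with `0/0` defined as 0. Aggregation is support-weighted (by class
#' frequency among the true labels), which makes the weighted recall equal
#' the overall accuracy `trace/total` identically.
#'
#' @param cm Matrix from [confusionMatrix()].
#' @return A [MetricReport-class] (AUC fields are `NA`; see [rocAucOvr()]
#'   or [metricReport()] for probability-based AUC).
#' @export
classificationMetrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  TP <- diag(cm)
  FN <- rowSums(cm) - TP
  FP <- colSums(cm) - TP
  TN <- total - TP - FP - FN
  precision <- safeDiv(TP, TP + FP)
  recall <- safeDiv(TP, TP + FN)
  f1 <- safeDiv(2 * precision * recall, precision + recall)
  specificity <- safeDiv(TN, TN + FP)
  support <- rowSums(cm) / total
  perClass <- data.frame(
    class = if (!is.null(rownames(cm))) rownames(cm)
            else paste0("class_", seq_len(nrow(cm)) - 1L),
    support = rowSums(cm),
    precision = precision, recall = recall, f1 = f1,
    specificity = specificity, auc = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  new("MetricReport",
      accuracy = sum(TP) / total,
      perClass = perClass,
      weighted = c(precision = sum(support * precision),
                   recall = sum(support * recall),
                   f1 = sum(support * f1),
                   specificity = sum(support * specificity)),
      macroAuc = NA_real_)
}

#' One-vs-rest ROC-AUC per class
#'
#' For each class, the class-c probability column scores the one-vs-rest
#' labelling; the AUC is computed by the midrank (Mann-Whitney) statistic,
#' equivalent to trapezoidal integration over all thresholds with ties
#' handled by midranks. Classes absent from the labels get `NA`.
#'
#' @param labels A [LabelVector-class].
#' @param pred A [PredictionSet-class] covering the labelled samples.
#' @return List with `perClass` (numeric vector of per-class AUCs) and
#'   `macro` (mean of the defined AUCs).
#' @export
rocAucOvr <- function(labels, pred) {
  stopifnot(is(labels, "LabelVector"), is(pred, "PredictionSet"))
  sel <- match(labels@sampleIds, pred@sampleIds)
  if (anyNA(sel)) stop("labels contain sample ids absent from predictions")
  P <- pred@P[sel, , drop = FALSE]
  y <- labels@y
  if (length(unique(y)) < 2L)
    stop("AUC undefined: labels contain a single class")
  C <- labels@nClasses
  auc <- rep(NA_real_, C)
  for (c in seq_len(C) - 1L) {
    pos <- y == c
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(P[, c + 1L])  # midranks
    auc[c + 1L] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  names(auc) <- if (length(labels@classNames)) labels@classNames
                else paste0("class_", 0:(C - 1L))
  list(perClass = auc, macro = mean(auc, na.rm = TRUE))
}

#' Full metric report for a prediction set against labels
#'
#' Convenience wrapper: hard labels, confusion matrix, support-weighted
#' metrics, and one-vs-rest AUC in one [MetricReport-class].
#'
#' @param labels A [LabelVector-class].
#' @param pred A [PredictionSet-class] covering the labelled samples.
#' @return A [MetricReport-class] with AUC columns filled when at least two
#'   classes are present.
#' @export
metricReport <- function(labels, pred) {
  stopifnot(is(labels, "LabelVector"), is(pred, "PredictionSet"))
  sel <- match(labels@sampleIds, pred@sampleIds)
  if (anyNA(sel)) stop("labels contain sample ids absent from predictions")
  yPred <- hardLabels(pred)[sel]
  cn <- if (length(labels@classNames)) labels@classNames else NULL
  cm <- confusionMatrix(labels@y, yPred, labels@nClasses, classNames = cn)
  rep <- classificationMetrics(cm)
  if (length(unique(labels@y)) >= 2L) {
    a <- rocAucOvr(labels, pred)
    rep@perClass$auc <- unname(a$perClass)
    rep@macroAuc <- a$macro
  }
  rep
}
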