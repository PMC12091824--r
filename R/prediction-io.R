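## Readers and writers for labels and classifier probability outputs.
## CSV is the portable text dialect (header sample_id,p_0,...,p_{C-1});
## "rds" is the binary dialect used for bit-identical round trips.

#' Read true labels from a CSV file
#'
#' The file must contain a `sample_id` column and a `label` column. Labels
#' are either integer class indices in `[0, C)` or class names resolved
#' against `classNames`.
#'
#' @param path Path to a CSV file.
#' @param classNames Optional ordered class names declaring the index
#'   mapping; required when the label column is non-integer.
#' @param nClasses Optional class count C; inferred otherwise.
#' @return A validated [LabelVector-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sample_id = c("a", "b"), label = c(0, 1)), f,
#'           row.names = FALSE)
#' readLabels(f, nClasses = 2)
#' @export
readLabels <- function(path, classNames = NULL, nClasses = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label")
  if (!all(need %in% names(df)))
    stop("label file must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in label file")
  lab <- df$label
  if (!is.null(classNames) && !is.numeric(lab)) {
    idx <- match(lab, classNames) - 1L
    if (anyNA(idx))
      stop("labels not covered by classNames: ",
           paste(unique(lab[is.na(idx)]), collapse = ", "))
    lab <- idx
  }
  if (!is.numeric(lab)) stop("label column must be integer or resolvable ",
                             "against classNames")
  LabelVector(df$sample_id, as.integer(lab), nClasses = nClasses,
              classNames = classNames)
}

#' Write labels to CSV
#'
#' @param labels A [LabelVector-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "LabelVector"))
  utils::write.csv(
    data.frame(sample_id = labels@sampleIds, label = labels@y),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one classifier's probability matrix
#'
#' CSV dialect: header `sample_id,p_0,...,p_{C-1}` with contiguous, complete
#' probability columns. RDS dialect: a serialized [PredictionSet-class]
#' (bit-identical round trip). Rows whose sum deviates from one by at most
#' 1e-3 are renormalized; larger deviations are an error.
#'
#' @param path Input path.
#' @param dialect `"csv"` or `"rds"`; inferred from the file extension by
#'   default.
#' @param classifierId Classifier id to record; defaults to the file base
#'   name (CSV only).
#' @return A validated [PredictionSet-class].
#' @export
readPredictions <- function(path, dialect = c("auto", "csv", "rds"),
                            classifierId = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  if (!file.exists(path)) stop("prediction file not found: ", path)
  if (dialect == "rds") {
    obj <- readRDS(path)
    if (!is(obj, "PredictionSet"))
      stop("rds file does not contain a PredictionSet")
    validObject(obj)
    return(obj)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("prediction file must contain a sample_id column")
  pcols <- grep("^p_[0-9]+$", names(df), value = TRUE)
  if (!length(pcols)) stop("no probability columns p_0..p_{C-1} found")
  idx <- as.integer(sub("^p_", "", pcols))
  expect <- paste0("p_", seq_len(max(idx) + 1L) - 1L)
  if (!setequal(pcols, expect))
    stop("probability columns must be contiguous p_0..p_{C-1}")
  P <- as.matrix(df[, expect, drop = FALSE])
  storage.mode(P) <- "double"
  if (anyNA(P)) stop("ragged or non-numeric probability rows")
  if (min(P) < 0) stop("negative probability in ", path)
  rs <- rowSums(P)
  bad <- abs(rs - 1) > 1e-3
  if (any(bad))
    stop(sum(bad), " row(s) with probability sum outside [0.999, 1.001]")
  P <- P / rs
  if (is.null(classifierId))
    classifierId <- sub("\\.[^.]*$", "", basename(path))
  PredictionSet(classifierId, df$sample_id, P)
}

#' Write one classifier's probability matrix
#'
#' CSV output round-trips through [readPredictions()] within 1e-12 (17
#' significant digits); RDS output round-trips bit-identically.
#'
#' @param pred A [PredictionSet-class].
#' @param path Output path.
#' @param dialect `"csv"` or `"rds"`; inferred from the extension by default.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(pred, path, dialect = c("auto", "csv", "rds")) {
  stopifnot(is(pred, "PredictionSet"))
  validObject(pred)
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  if (dialect == "rds") {
    saveRDS(pred, path)
    return(invisible(path))
  }
  C <- nClasses(pred)
  header <- paste(c("sample_id", paste0("p_", 0:(C - 1L))), collapse = ",")
  rows <- paste(pred@sampleIds,
                apply(pred@P, 1L, function(r)
                  paste(formatC(r, digits = 17, format = "g"),
                        collapse = ",")),
                sep = ",")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Align prediction sets to a label vector
#'
#' Reorders and subsets each member to the samples shared by all members and
#' the labels, in label order (the [LabelVector-class] order is canonical).
#' A warning reports any samples dropped from members or labels.
#'
#' @param members A list of [PredictionSet-class] objects (or a
#'   [PredictionBundle-class] to re-align).
#' @param labels A [LabelVector-class].
#' @return A list with elements `bundle` (the aligned
#'   [PredictionBundle-class]) and `labels` (the [LabelVector-class]
#'   restricted to the shared samples).
#' @examples
#' lab <- LabelVector(c("a", "b"), c(0L, 1L), 2L)
#' ps <- PredictionSet("m1", c("b", "a"), matrix(c(0.2, 0.7, 0.8, 0.3), 2))
#' alignBundle(list(ps), lab)$bundle
#' @export
alignBundle <- function(members, labels) {
  stopifnot(is(labels, "LabelVector"))
  if (is(members, "PredictionBundle")) members <- members(members)
  if (is(members, "PredictionSet")) members <- list(members)
  if (!length(members)) stop("no prediction sets supplied")
  Cs <- vapply(members, nClasses, integer(1))
  if (length(unique(Cs)) != 1L)
    stop("members disagree on class count: ",
         paste(unique(Cs), collapse = " vs "))
  if (Cs[1L] != labels@nClasses)
    stop("members have ", Cs[1L], " classes but labels declare ",
         labels@nClasses)
  shared <- Reduce(intersect, lapply(members, sampleIds), labels@sampleIds)
  if (!length(shared)) stop("no sample ids shared by labels and all members")
  keep <- labels@sampleIds[labels@sampleIds %in% shared]
  dropped <- length(labels@sampleIds) - length(keep) +
    sum(vapply(members, function(m) nSamples(m) - length(keep), integer(1)))
  if (dropped > 0L)
    warning("alignBundle dropped ", dropped,
            " sample slot(s) outside the shared id set")
  aligned <- lapply(members, function(m) {
    i <- match(keep, m@sampleIds)
    PredictionSet(m@classifierId, keep, m@P[i, , drop = FALSE])
  })
  labKeep <- labels@y[match(keep, labels@sampleIds)]
  list(
    bundle = PredictionBundle(aligned),
    labels = LabelVector(keep, labKeep, nClasses = labels@nClasses,
                         classNames = if (length(labels@classNames))
                           labels@classNames else NULL)
  )
}
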