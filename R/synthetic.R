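## Generators for labels, banks of imperfect classifiers, and lesion-grouped
## cohorts, plus the leakage-free grouped splitter. Everything is
## deterministic given its seed and leaves the caller's RNG state untouched.

#' Class priors resembling a dermoscopy seven-class test composition
#'
#' Priors proportional to the per-class sample counts AK 22, BCC 27, BKL 66,
#' DF 6, MEL 35, NV 663, VASC 9 (total 828) — a strongly nevus-dominated
#' distribution typical of dermatoscopic cohorts.
#'
#' @return Named numeric vector of 7 priors summing to 1.
#' @examples
#' hamLikePriors()[["NV"]]  # 663/828
#' @export
hamLikePriors <- function() {
  counts <- c(AK = 22, BCC = 27, BKL = 66, DF = 6, MEL = 35, NV = 663,
              VASC = 9)
  counts / sum(counts)
}

#' Simulation configuration for a bank of imperfect classifiers
#'
#' @param nSamples Number of samples N.
#' @param classPriors Numeric simplex of class priors (named or not).
#' @param accuracies Numeric vector, one marginal accuracy per simulated
#'   classifier, each in `[0, 1]`.
#' @param concentration Dirichlet mass added on the predicted class when
#'   drawing probability rows (> 0); larger values give more confident
#'   rows.
#' @param difficultyRho Probability in `[0, 1]` that a sample is "hard" for
#'   all classifiers jointly, inducing positive correlation between their
#'   correctness vectors.
#' @param seed Integer RNG seed.
#' @param confusion `"prior"` draws wrong predictions from the class prior
#'   restricted to non-true classes (confusions concentrate on frequent
#'   classes); `"uniform"` draws them uniformly.
#' @param classifierIds Optional classifier ids (default `clf_1 ...`).
#' @return Validated configuration list of class `"simConfig"`.
#' @export
simConfig <- function(nSamples, classPriors, accuracies,
                      concentration = 8, difficultyRho = 0, seed = 1L,
                      confusion = c("prior", "uniform"),
                      classifierIds = NULL) {
  confusion <- match.arg(confusion)
  classPriors <- as.numeric(classPriors) / sum(classPriors)
  if (any(classPriors < 0)) stop("class priors must be nonnegative")
  if (length(classPriors) < 2L) stop("need at least 2 classes")
  if (any(accuracies < 0 | accuracies > 1))
    stop("accuracies must lie in [0, 1]")
  if (difficultyRho < 0 || difficultyRho > 1)
    stop("difficultyRho must lie in [0, 1]")
  if (concentration <= 0) stop("concentration must be positive")
  if (is.null(classifierIds))
    classifierIds <- paste0("clf_", seq_along(accuracies))
  structure(list(
    nSamples = as.integer(nSamples),
    nClasses = length(classPriors),
    classPriors = classPriors,
    accuracies = as.numeric(accuracies),
    concentration = concentration,
    difficultyRho = difficultyRho,
    seed = as.integer(seed),
    confusion = confusion,
    classifierIds = as.character(classifierIds)
  ), class = "simConfig")
}

#' Simulate true labels
#'
#' I.i.d. draws from the configured class priors, deterministic per seed.
#'
#' @param config A [simConfig()] list.
#' @return A [LabelVector-class] with sample ids `s000001, ...`.
#' @export
simulateLabels <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  y <- withSeed(config$seed,
    sample.int(config$nClasses, config$nSamples, replace = TRUE,
               prob = config$classPriors) - 1L)
  cn <- names(config$classPriors)
  LabelVector(sprintf("s%06d", seq_len(config$nSamples)), y,
              nClasses = config$nClasses, classNames = cn)
}

#' Simulate a bundle of imperfect classifiers
#'
#' The generator emulates a bank of sibling classifiers (e.g. fine-tuned
#' variants of related architectures evaluated on the same images), whose
#' errors are strongly correlated, not independent. Per sample, a shared
#' "hard" indicator is drawn with probability `difficultyRho`. On hard
#' samples all classifiers emit one shared prediction drawn from the class
#' prior independently of the truth (jointly correct with chance
#' probability `q = sum(pi_c^2)`). Easy samples carry a shared difficulty
#' latent `u ~ U(0, 1)`: classifier k is correct iff
#' `u <= aEasy_k = (a_k - rho * q) / (1 - rho)`, so its marginal accuracy
#' stays `a_k` while weaker classifiers' error sets nest those of stronger
#' ones. Wrong predictions on easy samples are drawn per classifier from
#' the prior restricted to non-true classes (or uniformly). Each
#' probability row is drawn from a Dirichlet with unit base mass plus
#' `concentration` on the predicted class; the row's largest entry is
#' swapped into the predicted class position so the hard label of the row
#' equals the intended prediction.
#'
#' @param config A [simConfig()] list.
#' @param labels A [LabelVector-class], typically from [simulateLabels()].
#' @return A [PredictionBundle-class] with one member per accuracy.
#' @export
simulateBundle <- function(config, labels) {
  stopifnot(inherits(config, "simConfig"), is(labels, "LabelVector"))
  n <- nSamples(labels)
  C <- config$nClasses
  pri <- config$classPriors
  q <- sum(pri^2)
  rho <- config$difficultyRho
  aEasy <- if (rho < 1) (config$accuracies - rho * q) / (1 - rho)
           else rep(NA_real_, length(config$accuracies))
  bad <- rho >= 1 | aEasy < 0 | aEasy > 1
  if (any(bad))
    stop("accuracy unreachable for classifier(s) ",
         paste(config$classifierIds[bad], collapse = ", "),
         " given difficultyRho = ", rho,
         " (need rho*q <= a_k <= 1 - rho*(1 - q))")
  y <- labels@y
  members <- withSeed(config$seed + 1L, {
    hard <- stats::runif(n) < rho
    sharedPred <- sample.int(C, n, replace = TRUE, prob = pri) - 1L
    u <- stats::runif(n)  # shared easy-sample difficulty latent
    lapply(seq_along(config$accuracies), function(k) {
      pred <- integer(n)
      # hard samples: one shared prior draw, independent of the truth
      pred[hard] <- sharedPred[hard]
      # easy samples: correct iff the shared latent clears this
      # classifier's adjusted accuracy, else a confusion draw
      easy <- which(!hard)
      correct <- u[easy] <= aEasy[k]
      pred[easy[correct]] <- y[easy[correct]]
      wrongIdx <- easy[!correct]
      for (c in unique(y[wrongIdx])) {
        ii <- wrongIdx[y[wrongIdx] == c]
        p <- if (config$confusion == "prior") pri else rep(1, C)
        p[c + 1L] <- 0
        pred[ii] <- sample.int(C, length(ii), replace = TRUE,
                               prob = p) - 1L
      }
      # Dirichlet rows with boosted mass on the predicted class
      alpha <- matrix(1, n, C)
      alpha[cbind(seq_len(n), pred + 1L)] <-
        1 + config$concentration
      G <- matrix(stats::rgamma(n * C, shape = alpha), n, C)
      P <- G / rowSums(G)
      # guarantee argmax == pred by swapping the max entry in
      mx <- max.col(P, ties.method = "first")
      swap <- which(mx != pred + 1L)
      if (length(swap)) {
        i1 <- cbind(swap, mx[swap])
        i2 <- cbind(swap, pred[swap] + 1L)
        tmp <- P[i1]; P[i1] <- P[i2]; P[i2] <- tmp
      }
      colnames(P) <- if (length(labels@classNames)) labels@classNames
      PredictionSet(config$classifierIds[k], labels@sampleIds, P)
    })
  })
  PredictionBundle(members)
}

#' Simulate a lesion-grouped cohort
#'
#' Each lesion receives a class drawn from the priors and between 1 and
#' `imagesPerLesionMax` images; all images of a lesion share its class.
#'
#' @param nLesions Number of lesions.
#' @param imagesPerLesionMax Maximum images per lesion (uniform 1..max).
#' @param priors Class priors (default [hamLikePriors()]).
#' @param seed Integer RNG seed.
#' @return `data.frame` with columns `image_id`, `lesion_id`, `label`
#'   (0-based class index).
#' @export
simulateCohort <- function(nLesions, imagesPerLesionMax = 3L,
                           priors = hamLikePriors(), seed = 1L) {
  stopifnot(nLesions >= 1L, imagesPerLesionMax >= 1L)
  priors <- as.numeric(priors) / sum(priors)
  withSeed(seed, {
    cls <- sample.int(length(priors), nLesions, replace = TRUE,
                      prob = priors) - 1L
    sizes <- sample.int(imagesPerLesionMax, nLesions, replace = TRUE)
    lesion <- rep(sprintf("L%05d", seq_len(nLesions)), sizes)
    data.frame(
      image_id = sprintf("img%06d", seq_len(sum(sizes))),
      lesion_id = lesion,
      label = rep(cls, sizes),
      stringsAsFactors = FALSE
    )
  })
}

#' Leakage-free grouped train/validation/test split
#'
#' Lesions are shuffled by seed and assigned greedily — first filling the
#' test split, then validation, then train — against image-count targets,
#' so no lesion ever spans two splits. A single lesion larger than a split's
#' image target is assigned to train with a warning.
#'
#' @param cohort `data.frame` with columns `image_id`, `lesion_id` (e.g.
#'   from [simulateCohort()]).
#' @param fractions Numeric `(train, val, test)` fractions, positive and
#'   summing to 1 (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer RNG seed.
#' @return The cohort `data.frame` with an added `split` column
#'   (`"train"`, `"val"`, `"test"`).
#' @export
groupedSplit <- function(cohort, fractions = c(train = 0.70, val = 0.15,
                                               test = 0.15), seed = 1L) {
  stopifnot(all(c("image_id", "lesion_id") %in% names(cohort)))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three nonnegative values summing to 1")
  sizes <- table(cohort$lesion_id)
  nImages <- nrow(cohort)
  targetTest <- fractions[3L] * nImages
  targetVal <- fractions[2L] * nImages
  lesions <- withSeed(seed, sample(names(sizes)))
  assign <- stats::setNames(rep("train", length(lesions)), lesions)
  big <- lesions[as.vector(sizes[lesions]) >
                   max(targetTest, targetVal, 1)]
  if (length(big) && (targetTest > 0 || targetVal > 0))
    warning("lesion(s) larger than a split target assigned to train: ",
            paste(big, collapse = ", "))
  nTest <- 0; nVal <- 0
  for (l in lesions) {
    sz <- as.vector(sizes[l])
    if (l %in% big) next
    if (nTest < targetTest) {
      assign[l] <- "test"; nTest <- nTest + sz
    } else if (nVal < targetVal) {
      assign[l] <- "val"; nVal <- nVal + sz
    }
  }
  cohort$split <- unname(assign[cohort$lesion_id])
  cohort
}
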