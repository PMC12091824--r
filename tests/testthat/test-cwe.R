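test_that("hard labels take the argmax with lowest-index tie break", {
  ps <- PredictionSet("m", c("a", "b"),
                      rbind(c(0.1, 0.7, 0.2), c(0.4, 0.3, 0.3)))
  expect_identical(unname(hardLabels(ps)), c(1L, 0L))
  tie <- PredictionSet("m", "a", matrix(c(0.5, 0.5), 1))
  expect_identical(unname(hardLabels(tie)), 0L)
  # identity rows of a permutation matrix recover the permutation
  perm <- c(3L, 1L, 2L)
  P <- diag(3)[perm, ]
  expect_identical(
    unname(hardLabels(PredictionSet("m", letters[1:3], P))), perm - 1L)
})

test_that("correctness vector is the elementwise equality indicator", {
  lab <- LabelVector(c("a", "b", "c"), c(0L, 1L, 1L), 3L)
  expect_identical(correctnessVector(c(0L, 1L, 2L), lab), c(1L, 1L, 0L))
  expect_identical(correctnessVector(lab@y, lab), rep(1L, 3))
  expect_identical(correctnessVector(c(2L, 0L, 2L), lab), c(0L, 0L, 0L))
  expect_error(correctnessVector(c(0L, 1L), lab), "length")
})

test_that("expected frequencies implement the chance-agreement null", {
  lab <- LabelVector(paste0("s", 1:100), rep(c(0L, 1L), 50), 2L)
  expect_equal(unname(expectedFrequencies(lab)), c(50, 50))

  lab2 <- LabelVector(paste0("s", 1:100), rep(c(0L, 1L), c(80, 20)), 2L)
  expect_equal(unname(expectedFrequencies(lab2)), c(68, 32))

  # seven-class dermoscopy-like composition, oracle: brute-force sum of
  # squared class frequencies over the raw counts
  counts <- c(663, 66, 35, 27, 22, 9, 6)
  lab7 <- LabelVector(paste0("s", 1:828),
                      rep(0:6, counts), 7L)
  oracle <- 828 * sum((counts / 828)^2)
  expect_equal(unname(expectedFrequencies(lab7))[1], oracle)
  expect_equal(sum(expectedFrequencies(lab7)), 828)

  # degenerate single-class labels: marginal null undefined, uniform works
  lab1 <- LabelVector(paste0("s", 1:5), rep(2L, 5), 3L)
  expect_error(expectedFrequencies(lab1), "identical")
  expect_equal(unname(expectedFrequencies(lab1, null = "uniform")),
               c(5 / 3, 10 / 3))
})

test_that("two-cell chi-square statistic matches its closed form", {
  expect_equal(chiSquareStatistic(c(70, 30), c(50, 50)), 16)
  expect_equal(chiSquareStatistic(c(68, 32), c(68, 32)), 0)
  expect_error(chiSquareStatistic(c(1, 2), c(0, 3)), "positive")
  expect_error(chiSquareStatistic(1, c(1, 1)), "two cells")
})

test_that("weights are chi2 proportions with one-sided zeroing", {
  w <- computeWeights(reportFromChi2(c(16, 4)))
  expect_equal(unname(ensembleWeights(w)), c(0.8, 0.2))

  w <- computeWeights(reportFromChi2(rep(3.7, 5)))
  expect_equal(unname(ensembleWeights(w)), rep(0.2, 5))

  expect_warning(w0 <- computeWeights(reportFromChi2(c(0, 0, 0))), "uniform")
  expect_equal(unname(ensembleWeights(w0)), rep(1 / 3, 3))

  # below-chance classifiers are zeroed under one_sided, kept under raw
  rep2 <- reportFromChi2(c(10, 10), belowChance = c(TRUE, FALSE))
  expect_equal(unname(ensembleWeights(computeWeights(rep2))), c(0, 1))
  expect_equal(unname(ensembleWeights(computeWeights(rep2, mode = "raw"))),
               c(0.5, 0.5))
})

test_that("weights are invariant to uniform rescaling of chi2", {
  set.seed(5)
  for (i in 1:20) {
    chi2 <- rexp(4)
    w1 <- ensembleWeights(computeWeights(reportFromChi2(chi2)))
    w2 <- ensembleWeights(computeWeights(reportFromChi2(chi2 * 1000)))
    expect_equal(w1, w2, tolerance = 1e-12)
  }
})

test_that("blending is the weighted per-class mean", {
  b <- PredictionBundle(list(
    PredictionSet("m1", "s1", matrix(c(1, 0), 1)),
    PredictionSet("m2", "s1", matrix(c(0, 1), 1))))
  out <- cweBlend(b, WeightVector(c("m1", "m2"), c(0.8, 0.2)))
  expect_equal(unname(probMatrix(out)[1, ]), c(0.8, 0.2))

  # single member with weight 1 is the identity
  one <- PredictionBundle(list(randomPredictionSet(5, 3, "m")))
  expect_equal(probMatrix(cweBlend(one, WeightVector("m", 1))),
               probMatrix(members(one)$m))

  # identical members blend to themselves under any weights (convexity)
  ps <- randomPredictionSet(6, 4, "a")
  same <- PredictionBundle(list(ps, PredictionSet("b", ps@sampleIds, ps@P),
                                PredictionSet("c", ps@sampleIds, ps@P)))
  wr <- rexp(3); wr <- wr / sum(wr)
  out <- cweBlend(same, WeightVector(c("a", "b", "c"), wr))
  expect_equal(probMatrix(out), probMatrix(ps), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(cweBlend(one, WeightVector(c("x", "y"), c(0.5, 0.5))),
               "classifier ids")
})

test_that("fitCwe favors accurate classifiers and zeroes below-chance ones", {
  set.seed(13)
  n <- 400
  lab <- randomLabels(n, 2)
  # perfect classifier
  Pp <- matrix(0.05, n, 2); Pp[cbind(1:n, lab@y + 1L)] <- 0.95
  perfect <- PredictionSet("perfect", lab@sampleIds, Pp)
  # chance-level classifier: prior draw independent of the truth
  guess <- sample(0:1, n, replace = TRUE)
  Pg <- matrix(0.05, n, 2); Pg[cbind(1:n, guess + 1L)] <- 0.95
  chance <- PredictionSet("chance", lab@sampleIds, Pg)
  fit <- fitCwe(PredictionBundle(list(perfect, chance)), lab)
  expect_gt(ensembleWeights(fit$weights)[["perfect"]], 0.9)

  # identical classifiers get uniform weights
  twin <- PredictionSet("twin", lab@sampleIds, Pp)
  fit2 <- fitCwe(PredictionBundle(list(perfect, twin)), lab)
  expect_equal(unname(ensembleWeights(fit2$weights)), c(0.5, 0.5))

  # anti-classifier (always wrong) is zeroed under one_sided
  Pa <- Pp[, 2:1]
  anti <- PredictionSet("anti", lab@sampleIds, Pa)
  fit3 <- fitCwe(PredictionBundle(list(perfect, anti)), lab)
  expect_identical(ensembleWeights(fit3$weights)[["anti"]], 0)
  expect_true(fit3$report@belowChance[2])
})

test_that("permuting bundle member order permutes weights, blend unchanged", {
  set.seed(23)
  lab <- randomLabels(200, 3)
  mem <- lapply(1:4, function(i) randomPredictionSet(200, 3,
                                                     paste0("m", i)))
  b1 <- PredictionBundle(mem)
  b2 <- PredictionBundle(mem[c(3, 1, 4, 2)])
  f1 <- suppressWarnings(fitCwe(b1, lab))
  f2 <- suppressWarnings(fitCwe(b2, lab))
  w1 <- ensembleWeights(f1$weights)
  w2 <- ensembleWeights(f2$weights)
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))])
  expect_equal(probMatrix(cweBlend(b1, f1$weights)),
               probMatrix(cweBlend(b2, f2$weights)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("report serializes to classifier-keyed JSON", {
  set.seed(3)
  fit <- suppressWarnings(fitCwe(randomBundle(2, 50, 3),
                                 randomLabels(50, 3)))
  js <- jsonlite::fromJSON(toJson(fit$report))
  expect_named(js, c("clf_1", "clf_2"))
  expect_named(js$clf_1, c("n_correct", "n_incorrect", "expected_correct",
                           "expected_incorrect", "chi2", "below_chance"))
  wj <- jsonlite::fromJSON(toJson(fit$weights))
  expect_equal(unlist(wj), ensembleWeights(fit$weights),
               tolerance = 1e-12)
})
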