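test_that("dermoscopy-like priors reproduce the seven-class composition", {
  pri <- hamLikePriors()
  expect_equal(sum(pri), 1)
  expect_equal(pri[["NV"]], 663 / 828)
  expect_equal(pri[["DF"]], 6 / 828)
  expect_length(pri, 7)
})

test_that("label simulation is deterministic and follows the priors", {
  cfg <- simConfig(10000, rep(1 / 7, 7), 0.8, seed = 11)
  lab1 <- simulateLabels(cfg)
  lab2 <- simulateLabels(cfg)
  expect_identical(trueLabels(lab1), trueLabels(lab2))
  freq <- tabulate(lab1@y + 1L, 7) / 10000
  expect_true(all(abs(freq - 1 / 7) < 0.02))
  # one-hot priors give constant labels
  cfg1 <- simConfig(50, c(0, 1, 0), 0.8, seed = 1)
  expect_true(all(trueLabels(simulateLabels(cfg1)) == 1L))
  # distinct seeds give distinct draws
  cfgB <- simConfig(10000, rep(1 / 7, 7), 0.8, seed = 12)
  expect_false(identical(trueLabels(simulateLabels(cfgB)),
                         trueLabels(lab1)))
})

test_that("simulated classifiers hit their marginal accuracies", {
  # perfect classifier with no hard samples is always right
  cfg <- simConfig(500, c(0.5, 0.3, 0.2), c(1, 0.7), seed = 21)
  lab <- simulateLabels(cfg)
  b <- simulateBundle(cfg, lab)
  expect_true(all(hardLabels(members(b)$clf_1) == trueLabels(lab)))

  # a 0.7 classifier at n = 5000 stays inside the 99% binomial CI
  cfg2 <- simConfig(5000, hamLikePriors(), 0.7, seed = 22)
  lab2 <- simulateLabels(cfg2)
  b2 <- simulateBundle(cfg2, lab2)
  acc <- mean(hardLabels(members(b2)$clf_1) == trueLabels(lab2))
  ci <- qnorm(0.995) * sqrt(0.7 * 0.3 / 5000)
  expect_lt(abs(acc - 0.7), ci)

  # shared difficulty induces positively correlated correctness
  cfg3 <- simConfig(4000, hamLikePriors(), c(0.7, 0.75),
                    difficultyRho = 0.5, seed = 23)
  lab3 <- simulateLabels(cfg3)
  b3 <- simulateBundle(cfg3, lab3)
  c1 <- hardLabels(members(b3)$clf_1) == trueLabels(lab3)
  c2 <- hardLabels(members(b3)$clf_2) == trueLabels(lab3)
  expect_gt(cor(c1, c2), 0)

  # unreachable accuracy under heavy shared difficulty errors out
  cfg4 <- simConfig(100, rep(1 / 7, 7), 0.95, difficultyRho = 0.5,
                    seed = 1)
  lab4 <- simulateLabels(cfg4)
  expect_error(simulateBundle(cfg4, lab4), "unreachable")
})

test_that("bundle rows are valid distributions whose argmax is the draw", {
  cfg <- simConfig(300, c(0.6, 0.2, 0.2), c(0.4, 0.8),
                   concentration = 4, difficultyRho = 0.2, seed = 31)
  lab <- simulateLabels(cfg)
  b <- simulateBundle(cfg, lab)
  for (m in members(b)) {
    P <- probMatrix(m)
    expect_true(all(P >= 0 & P <= 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
  # determinism
  b2 <- simulateBundle(cfg, lab)
  expect_equal(lapply(members(b), probMatrix),
               lapply(members(b2), probMatrix))
})

test_that("cohorts keep one class per lesion", {
  co <- simulateCohort(150, imagesPerLesionMax = 4, seed = 41)
  expect_false(anyDuplicated(co$image_id) > 0)
  perLesion <- tapply(co$label, co$lesion_id, function(x)
    length(unique(x)))
  expect_true(all(perLesion == 1))
  # one image per lesion: image count equals lesion count
  co1 <- simulateCohort(80, imagesPerLesionMax = 1, seed = 42)
  expect_identical(nrow(co1), 80L)
  expect_identical(simulateCohort(80, imagesPerLesionMax = 1, seed = 42),
                   co1)
})

test_that("grouped split is leakage-free with near-target fractions", {
  co <- simulateCohort(1000, imagesPerLesionMax = 1, seed = 43)
  sp <- groupedSplit(co, c(0.7, 0.15, 0.15), seed = 44)
  tab <- table(sp$split) / nrow(sp)
  expect_lt(abs(tab[["train"]] - 0.70), 0.02)
  expect_lt(abs(tab[["val"]] - 0.15), 0.02)
  expect_lt(abs(tab[["test"]] - 0.15), 0.02)
  # no lesion spans two splits
  cross <- tapply(sp$split, sp$lesion_id, function(x) length(unique(x)))
  expect_true(all(cross == 1))
  # everything lands in train when asked
  sp1 <- groupedSplit(co, c(1, 0, 0), seed = 45)
  expect_true(all(sp1$split == "train"))
  # one giant lesion cannot fit a 15% target: warned into train
  giant <- data.frame(image_id = paste0("i", 1:30),
                      lesion_id = c(rep("L1", 25), paste0("S", 1:5)),
                      label = 0L)
  expect_warning(spg <- groupedSplit(giant, c(0.7, 0.15, 0.15), seed = 1),
                 "larger than")
  expect_true(all(spg$split[spg$lesion_id == "L1"] == "train"))
})
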