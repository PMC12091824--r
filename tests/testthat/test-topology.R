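test_that("the canonical layered preset has the expected structure", {
  topo <- buildLayeredTopology()
  expect_length(topo@leafIds, 96)
  layers <- vapply(topo@nodes, function(n) n@layer, integer(1))
  expect_equal(unname(table(layers)), c(24L, 14L, 2L, 1L),
               ignore_attr = TRUE)
  expect_identical(topo@terminalId, "RN")
  expect_length(topo@nodes, 41)
  expect_silent(validateTopology(topo))
  # family and pairing nodes have the right in-degrees
  expect_length(topo@nodes[["RNX"]]@inputIds, 12)
  expect_length(topo@nodes[["RNY"]]@inputIds, 12)
  expect_length(topo@nodes[["RN_XY"]]@inputIds, 12)
  expect_identical(topo@nodes[["RN"]]@inputIds, c("RNXY", "RN_XY"))
})

test_that("degenerate one-backbone-per-family preset still validates", {
  topo <- buildLayeredTopology(backbonesX = "RNX002",
                               backbonesY = "RNY002")
  layers <- vapply(topo@nodes, function(n) n@layer, integer(1))
  expect_equal(unname(table(layers)), c(2L, 3L, 2L, 1L),
               ignore_attr = TRUE)
  expect_silent(validateTopology(topo))
  # and a 3-variant generalization gives 3-input layer-1 nodes
  topo3 <- buildLayeredTopology(variants = c("C", "CA", "SA"))
  expect_length(topo3@nodes[["RNX002"]]@inputIds, 3)
  expect_length(topo3@leafIds, 72)
})

test_that("topology validation rejects malformed graphs", {
  nodes <- list(TopologyNode("a", 1L, "cwe", c("l1", "l2")),
                TopologyNode("b", 2L, "cwe", "a"))
  expect_silent(validateTopology(
    new("EnsembleTopology", leafIds = c("l1", "l2"),
        nodes = setNames(nodes, c("a", "b")), terminalId = "b")))
  # self reference
  bad <- list(a = TopologyNode("a", 1L, "cwe", "a"))
  expect_error(validateTopology(
    new("EnsembleTopology", leafIds = "l1", nodes = bad,
        terminalId = "a")), "unknown input|lower layers")
  # two terminals
  two <- list(a = TopologyNode("a", 1L, "cwe", "l1"),
              b = TopologyNode("b", 1L, "cwe", "l1"))
  expect_error(validateTopology(
    new("EnsembleTopology", leafIds = "l1", nodes = two,
        terminalId = "a")), "exactly one terminal")
  # dangling input
  dang <- list(a = TopologyNode("a", 1L, "cwe", c("l1", "ghost")))
  expect_error(validateTopology(
    new("EnsembleTopology", leafIds = "l1", nodes = dang,
        terminalId = "a")), "unknown input")
})

test_that("single-node topology reduces to fitCwe + cweBlend", {
  set.seed(53)
  cfg <- simConfig(300, c(0.5, 0.3, 0.2), c(0.5, 0.7, 0.9), seed = 5)
  lab <- simulateLabels(cfg)
  b <- simulateBundle(cfg, lab)
  topo <- EnsembleTopology(
    classifierIds(b),
    list(TopologyNode("root", 1L, "cwe", classifierIds(b))), "root")
  res <- executeTopology(topo, b, lab)
  direct <- fitCwe(b, lab)
  expect_equal(ensembleWeights(res$root$weights),
               ensembleWeights(direct$weights), tolerance = 1e-12)
  expect_equal(probMatrix(terminalPrediction(res)),
               probMatrix(cweBlend(b, direct$weights)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical leaves propagate unchanged through every layer", {
  topo <- buildLayeredTopology(
    backbonesX = c("RNX002", "RNX004"), backbonesY = c("RNY002", "RNY004"))
  set.seed(59)
  lab <- randomLabels(60, 3)
  ps <- randomPredictionSet(60, 3, "ref")
  mem <- lapply(topo@leafIds, function(id)
    PredictionSet(id, ps@sampleIds, ps@P))
  b <- PredictionBundle(mem)
  res <- suppressWarnings(executeTopology(topo, b, lab))
  expect_equal(probMatrix(terminalPrediction(res)), probMatrix(ps),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("execution is deterministic and content-ordered", {
  set.seed(61)
  cfg <- simConfig(200, c(0.4, 0.3, 0.3), runif(8, 0.5, 0.9), seed = 9)
  lab <- simulateLabels(cfg)
  b <- simulateBundle(cfg, lab)
  ids <- classifierIds(b)
  nodes <- list(
    TopologyNode("n1", 1L, "cwe", ids[1:4]),
    TopologyNode("n2", 1L, "cwe", ids[5:8]),
    TopologyNode("top", 2L, "cwe", c("n1", "n2")))
  t1 <- EnsembleTopology(ids, nodes, "top")
  t2 <- EnsembleTopology(ids, nodes[c(3, 1, 2)], "top")
  r1 <- executeTopology(t1, b, lab, evalLabels = lab)
  r2 <- executeTopology(t2, b, lab, evalLabels = lab)
  expect_equal(probMatrix(terminalPrediction(r1)),
               probMatrix(terminalPrediction(r2)))
  expect_equal(r1$top$metrics@accuracy, r2$top$metrics@accuracy)
  # every intermediate output is a valid probability matrix
  for (r in r1) {
    P <- probMatrix(r$prediction)
    expect_true(all(P >= 0 & P <= 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
  expect_error(executeTopology(t1, PredictionBundle(members(b)[1:3]), lab),
               "missing leaf")
})

test_that("topologies round-trip through YAML and JSON", {
  topo <- buildLayeredTopology(
    backbonesX = c("RNX002", "RNX004"), backbonesY = c("RNY002", "RNY004"))
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    writeTopology(topo, f)
    back <- readTopology(f)
    expect_identical(back@leafIds, topo@leafIds)
    expect_identical(back@terminalId, topo@terminalId)
    expect_identical(names(back@nodes), names(topo@nodes))
    expect_identical(back@nodes[["RN"]]@inputIds,
                     topo@nodes[["RN"]]@inputIds)
  }
})
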