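## Ensemble DAG execution and the canonical 4-layer preset combining two
## families of 12 backbones, each trained in 4 attention variants.

#' Validate an ensemble topology
#'
#' Asserts that every node input resolves to a leaf or a strictly
#' lower-layer node, that the graph is acyclic, and that exactly one
#' terminal node exists.
#'
#' @param topology An [EnsembleTopology-class].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validateTopology <- function(topology) {
  nodes <- topology@nodes
  nodeIds <- names(nodes)
  if (anyDuplicated(c(topology@leafIds, nodeIds)))
    stop("duplicate ids among leaves and nodes")
  for (nd in nodes) {
    validObject(nd)
    for (inp in nd@inputIds) {
      if (inp %in% topology@leafIds) next
      if (!inp %in% nodeIds)
        stop("node '", nd@nodeId, "' references unknown input '", inp, "'")
      if (nodes[[inp]]@layer >= nd@layer)
        stop("node '", nd@nodeId, "' (layer ", nd@layer,
             ") consumes node '", inp, "' of layer ", nodes[[inp]]@layer,
             "; inputs must come from strictly lower layers")
    }
  }
  consumed <- unique(unlist(lapply(nodes, function(n) n@inputIds)))
  terminals <- setdiff(nodeIds, consumed)
  if (length(terminals) != 1L)
    stop("topology must have exactly one terminal node, found ",
         length(terminals), ": ", paste(terminals, collapse = ", "))
  if (!identical(terminals, topology@terminalId))
    stop("declared terminal '", topology@terminalId,
         "' is not the unique unconsumed node '", terminals, "'")
  # reachability: every node reachable from the leaves
  reach <- topology@leafIds
  repeat {
    newly <- vapply(nodes, function(n)
      !(n@nodeId %in% reach) && all(n@inputIds %in% reach), logical(1))
    if (!any(newly)) break
    reach <- c(reach, nodeIds[newly])
  }
  unreached <- setdiff(nodeIds, reach)
  if (length(unreached))
    stop("node(s) not reachable from the leaves: ",
         paste(unreached, collapse = ", "))
  invisible(TRUE)
}

#' Build the canonical 4-layer ensemble topology
#'
#' Constructs the layered scheme for two families of backbones (X and Y),
#' each trained in several attention variants:
#' * Layer 1: one node per backbone, ensembling its variants
#'   (default 24 nodes).
#' * Layer 2: one node per family over that family's Layer-1 nodes
#'   (`RNX`, `RNY`), plus one node per common size pairing the X and Y
#'   Layer-1 nodes (default 12 `XY*` nodes).
#' * Layer 3: `RNXY` over (`RNX`, `RNY`) and `RN_XY` over the size-pairing
#'   nodes.
#' * Layer 4: the terminal `RN` over (`RNXY`, `RN_XY`).
#'
#' With the default 12 + 12 backbones and 4 variants this yields 96 leaves
#' and 41 ensemble nodes with per-layer counts (24, 14, 2, 1).
#'
#' @param backbonesX,backbonesY Character vectors of backbone names for the
#'   two families; must have equal length so common sizes can be paired.
#' @param variants Character vector of variant suffixes; each leaf id is
#'   `"<backbone>_<variant>"`.
#' @param method Ensembling method used at every node (default `"cwe"`).
#' @return A validated [EnsembleTopology-class] with terminal node `"RN"`.
#' @examples
#' topo <- buildLayeredTopology()
#' topo
#' @export
buildLayeredTopology <- function(
    backbonesX = paste0("RNX", c("002", "004", "006", "008", "016", "032",
                                 "040", "064", "080", "120", "160", "320")),
    backbonesY = paste0("RNY", c("002", "004", "006", "008", "016", "032",
                                 "040", "064", "080", "120", "160", "320")),
    variants = c("C", "CA", "SEA", "SA"),
    method = "cwe") {
  if (length(backbonesX) != length(backbonesY))
    stop("backbone families must have equal length for size pairing")
  if (anyDuplicated(c(backbonesX, backbonesY)))
    stop("duplicate backbone names")
  if (anyDuplicated(variants) || length(variants) < 1L)
    stop("variants must be non-empty and unique")
  backbones <- c(backbonesX, backbonesY)
  leaves <- as.vector(t(outer(backbones, variants, paste, sep = "_")))
  nodes <- list()
  # Layer 1: each backbone over its variants
  for (b in backbones)
    nodes[[b]] <- TopologyNode(b, 1L, method, paste(b, variants, sep = "_"))
  # Layer 2: family nodes + common-size pairings
  nodes[["RNX"]] <- TopologyNode("RNX", 2L, method, backbonesX)
  nodes[["RNY"]] <- TopologyNode("RNY", 2L, method, backbonesY)
  sizeId <- function(i) {
    sfx <- sub("^[A-Za-z]+", "", backbonesY[i])
    if (!nzchar(sfx)) sfx <- sprintf("%02d", i)
    paste0("XY", sfx)
  }
  xyIds <- vapply(seq_along(backbonesX), sizeId, character(1))
  if (anyDuplicated(xyIds)) xyIds <- paste0("XY", seq_along(backbonesX))
  for (i in seq_along(backbonesX))
    nodes[[xyIds[i]]] <- TopologyNode(xyIds[i], 2L, method,
                                      c(backbonesX[i], backbonesY[i]))
  # Layer 3: pre-final nodes
  nodes[["RNXY"]] <- TopologyNode("RNXY", 3L, method, c("RNX", "RNY"))
  nodes[["RN_XY"]] <- TopologyNode("RN_XY", 3L, method, xyIds)
  # Layer 4: terminal
  nodes[["RN"]] <- TopologyNode("RN", 4L, method, c("RNXY", "RN_XY"))
  EnsembleTopology(leaves, nodes, "RN")
}

# Content-determined execution order: by layer, then node id.
topologicalOrder <- function(topology) {
  nodes <- topology@nodes
  layers <- vapply(nodes, function(n) n@layer, integer(1))
  names(nodes)[order(layers, names(nodes))]
}

#' Execute an ensemble topology over a bundle
#'
#' Nodes run in topological order. At every `"cwe"` node the chi-square
#' weights are refit on the calibration labels from that node's own
#' (possibly already-ensembled) inputs, so each layer re-applies the full
#' scoring procedure. Single-input nodes are identity blends. When
#' `evalLabels` is given, a [MetricReport-class] is computed per node.
#'
#' @param topology A validated [EnsembleTopology-class].
#' @param bundle A [PredictionBundle-class] whose classifier ids cover
#'   `topology@leafIds`.
#' @param calibLabels A [LabelVector-class] used to fit chi-square weights
#'   (a calibration split of the bundle's samples, or all of them in
#'   replication mode).
#' @param evalLabels Optional [LabelVector-class] for per-node metrics.
#' @param mode Weighting mode for `"cwe"` nodes (see [computeWeights()]).
#' @param null Chance null for `"cwe"` nodes (see [expectedFrequencies()]).
#' @return Named list with one entry per node: `prediction`
#'   ([PredictionSet-class]), `weights` ([WeightVector-class] or `NULL`),
#'   `report` ([ChiSquareReport-class] or `NULL`) and `metrics`
#'   ([MetricReport-class] or `NULL`); the attribute `"terminalId"` names
#'   the terminal entry.
#' @export
executeTopology <- function(topology, bundle, calibLabels,
                            evalLabels = NULL,
                            mode = c("one_sided", "raw"),
                            null = c("marginal", "uniform")) {
  validateTopology(topology)
  stopifnot(is(bundle, "PredictionBundle"), is(calibLabels, "LabelVector"))
  mode <- match.arg(mode)
  null <- match.arg(null)
  missing <- setdiff(topology@leafIds, classifierIds(bundle))
  if (length(missing))
    stop("bundle is missing leaf classifier(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  pool <- members(bundle)
  results <- list()
  for (id in topologicalOrder(topology)) {
    nd <- topology@nodes[[id]]
    inputs <- lapply(nd@inputIds, function(i) {
      if (i %in% names(pool)) pool[[i]] else results[[i]]$prediction
    })
    # inputs keep their upstream ids so weights are keyed meaningfully
    sub <- PredictionBundle(inputs)
    weights <- NULL; report <- NULL
    if (length(inputs) == 1L) {
      pred <- PredictionSet(id, sampleIds(sub), inputs[[1L]]@P)
      weights <- WeightVector(nd@inputIds, 1)
    } else if (nd@method == "cwe") {
      fit <- fitCwe(sub, calibLabels, mode = mode, null = null)
      weights <- fit$weights
      report <- fit$report
      pred <- cweBlend(sub, weights, nodeId = id)
    } else if (nd@method == "softmax_avg") {
      pred <- softmaxAverage(sub, nodeId = id)
    } else if (nd@method == "majority_vote") {
      pred <- majorityVote(sub, nodeId = id)
    } else {
      w <- nd@fixedWeights
      if (is.null(w))
        w <- WeightVector(nd@inputIds,
                          rep(1 / length(nd@inputIds), length(nd@inputIds)))
      weights <- w
      pred <- weightedAverage(sub, w, nodeId = id)
    }
    metrics <- if (!is.null(evalLabels))
      metricReport(evalLabels, pred) else NULL
    results[[id]] <- list(prediction = pred, weights = weights,
                          report = report, metrics = metrics)
  }
  attr(results, "terminalId") <- topology@terminalId
  results
}

#' Terminal prediction of executed topology results
#'
#' @param results Return value of [executeTopology()].
#' @return The terminal node's [PredictionSet-class].
#' @export
terminalPrediction <- function(results) {
  results[[attr(results, "terminalId")]]$prediction
}

#' Write a topology to YAML or JSON
#'
#' @param topology An [EnsembleTopology-class].
#' @param path Output path; format inferred from the extension unless given.
#' @param format `"yaml"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
writeTopology <- function(topology, path,
                          format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "yaml"
  obj <- list(
    leaves = as.list(topology@leafIds),
    terminal = topology@terminalId,
    nodes = lapply(unname(topology@nodes), function(n) {
      out <- list(node_id = n@nodeId, layer = n@layer, method = n@method,
                  inputs = as.list(n@inputIds))
      if (!is.null(n@fixedWeights))
        out$fixed_weights <- as.list(ensembleWeights(n@fixedWeights))
      out
    })
  )
  if (format == "json")
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  else
    yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a topology from YAML or JSON
#'
#' @param path Path to a file written by [writeTopology()].
#' @return A validated [EnsembleTopology-class].
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  nodes <- lapply(obj$nodes, function(n) {
    fw <- NULL
    if (!is.null(n$fixed_weights))
      fw <- WeightVector(names(n$fixed_weights),
                         unlist(n$fixed_weights, use.names = FALSE))
    TopologyNode(n$node_id, n$layer, n$method,
                 unlist(n$inputs, use.names = FALSE), fixedWeights = fw)
  })
  EnsembleTopology(unlist(obj$leaves, use.names = FALSE), nodes,
                   obj$terminal)
}
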