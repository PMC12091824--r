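## Forward-pass operators for the three attention mechanisms on a single
## C x H x W feature map. Parameters are supplied explicitly or seeded
## randomly (he-style); no training is performed here.

checkFeatureMap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be a 3-D array of shape C x H x W")
  if (any(!is.finite(x))) stop("feature map must be finite")
  invisible(dim(x))
}

heInit <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

#' Seeded random attention parameters
#'
#' He-style normal initialization (sd `sqrt(2 / fan_in)`) for any of the
#' three operators, reproducible by seed.
#'
#' @param type `"ca"`, `"sea"` or `"sa"`.
#' @param nChannels Number of channels C of the feature maps.
#' @param reduction Bottleneck reduction r (`"ca"`/`"sea"`; must divide C).
#' @param seed Integer RNG seed.
#' @param order Activation order for `"sea"` (see [squeezeExcitation()]).
#' @param gamma Output scale for `"sa"` (see [softAttention()]).
#' @return Parameter list for the matching operator.
#' @export
makeAttentionParams <- function(type = c("ca", "sea", "sa"), nChannels,
                                reduction = 4L, seed = 1L,
                                order = "paper", gamma = 1) {
  type <- match.arg(type)
  withSeed(seed, {
    switch(type,
      ca = caParams(heInit(nChannels %/% reduction, nChannels),
                    heInit(nChannels, nChannels %/% reduction),
                    reduction = reduction),
      sea = seaParams(heInit(nChannels %/% reduction, nChannels),
                      heInit(nChannels, nChannels %/% reduction),
                      order = order),
      sa = saParams(stats::rnorm(nChannels, sd = sqrt(2 / nChannels)),
                    gamma = gamma))
  })
}

#' Channel-attention parameters
#'
#' @param W1 Matrix mapping a C-vector descriptor to C/r.
#' @param W2 Matrix mapping C/r back to C.
#' @param reduction Reduction ratio r; must divide C.
#' @return Parameter list of class `"caParams"`.
#' @export
caParams <- function(W1, W2, reduction = NULL) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  C <- ncol(W1)
  if (nrow(W2) != C || ncol(W2) != nrow(W1))
    stop("W1 (C/r x C) and W2 (C x C/r) have inconsistent shapes")
  if (is.null(reduction)) reduction <- C %/% nrow(W1)
  if (C %% reduction != 0L || C %/% reduction != nrow(W1))
    stop("reduction must divide C and match the bottleneck width")
  structure(list(W1 = W1, W2 = W2, reduction = as.integer(reduction)),
            class = "caParams")
}

#' Squeeze-excitation parameters
#'
#' @param W1 Matrix C -> C/r.
#' @param W2 Matrix C/r -> C.
#' @param order `"paper"` applies `ReLU(W2 sigmoid(W1 z))` exactly as the
#'   excitation is printed in the source formulation (unbounded above);
#'   `"standard"` applies the canonical `sigmoid(W2 ReLU(W1 z))` gate in
#'   (0, 1).
#' @return Parameter list of class `"seaParams"`.
#' @export
seaParams <- function(W1, W2, order = c("paper", "standard")) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  if (nrow(W2) != ncol(W1) || ncol(W2) != nrow(W1))
    stop("W1 (C/r x C) and W2 (C x C/r) have inconsistent shapes")
  structure(list(W1 = W1, W2 = W2, order = match.arg(order)),
            class = "seaParams")
}

#' Soft-attention parameters
#'
#' @param scoreWeights C-vector projecting each spatial position's channel
#'   vector to its scalar attention score.
#' @param gamma Output scale (default 1).
#' @return Parameter list of class `"saParams"`.
#' @export
saParams <- function(scoreWeights, gamma = 1) {
  scoreWeights <- as.numeric(scoreWeights)
  if (any(!is.finite(scoreWeights)) || !is.finite(gamma))
    stop("soft-attention parameters must be finite")
  structure(list(scoreWeights = scoreWeights, gamma = gamma),
            class = "saParams")
}

#' Channel attention forward pass
#'
#' Pools the feature map into a mean descriptor and a (population) standard
#' deviation descriptor per channel, passes each through the shared
#' bottleneck projection `W2 ReLU(W1 .)`, sums the two pre-activations, and
#' gates the input channels with the sigmoid of the sum:
#' `y = sigmoid(W2 relu(W1 m) + W2 relu(W1 s)) * x`. The gate lies in
#' (0, 1) per channel and is constant over the spatial grid.
#'
#' @param x 3-D array C x H x W.
#' @param params A [caParams()] list.
#' @return 3-D array of the same shape.
#' @export
channelAttention <- function(x, params) {
  d <- checkFeatureMap(x)
  stopifnot(inherits(params, "caParams"))
  C <- d[1L]
  if (ncol(params$W1) != C)
    stop("params expect ", ncol(params$W1), " channels, got ", C)
  xm <- matrix(x, nrow = C)             # C x (H*W)
  m <- rowMeans(xm)
  s <- sqrt(rowMeans((xm - m)^2))       # population sd per channel
  pre <- params$W2 %*% relu(params$W1 %*% m) +
         params$W2 %*% relu(params$W1 %*% s)
  w <- sigmoid(as.vector(pre))
  x * w                                  # recycles over the channel dim
}

#' Squeeze-excitation forward pass
#'
#' Squeeze: global average pooling per channel. Excitation: either the
#' as-printed order `ReLU(W2 sigmoid(W1 z))` (`order = "paper"`,
#' nonnegative and unbounded) or the canonical `sigmoid(W2 ReLU(W1 z))`
#' (`order = "standard"`, a (0,1) gate). Scale: `y = s * x`.
#'
#' @param x 3-D array C x H x W.
#' @param params A [seaParams()] list.
#' @param order Optional override of `params$order`.
#' @return 3-D array of the same shape.
#' @export
squeezeExcitation <- function(x, params, order = NULL) {
  d <- checkFeatureMap(x)
  stopifnot(inherits(params, "seaParams"))
  if (is.null(order)) order <- params$order
  order <- match.arg(order, c("paper", "standard"))
  C <- d[1L]
  if (ncol(params$W1) != C)
    stop("params expect ", ncol(params$W1), " channels, got ", C)
  z <- rowMeans(matrix(x, nrow = C))
  s <- if (order == "paper")
    relu(params$W2 %*% sigmoid(params$W1 %*% z))
  else
    sigmoid(params$W2 %*% relu(params$W1 %*% z))
  x * as.vector(s)
}

#' Soft attention forward pass
#'
#' Each spatial position's channel vector is projected to a scalar score
#' `e_i`; a numerically stable softmax over the `T = H * W` positions gives
#' attention weights `a` summing to one; the output is
#' `gamma * a_i * x[, i]` broadcast over channels.
#'
#' @param x 3-D array C x H x W.
#' @param params A [saParams()] list.
#' @return List with `output` (3-D array, same shape) and `attention`
#'   (H x W matrix summing to 1).
#' @export
softAttention <- function(x, params) {
  d <- checkFeatureMap(x)
  stopifnot(inherits(params, "saParams"))
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  if (length(params$scoreWeights) != C)
    stop("scoreWeights must have one entry per channel")
  xm <- matrix(x, nrow = C)
  e <- as.vector(crossprod(xm, params$scoreWeights))
  a <- stableSoftmax(e)
  y <- params$gamma * x * array(rep(a, each = C), dim = d)
  list(output = y, attention = matrix(a, H, W))
}
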