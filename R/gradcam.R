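## Grad-CAM aggregation: given a layer's activations and the gradients of a
## class score with respect to them (both supplied by the caller), pool the
## gradients per channel, weight and sum the activation channels, rectify,
## and min-max normalize to [0, 1]. Gradient computation itself is out of
## scope by contract.

checkStack <- function(x, what) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a 3-D array of shape H x W x K")
  if (any(!is.finite(x))) stop(what, " must be finite")
  invisible(dim(x))
}

#' Channel importances by spatial gradient pooling
#'
#' @param g 3-D array H x W x K of class-score gradients with respect to
#'   the activations.
#' @return Numeric K-vector; entry k is the spatial mean of `g[,,k]`.
#' @export
pooledGradients <- function(g) {
  checkStack(g, "gradient stack")
  apply(g, 3L, mean)
}

#' Class activation heatmap
#'
#' Weights each activation channel by its pooled-gradient importance, sums
#' over channels, rectifies (negative contributions are discarded by
#' default), and min-max normalizes to `[0, 1]`. A rectified map with zero
#' range yields an all-zero heatmap rather than NaN.
#'
#' @param a 3-D array H x W x K of activations.
#' @param alphas Numeric K-vector of channel importances (see
#'   [pooledGradients()]).
#' @param rectify Apply ReLU before normalization (default `TRUE`).
#' @return H x W matrix with values in `[0, 1]`.
#' @examples
#' a <- array(seq(0, 2, length.out = 8), c(2, 2, 2))
#' camHeatmap(a, c(1, 0))
#' @export
camHeatmap <- function(a, alphas, rectify = TRUE) {
  d <- checkStack(a, "activation stack")
  if (length(alphas) != d[3L])
    stop("alphas must have one entry per activation channel")
  raw <- matrix(matrix(a, ncol = d[3L]) %*% as.numeric(alphas),
                d[1L], d[2L])
  m <- if (rectify) pmax(raw, 0) else raw
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(matrix(0, d[1L], d[2L]))
  (m - lo) / (hi - lo)
}

#' Fixed jet-like colormap lookup table
#'
#' A 256-entry blue-cyan-yellow-red colormap computed in code so overlays
#' are reproducible across platforms.
#'
#' @param n Number of entries (default 256).
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
jetColormap <- function(n = 256L) {
  t <- seq(0, 1, length.out = n)
  interp <- function(v) pmin(pmax(1.5 - abs(4 * v), 0), 1)
  cbind(red = interp(t - 0.75), green = interp(t - 0.5),
        blue = interp(t - 0.25))
}

# Bilinear resize of a matrix onto an nh x nw grid (align-corners style).
bilinearResize <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  if (h == nh && w == nw) return(m)
  ri <- if (h == 1L) rep(1, nh) else seq(1, h, length.out = nh)
  ci <- if (w == 1L) rep(1, nw) else seq(1, w, length.out = nw)
  r0 <- pmax(pmin(floor(ri), h - 1L), 1L); fr <- ri - r0
  c0 <- pmax(pmin(floor(ci), w - 1L), 1L); fc <- ci - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  out <- outer(1 - fr, 1 - fc) * m[r0, c0, drop = FALSE] +
         outer(1 - fr, fc)     * m[r0, c1, drop = FALSE] +
         outer(fr, 1 - fc)     * m[r1, c0, drop = FALSE] +
         outer(fr, fc)         * m[r1, c1, drop = FALSE]
  out
}

#' Overlay a heatmap on an RGB image
#'
#' The heatmap is resized to the image grid by bilinear interpolation,
#' mapped through the colormap, and alpha-blended:
#' `out = (1 - alpha) * image + alpha * colormap(heatmap)`, clipped to
#' `[0, 1]`.
#'
#' @param h H x W heatmap matrix in `[0, 1]`.
#' @param image H' x W' x 3 array of RGB values in `[0, 1]`.
#' @param alpha Blend factor in `[0, 1]` (0 = original image).
#' @param colormap n x 3 RGB lookup table (default [jetColormap()]).
#' @return H' x W' x 3 RGB array in `[0, 1]`.
#' @export
overlayHeatmap <- function(h, image, alpha = 0.4,
                           colormap = jetColormap()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (min(h) < 0 || max(h) > 1) stop("heatmap values must lie in [0, 1]")
  hh <- bilinearResize(as.matrix(h), dim(image)[1L], dim(image)[2L])
  hh <- pmin(pmax(hh, 0), 1)
  idx <- pmin(floor(hh * (nrow(colormap) - 1L)) + 1L, nrow(colormap))
  cmapped <- array(0, dim(image))
  for (ch in 1:3)
    cmapped[, , ch] <- matrix(colormap[idx, ch], nrow(hh), ncol(hh))
  out <- (1 - alpha) * image + alpha * cmapped
  pmin(pmax(out, 0), 1)
}

#' Write an RGB array to PNG
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePng <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG files")
  png::writePNG(aperm(image, c(1, 2, 3)), path)
  invisible(path)
}
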