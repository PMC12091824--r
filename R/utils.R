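## Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Numerically stable softmax over a numeric vector.
stableSoftmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# 0/0 -> 0 division used by metric cells with empty denominators.
safeDiv <- function(num, den) ifelse(den == 0, 0, num / den)
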