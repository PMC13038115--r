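# Shared fixtures: a micro model configuration cheap enough for CPU tests,
# small random feature maps, and brute-force oracles used against the
# production implementations.

microConfig <- function(...) {
  args <- list(embedDim = 4L, depths = c(1L, 1L, 1L, 2L),
               decoderDepths = c(1L, 1L, 1L), window = c(2L, 2L, 2L),
               dilation = c(2L, 2L, 2L), heads = c(1L, 1L, 2L, 4L),
               patchSize = c(2L, 2L, 2L), dropout = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(modelConfig, args)
}

randomFeature <- function(channels, grid, seed = 1L) {
  set.seed(seed)
  array(rnorm(channels * prod(grid)), c(channels, grid))
}

# brute-force softmax attention over an explicit token matrix (no windows)
denseAttentionOracle <- function(x, qkvWeight, qkvBias = NULL, heads = 1L,
                                 bias = NULL) {
  C <- ncol(x)
  d <- C / heads
  qkv <- x %*% qkvWeight
  if (!is.null(qkvBias)) qkv <- sweep(qkv, 2L, qkvBias, "+")
  out <- matrix(0, nrow(x), C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * d + 1):(h * d)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, C + cols, drop = FALSE]
    V <- qkv[, 2 * C + cols, drop = FALSE]
    for (i in seq_len(nrow(x))) {
      s <- as.numeric(Q[i, ] %*% t(K)) / sqrt(d)
      if (!is.null(bias))
        s <- s + (if (length(dim(bias)) == 3L) bias[i, , h] else bias[i, ])
      e <- exp(s - max(s))
      a <- e / sum(e)
      out[i, cols] <- a %*% V
    }
  }
  out
}

# O(n^2) pairwise surface-distance oracle (mm)
bruteSurfaceDistances <- function(from, to, spacing = c(1, 1, 1)) {
  bf <- which(surfaceVoxels(from), arr.ind = TRUE)
  bt <- which(surfaceVoxels(to), arr.ind = TRUE)
  if (nrow(bf) == 0) return(numeric(0))
  if (nrow(bt) == 0) return(rep(Inf, nrow(bf)))
  apply(bf, 1L, function(v)
    sqrt(min(colSums((t(bt) - v)^2 * spacing^2))))
}

randomMask <- function(grid, pFill = 0.3, seed = 1L) {
  set.seed(seed)
  array(runif(prod(grid)) < pFill, grid)
}

# small labelled phantom suitable for 16^3-input micro models
tinyCase <- function(seed = 1L, extents = c(16L, 16L, 16L)) {
  generatePhantom(phantomSpec(extents, tumorFraction = 0.08, seed = seed),
                  id = sprintf("tiny-%d", seed))
}
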