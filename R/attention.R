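# Window partitioning, windowed / dilated-window multi-head self-attention,
# the alternating transformer block, and the analytic complexity formulas.

## ---- partition index maps --------------------------------------------------

# Standard partition: non-overlapping (pD,pH,pW) windows on a (D,H,W) grid.
# Returns an N x nWin matrix of 1-based token indices; column j lists the
# tokens of window j in within-window order (depth fastest).
windowIndexMap <- function(grid, p) {
  stopifnot(all(grid %% p == 0L))
  t0 <- 0:(prod(grid) - 1L)
  co <- tokenCoords(t0, grid)
  nw <- grid %/% p
  win <- (co[, 1L] %/% p[1L]) +
    nw[1L] * ((co[, 2L] %/% p[2L]) + nw[2L] * (co[, 3L] %/% p[3L]))
  pos <- (co[, 1L] %% p[1L]) +
    p[1L] * ((co[, 2L] %% p[2L]) + p[2L] * (co[, 3L] %% p[3L]))
  idx <- matrix(0L, prod(p), prod(nw))
  idx[cbind(pos + 1L, win + 1L)] <- t0 + 1L
  idx
}

# Dilated partition: the grid is tiled by contiguous (M = r*p) blocks; within
# a block, the patches congruent to one residue class modulo r form one
# window, so every window holds prod(p) patches at stride r and the residue
# classes jointly cover every patch exactly once. With r = (1,1,1) this is
# the standard partition, window for window.
dilatedIndexMap <- function(grid, p, r) {
  M <- p * r
  stopifnot(all(grid %% M == 0L))
  t0 <- 0:(prod(grid) - 1L)
  co <- tokenCoords(t0, grid)
  nb <- grid %/% M
  blk <- (co[, 1L] %/% M[1L]) +
    nb[1L] * ((co[, 2L] %/% M[2L]) + nb[2L] * (co[, 3L] %/% M[3L]))
  loc <- cbind(co[, 1L] %% M[1L], co[, 2L] %% M[2L], co[, 3L] %% M[3L])
  res <- (loc[, 1L] %% r[1L]) +
    r[1L] * ((loc[, 2L] %% r[2L]) + r[2L] * (loc[, 3L] %% r[3L]))
  win <- blk + prod(nb) * res
  pos <- (loc[, 1L] %/% r[1L]) +
    p[1L] * ((loc[, 2L] %/% r[2L]) + p[2L] * (loc[, 3L] %/% r[3L]))
  idx <- matrix(0L, prod(p), prod(nb) * prod(r))
  idx[cbind(pos + 1L, win + 1L)] <- t0 + 1L
  idx
}

# Relative-position-bias lookup: table rows are indexed by the raw spatial
# offset between two patches of one window. For a dilated window the offsets
# are multiples of r, so the table spans (2*span - 1) entries per axis with
# span = configured window * configured dilation; runtime-clamped windows use
# the central sub-range. Returns an N^2 vector of table row indices in
# (query, key) column-major order.
biasIndexMatrix <- function(p, r, span) {
  n <- prod(p)
  a0 <- 0:(n - 1L)
  ad <- a0 %% p[1L]
  ah <- (a0 %/% p[1L]) %% p[2L]
  aw <- a0 %/% (p[1L] * p[2L])
  offAxis <- function(a, rr, sp) {
    o <- outer(a, a, "-") * rr          # query - key, raw offset
    o + sp - 1L
  }
  i1 <- offAxis(ad, r[1L], span[1L])
  i2 <- offAxis(ah, r[2L], span[2L])
  i3 <- offAxis(aw, r[3L], span[3L])
  as.integer(i1 + (2L * span[1L] - 1L) * (i2 + (2L * span[2L] - 1L) * i3)) + 1L
}

## ---- exported functional partition API -------------------------------------

resolvePadding <- function(grid, unit, padding) {
  padded <- as.integer(ceiling(grid / unit) * unit)
  if (any(padded != grid) && padding == "strict")
    stop("feature extents (", paste(grid, collapse = "x"),
         ") are not divisible by the window unit (",
         paste(unit, collapse = "x"), ") under strict padding")
  padded
}

partitionCore <- function(x, window, dilation, padding) {
  padding <- match.arg(padding, c("strict", "pad"))
  tok <- featureToTokens(x)
  grid <- attr(tok, "grid")
  p <- as.integer(window); r <- as.integer(dilation)
  padded <- resolvePadding(grid, p * r, padding)
  pm <- padTokenMap(grid, padded)
  X2 <- matrix(0, prod(padded), ncol(tok))
  X2[pm, ] <- tok
  idx <- if (all(r == 1L)) windowIndexMap(padded, p)
         else dilatedIndexMap(padded, p, r)
  blocks <- array(X2[as.vector(idx), ], c(nrow(idx), ncol(idx), ncol(tok)))
  blocks <- aperm(blocks, c(1L, 3L, 2L))       # (N, C, nWin)
  structure(list(blocks = blocks, index = idx, grid = grid, padded = padded,
                 window = p, dilation = r, channels = dim(x)[1L]),
            class = "windowPartition")
}

#' Partition a feature map into non-overlapping 3D windows
#'
#' Splits a (C, D, H, W) feature map into windows of \code{window} patches
#' per axis (D, H, W order). Every patch lands in exactly one window; the
#' returned index map inverts the partition via [reverseWindows()].
#'
#' @param x numeric array (C, D, H, W).
#' @param window integer(3), patches per window along (D, H, W).
#' @param padding \code{"strict"} errors on non-divisible extents;
#'   \code{"pad"} zero-pads symmetrically to the next multiple (padded slots
#'   carry index 0 semantics only through the internal attention path and are
#'   dropped again by [reverseWindows()]).
#' @return A \code{windowPartition}: list with \code{blocks}, an
#'   (N, C, nWindows) array of window token blocks, and \code{index}, the
#'   N x nWindows map of token positions.
#' @examples
#' x <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
#' pw <- partitionWindows(x, c(2, 2, 2))
#' dim(pw$blocks)   # 8 patches per window, 1 channel, 8 windows
#' stopifnot(identical(reverseWindows(pw), x))
#' @export
partitionWindows <- function(x, window, padding = c("strict", "pad"))
  partitionCore(x, window, c(1L, 1L, 1L), match.arg(padding))

#' Partition a feature map into dilated 3D windows
#'
#' Tiles the grid with contiguous blocks of \code{window * dilation} patches
#' per axis; within each block the patches at stride \code{dilation}
#' (one window per residue class) form a window. Each window therefore holds
#' the same number of patches as the standard partition while spanning a
#' \code{dilation}-fold larger receptive field, and the union over residue
#' classes covers every patch exactly once.
#'
#' @inheritParams partitionWindows
#' @param dilation integer(3), dilation factors along (D, H, W).
#' @return A \code{windowPartition}, as [partitionWindows()].
#' @export
partitionDilatedWindows <- function(x, window, dilation,
                                    padding = c("strict", "pad"))
  partitionCore(x, window, dilation, match.arg(padding))

#' Invert a window partition
#'
#' Reassembles the feature map from a \code{windowPartition}, dropping any
#' padding. Round-trips bit-for-bit.
#'
#' @param partition a \code{windowPartition} from [partitionWindows()] or
#'   [partitionDilatedWindows()].
#' @return numeric array (C, D, H, W).
#' @export
reverseWindows <- function(partition) {
  stopifnot(inherits(partition, "windowPartition"))
  blocks <- aperm(partition$blocks, c(1L, 3L, 2L))   # (N, nWin, C)
  C <- dim(blocks)[3L]
  X2 <- matrix(0, prod(partition$padded), C)
  X2[as.vector(partition$index), ] <- matrix(blocks, ncol = C)
  pm <- padTokenMap(partition$grid, partition$padded)
  tokensToFeature(X2[pm, , drop = FALSE], partition$grid)
}

## ---- functional attention --------------------------------------------------

#' Multi-head self-attention over one window of tokens
#'
#' Computes \code{softmax(Q K' / sqrt(d) + B) V} per head, followed by an
#' output projection. Q, K, V come from a single linear map of the tokens;
#' \code{d} is the per-head dimension and \code{B} an optional additive
#' relative-position bias.
#'
#' @param x numeric matrix (N tokens x C channels), all finite.
#' @param qkvWeight C x 3C projection matrix (columns: Q, then K, then V).
#' @param qkvBias optional length-3C bias.
#' @param projWeight optional C x C output projection (identity if NULL).
#' @param projBias optional length-C projection bias.
#' @param heads number of attention heads; must divide C.
#' @param bias optional relative-position bias: N x N matrix (shared) or
#'   N x N x heads array.
#' @return list with \code{output} (N x C) and \code{weights}
#'   (N x N x heads attention matrix; rows sum to 1).
#' @export
windowAttention <- function(x, qkvWeight, qkvBias = NULL, projWeight = NULL,
                            projBias = NULL, heads = 1L, bias = NULL) {
  checkFinite(x, "attention input")
  C <- ncol(x); N <- nrow(x)
  if (C %% heads != 0L)
    stop("channel count ", C, " is not divisible by ", heads, " heads")
  if (nrow(qkvWeight) != C || ncol(qkvWeight) != 3L * C)
    stop("qkvWeight must be C x 3C for C = ", C)
  d <- C %/% heads
  qkv <- x %*% qkvWeight
  if (!is.null(qkvBias)) qkv <- sweep(qkv, 2L, qkvBias, "+")
  out <- matrix(0, N, C)
  wts <- array(0, c(N, N, heads))
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, C + cols, drop = FALSE]
    V <- qkv[, 2L * C + cols, drop = FALSE]
    S <- tcrossprod(Q, K) / sqrt(d)
    if (!is.null(bias))
      S <- S + if (length(dim(bias)) == 3L) bias[, , h] else bias
    A <- softmaxRows(S)
    wts[, , h] <- A
    out[, cols] <- A %*% V
  }
  if (!is.null(projWeight)) out <- out %*% projWeight
  if (!is.null(projBias)) out <- sweep(out, 2L, projBias, "+")
  list(output = out, weights = wts)
}

## ---- trainable MSA module --------------------------------------------------

# Windowed (dilation NULL) or dilated-window multi-head self-attention as a
# trainable module operating on token matrices. The relative-bias table is
# sized from the configured window/dilation alone so that the parameter count
# is independent of the input extent; runtime grids smaller than the window
# clamp the window (and dilation) and index the central part of the table.
msaLayer <- function(dim, heads, window, dilation = NULL, qkvBias = TRUE,
                     projDropout = 0, padding = "pad", name = "msa") {
  window <- as.integer(window)
  cfgR <- if (is.null(dilation)) c(1L, 1L, 1L) else as.integer(dilation)
  span <- window * cfgR
  tab <- newParam(matrix(0, prod(2L * span - 1L), heads),
                  paste0(name, ".biasTable"))
  qkv <- lyLinear(dim, 3L * dim, bias = qkvBias, name = paste0(name, ".qkv"))
  proj <- lyLinear(dim, dim, name = paste0(name, ".proj"))
  drop <- lyDropout(projDropout)
  d <- dim %/% heads
  scale <- 1 / sqrt(d)
  cache <- new.env(parent = emptyenv())
  list(
    kind = if (is.null(dilation)) "wmsa" else "dwmsa",
    params = list(qkv = qkv$params, proj = proj$params, biasTable = tab),
    forward = function(x, grid, training = FALSE) {
      p <- pmin(window, grid)
      r <- if (is.null(dilation)) c(1L, 1L, 1L)
           else pmax(1L, pmin(cfgR, grid %/% p))
      padded <- resolvePadding(grid, p * r, padding)
      pm <- padTokenMap(grid, padded)
      T2 <- prod(padded)
      X2 <- matrix(0, T2, dim)
      X2[pm, ] <- x
      valid <- logical(T2); valid[pm] <- TRUE
      G <- qkv$forward(X2, training)
      idx <- if (all(r == 1L)) windowIndexMap(padded, p)
             else dilatedIndexMap(padded, p, r)
      bIdx <- biasIndexMatrix(p, r, span)
      N <- nrow(idx); nWin <- ncol(idx)
      O <- matrix(0, T2, dim)
      Alist <- vector("list", nWin * heads)
      for (w in seq_len(nWin)) {
        rows <- idx[, w]
        vmask <- valid[rows]
        anyInvalid <- !all(vmask)
        for (h in seq_len(heads)) {
          cols <- ((h - 1L) * d + 1L):(h * d)
          Q <- G[rows, cols, drop = FALSE]
          K <- G[rows, dim + cols, drop = FALSE]
          V <- G[rows, 2L * dim + cols, drop = FALSE]
          S <- tcrossprod(Q, K) * scale +
            matrix(tab$value[bIdx, h], N, N)
          if (anyInvalid) S[, !vmask] <- -Inf
          A <- softmaxRows(S)
          Alist[[(w - 1L) * heads + h]] <- A
          O[rows, cols] <- A %*% V
        }
      }
      cache$G <- G; cache$idx <- idx; cache$bIdx <- bIdx
      cache$A <- Alist; cache$pm <- pm; cache$T2 <- T2
      Y <- drop$forward(proj$forward(O[pm, , drop = FALSE], training),
                        training)
      Y
    },
    backward = function(dy) {
      dOc <- proj$backward(drop$backward(dy))
      T2 <- cache$T2; idx <- cache$idx
      dO <- matrix(0, T2, dim)
      dO[cache$pm, ] <- dOc
      G <- cache$G
      dG <- matrix(0, T2, 3L * dim)
      N <- nrow(idx); nWin <- ncol(idx)
      dTab <- matrix(0, nrow(tab$value), heads)
      for (w in seq_len(nWin)) {
        rows <- idx[, w]
        for (h in seq_len(heads)) {
          cols <- ((h - 1L) * d + 1L):(h * d)
          A <- cache$A[[(w - 1L) * heads + h]]
          dOw <- dO[rows, cols, drop = FALSE]
          V <- G[rows, 2L * dim + cols, drop = FALSE]
          dV <- crossprod(A, dOw)
          dA <- tcrossprod(dOw, V)
          dS <- A * (dA - rowSums(dA * A))
          agg <- rowsum(as.vector(dS), cache$bIdx)
          ridx <- as.integer(rownames(agg))
          dTab[ridx, h] <- dTab[ridx, h] + agg[, 1L]
          K <- G[rows, dim + cols, drop = FALSE]
          Q <- G[rows, cols, drop = FALSE]
          dG[rows, cols] <- dG[rows, cols, drop = FALSE] + (dS %*% K) * scale
          dG[rows, dim + cols] <- dG[rows, dim + cols, drop = FALSE] +
            crossprod(dS, Q) * scale
          dG[rows, 2L * dim + cols] <- dG[rows, 2L * dim + cols,
                                          drop = FALSE] + dV
        }
      }
      tab$grad <- tab$grad + dTab
      dX2 <- qkv$backward(dG)
      dX2[cache$pm, , drop = FALSE]
    })
}

## ---- alternating transformer block -----------------------------------------

#' Build one alternating windowed/dilated-window transformer block
#'
#' One block applies, in order: dynamic depthwise-convolutional position
#' encoding (residual), pre-norm windowed multi-head self-attention
#' (residual), pre-norm MLP (residual), pre-norm dilated-window attention
#' (residual), and a second pre-norm MLP (residual). Resolution and channel
#' count are unchanged.
#'
#' @param channels token channel count.
#' @param heads attention heads (must divide \code{channels}).
#' @param window integer(3), window extent in patches (D, H, W).
#' @param dilation integer(3), dilation factors for the dilated half.
#' @param mlpRatio MLP hidden expansion.
#' @param dropout dropout probability (MLP and projection paths; inactive in
#'   inference mode).
#' @param qkvBias bias on the qkv projections.
#' @param dipeKernel depthwise position-encoding kernel extent.
#' @return An internal block module usable with [vitBlockForward()].
#' @export
buildVitBlock <- function(channels, heads, window, dilation = c(2L, 2L, 2L),
                          mlpRatio = 4, dropout = 0, qkvBias = TRUE,
                          dipeKernel = 3L) {
  dipe <- lyDIPE(channels, dipeKernel)
  ln1 <- lyLayerNorm(channels); ln2 <- lyLayerNorm(channels)
  ln3 <- lyLayerNorm(channels); ln4 <- lyLayerNorm(channels)
  msaW <- msaLayer(channels, heads, window, NULL, qkvBias, dropout)
  msaD <- msaLayer(channels, heads, window, dilation, qkvBias, dropout)
  mlp1 <- lyMLP(channels, mlpRatio, dropout)
  mlp2 <- lyMLP(channels, mlpRatio, dropout)
  list(
    kind = "vitBlock", channels = channels,
    params = list(dipe = dipe$params, ln1 = ln1$params, msaW = msaW$params,
                  ln2 = ln2$params, mlp1 = mlp1$params, ln3 = ln3$params,
                  msaD = msaD$params, ln4 = ln4$params, mlp2 = mlp2$params),
    forward = function(x, grid, training = FALSE) {
      x <- dipe$forward(x, grid, training)
      x <- x + msaW$forward(ln1$forward(x, training), grid, training)
      x <- x + mlp1$forward(ln2$forward(x, training), training)
      x <- x + msaD$forward(ln3$forward(x, training), grid, training)
      x + mlp2$forward(ln4$forward(x, training), training)
    },
    backward = function(dy) {
      dy <- dy + ln4$backward(mlp2$backward(dy))
      dy <- dy + ln3$backward(msaD$backward(dy))
      dy <- dy + ln2$backward(mlp1$backward(dy))
      dy <- dy + ln1$backward(msaW$backward(dy))
      dipe$backward(dy)
    })
}

#' Run one transformer block on a feature map
#'
#' @param block a block from [buildVitBlock()].
#' @param x numeric array (C, D, H, W) with C equal to the block's channels.
#' @param training logical; enables dropout.
#' @return numeric array of the same shape as \code{x}.
#' @export
vitBlockForward <- function(block, x, training = FALSE) {
  stopifnot(length(dim(x)) == 4L)
  if (dim(x)[1L] != block$channels)
    stop("feature map has ", dim(x)[1L], " channels; block expects ",
         block$channels)
  tok <- featureToTokens(x)
  grid <- attr(tok, "grid")
  tokensToFeature(block$forward(tok, grid, training), grid)
}

## ---- analytic complexity ---------------------------------------------------

#' Analytic self-attention complexity
#'
#' Multiply-accumulate count of one multi-head self-attention layer over a
#' feature map of \code{omega} patches with \code{channels} channels:
#' dense (global) attention costs \eqn{4 \Omega C^2 + 2 \Omega^2 C}, windowed
#' attention with N patches per window costs \eqn{4 \Omega C^2 + 2 N \Omega C}
#' — linear in the total patch count for fixed window. (A commonly quoted
#' windowed form drops the channel factor from its first term; the
#' dimensionally consistent forms above are used throughout this package.)
#'
#' @param omega total number of patches in the feature map.
#' @param channels channel count C.
#' @param windowPatches patches per window N (windowed mode only; N <= omega).
#' @param mode \code{"windowed"} or \code{"dense"}.
#' @return multiply-accumulate count (numeric scalar).
#' @examples
#' complexityEstimate(64, 8, 8, "windowed")
#' @export
complexityEstimate <- function(omega, channels, windowPatches = NULL,
                               mode = c("windowed", "dense")) {
  mode <- match.arg(mode)
  stopifnot(omega > 0, channels > 0)
  if (mode == "dense")
    return(4 * omega * channels^2 + 2 * omega^2 * channels)
  stopifnot(!is.null(windowPatches), windowPatches > 0,
            windowPatches <= omega)
  4 * omega * channels^2 + 2 * windowPatches * omega * channels
}

#' Dynamic input-dependent position encoding
#'
#' Applies a per-channel (depthwise) 3D convolution to the feature map and
#' adds the result to the input, injecting learned absolute/relative
#' positional information. The convolution runs at native resolution with
#' zero padding, so the output shape equals the input shape; a zero kernel
#' reduces the operation to the identity.
#'
#' @param x numeric array (C, D, H, W).
#' @param kernel numeric array: (k, k, k) (shared across channels) or
#'   (k, k, k, C) with one filter per channel; k odd.
#' @param bias optional length-C additive bias on the convolution output.
#' @return numeric array of the same shape as \code{x}.
#' @examples
#' x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
#' stopifnot(identical(dipeEncode(x, array(0, c(3, 3, 3))), x))
#' @export
dipeEncode <- function(x, kernel, bias = NULL) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[1L]
  kd <- dim(kernel)
  if (length(kd) == 3L) kernel <- array(kernel, c(kd, C))
  else if (length(kd) != 4L || kd[4L] != C)
    stop("kernel must have one filter per input channel (", C, ")")
  if (dim(kernel)[1L] %% 2L != 1L) stop("kernel extent must be odd")
  a <- aperm(x, c(2L, 3L, 4L, 1L))
  conv <- depthwiseConv3(a, kernel)
  if (!is.null(bias)) conv <- sweep(conv, 4L, bias, "+")
  x + aperm(conv, c(4L, 1L, 2L, 3L))
}
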