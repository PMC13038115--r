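# U-shaped assembly: patch embedding, three encoder stages with patch
# merging, bottleneck, symmetric decoder with patch expanding and skip
# fusion, and the fused terminal expansion that maps final-stage tokens
# directly to per-voxel class scores.

## ---- patch regrouping helpers ---------------------------------------------

# (D,H,W,C) array -> (T/prod(f)) x (prod(f)*C) matrix grouping each f-block
# of voxels into one row (child order: depth fastest, channel slowest)
gatherPatches <- function(a, f) {
  d <- dim(a)
  g <- d[1:3] %/% f
  stopifnot(all(d[1:3] %% f == 0L))
  b <- array(a, c(f[1L], g[1L], f[2L], g[2L], f[3L], g[3L], d[4L]))
  b <- aperm(b, c(2L, 4L, 6L, 1L, 3L, 5L, 7L))
  dim(b) <- c(prod(g), prod(f) * d[4L])
  b
}

# inverse of gatherPatches: rows over the coarse grid g, columns
# (child, channel) -> (g*f, C) array
scatterPatches <- function(m, g, f, C) {
  b <- array(m, c(g[1L], g[2L], g[3L], f[1L], f[2L], f[3L], C))
  b <- aperm(b, c(4L, 1L, 5L, 2L, 6L, 3L, 7L))
  dim(b) <- c(g * f, C)
  b
}

tokensToMerged <- function(tok, grid) {
  gatherPatches(array(tok, c(grid, ncol(tok))), c(2L, 2L, 2L))
}

## ---- exported functional resampling ops ------------------------------------

#' Embed a volume into a patch-token grid
#'
#' Partitions the input volume into non-overlapping \code{patchSize} blocks
#' and linearly projects each block (all voxels, all channels) to one token.
#'
#' @param x numeric array (C_in, D, H, W).
#' @param patchSize integer(3) patch extent (D, H, W); extents must divide.
#' @param weight projection matrix, \code{prod(patchSize)*C_in} rows.
#' @param bias optional bias of length \code{ncol(weight)}.
#' @return numeric array (C_out, D/p1, H/p2, W/p3).
#' @export
patchEmbed <- function(x, patchSize, weight, bias = NULL) {
  stopifnot(length(dim(x)) == 4L)
  p <- as.integer(patchSize)
  if (any(dim(x)[2:4] %% p != 0L))
    stop("input extents must be divisible by the patch size")
  a <- aperm(x, c(2L, 3L, 4L, 1L))
  m <- gatherPatches(a, p)
  if (nrow(weight) != ncol(m))
    stop("weight must have ", ncol(m), " rows (prod(patchSize) * channels)")
  y <- m %*% weight
  if (!is.null(bias)) y <- sweep(y, 2L, bias, "+")
  tokensToFeature(y, dim(x)[2:4] %/% p)
}

#' Merge 2x2x2 token neighborhoods
#'
#' Concatenates each 2x2x2 neighborhood of tokens into one token of 8C
#' channels (reducing the token count by a factor of 8) and, if a weight is
#' given, linearly reduces the concatenation — to 2C in the standard
#' schedule, doubling the channel width while halving every spatial extent.
#'
#' @param x numeric array (C, D, H, W); spatial extents must be even.
#' @param weight optional reduction matrix with 8C rows.
#' @return numeric array (8C or ncol(weight), D/2, H/2, W/2).
#' @export
patchMerge <- function(x, weight = NULL) {
  stopifnot(length(dim(x)) == 4L)
  if (any(dim(x)[2:4] %% 2L != 0L))
    stop("patch merging requires even spatial extents")
  a <- aperm(x, c(2L, 3L, 4L, 1L))
  m <- gatherPatches(a, c(2L, 2L, 2L))
  if (!is.null(weight)) {
    if (nrow(weight) != ncol(m)) stop("weight must have ", ncol(m), " rows")
    m <- m %*% weight
  }
  tokensToFeature(m, dim(x)[2:4] %/% 2L)
}

#' Expand tokens by 2x2x2
#'
#' Linearly maps each token to eight child tokens of half the channel count,
#' doubling every spatial extent: the inverse resampling of [patchMerge()].
#'
#' @param x numeric array (C, D, H, W); C must be even.
#' @param weight expansion matrix C x 4C (columns ordered child-fastest,
#'   giving each of the 8 children C/2 channels). Defaults to replicating
#'   the first C/2 channels into every child.
#' @return numeric array (C/2, 2D, 2H, 2W).
#' @export
patchExpand <- function(x, weight = NULL) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[1L]
  if (C %% 2L != 0L) stop("patch expansion requires an even channel count")
  half <- C %/% 2L
  if (is.null(weight)) {
    pick <- rbind(diag(half), matrix(0, half, half))
    weight <- do.call(cbind, rep(list(pick), 8L))
  }
  if (nrow(weight) != C || ncol(weight) != 4L * C)
    stop("weight must be C x 4C")
  tok <- featureToTokens(x)
  y <- tok %*% weight
  a <- scatterPatches(y, dim(x)[2:4], c(2L, 2L, 2L), half)
  aperm(a, c(4L, 1L, 2L, 3L))
}

#' Fuse decoder features with an encoder skip connection
#'
#' Concatenates decoder and encoder feature maps along channels and linearly
#' reduces back to the decoder channel count.
#'
#' @param decoder,encoder numeric arrays (C, D, H, W) with equal shapes.
#' @param weight reduction matrix 2C x C; defaults to averaging the two
#'   inputs channel-for-channel.
#' @return numeric array shaped like \code{decoder}.
#' @export
skipFuse <- function(decoder, encoder, weight = NULL) {
  if (!identical(dim(decoder), dim(encoder)))
    stop("decoder and encoder feature maps must share their shape")
  C <- dim(decoder)[1L]
  if (is.null(weight)) weight <- rbind(diag(C), diag(C)) / 2
  if (nrow(weight) != 2L * C)
    stop("weight must have 2C rows")
  tok <- cbind(featureToTokens(decoder), featureToTokens(encoder))
  tokensToFeature(tok %*% weight, dim(decoder)[2:4])
}

## ---- trainable resampling modules ------------------------------------------

lyPatchEmbed <- function(patch, cin, cout, name = "embed") {
  lin <- lyLinear(prod(patch) * cin, cout, name = paste0(name, ".proj"))
  ln <- lyLayerNorm(cout, name = paste0(name, ".norm"))
  cache <- new.env(parent = emptyenv())
  list(kind = "patchEmbed",
       params = list(proj = lin$params, norm = ln$params),
       forward = function(vol, training = FALSE) {
         a <- aperm(vol, c(2L, 3L, 4L, 1L))
         cache$gin <- dim(vol)[2:4]
         ln$forward(lin$forward(gatherPatches(a, patch), training), training)
       },
       backward = function(dy) {
         dm <- lin$backward(ln$backward(dy))
         g <- cache$gin %/% patch
         da <- scatterPatches(dm, g, patch, cin)
         aperm(da, c(4L, 1L, 2L, 3L))
       })
}

lyPatchMerge <- function(cin, name = "merge") {
  ln <- lyLayerNorm(8L * cin, name = paste0(name, ".norm"))
  lin <- lyLinear(8L * cin, 2L * cin, bias = FALSE,
                  name = paste0(name, ".reduce"))
  cache <- new.env(parent = emptyenv())
  list(kind = "patchMerge",
       params = list(norm = ln$params, reduce = lin$params),
       forward = function(x, grid, training = FALSE) {
         cache$grid <- grid
         lin$forward(ln$forward(tokensToMerged(x, grid), training), training)
       },
       backward = function(dy) {
         dm <- ln$backward(lin$backward(dy))
         g <- cache$grid %/% 2L
         da <- scatterPatches(dm, g, c(2L, 2L, 2L), cin)
         matrix(da, prod(cache$grid), cin)
       })
}

lyPatchExpand <- function(cin, name = "expand") {
  half <- cin %/% 2L
  lin <- lyLinear(cin, 4L * cin, bias = FALSE, name = paste0(name, ".proj"))
  ln <- lyLayerNorm(half, name = paste0(name, ".norm"))
  cache <- new.env(parent = emptyenv())
  list(kind = "patchExpand",
       params = list(proj = lin$params, norm = ln$params),
       forward = function(x, grid, training = FALSE) {
         cache$grid <- grid
         y <- lin$forward(x, training)
         a <- scatterPatches(y, grid, c(2L, 2L, 2L), half)
         ln$forward(matrix(a, prod(grid) * 8L, half), training)
       },
       backward = function(dy) {
         da <- ln$backward(dy)
         g2 <- cache$grid * 2L
         dm <- gatherPatches(array(da, c(g2, half)), c(2L, 2L, 2L))
         lin$backward(dm)
       })
}

lyFuse <- function(c, name = "fuse") {
  lin <- lyLinear(2L * c, c, bias = FALSE, name = paste0(name, ".reduce"))
  list(kind = "skipFuse", params = list(reduce = lin$params),
       forward = function(dec, enc, training = FALSE)
         lin$forward(cbind(dec, enc), training),
       backward = function(dy) {
         d <- lin$backward(dy)
         c2 <- ncol(d) %/% 2L
         list(dec = d[, seq_len(c2), drop = FALSE],
              enc = d[, c2 + seq_len(c2), drop = FALSE])
       })
}

lyFinalExpand <- function(C, patch, ncls, name = "head") {
  lin <- lyLinear(C, prod(patch) * ncls, name = paste0(name, ".proj"))
  cache <- new.env(parent = emptyenv())
  list(kind = "finalExpand", params = list(proj = lin$params),
       forward = function(x, grid, training = FALSE) {
         cache$grid <- grid
         y <- lin$forward(x, training)
         a <- scatterPatches(y, grid, patch, ncls)   # (D,H,W,ncls)
         aperm(a, c(4L, 1L, 2L, 3L))
       },
       backward = function(dscores) {
         da <- aperm(dscores, c(2L, 3L, 4L, 1L))
         dm <- gatherPatches(da, patch)
         lin$backward(dm)
       })
}

## ---- model -----------------------------------------------------------------

#' Instantiate the segmentation network
#'
#' Builds all trainable modules of the U-shaped transformer described by a
#' [ModelConfig-class]: patch embedding, three encoder stages of alternating
#' windowed/dilated-window blocks each followed by patch merging, the
#' bottleneck block(s), a mirrored decoder with patch expansion and skip
#' fusion, and the terminal expansion to per-voxel class scores.
#'
#' @param config a [ModelConfig-class].
#' @param init \code{"random"} (truncated-normal-style, sd 0.02) or
#'   \code{"zeros"} (useful for exact parameter counting).
#' @return A model object (list) with \code{$forward}, \code{$backward} and
#'   nested \code{$params}; see [forwardVolume()], [trainModel()].
#' @export
buildModel <- function(config, init = c("random", "zeros")) {
  init <- match.arg(init)
  cfg <- config
  chan <- stageChannels(cfg)
  nb <- stageBlocks(cfg)
  mkBlocks <- function(n, c, h)
    lapply(seq_len(n), function(i)
      buildVitBlock(c, h, cfg@window, cfg@dilation, cfg@mlpRatio,
                    cfg@dropout, cfg@qkvBias, cfg@dipeKernel))
  embed <- lyPatchEmbed(cfg@patchSize, cfg@inChannels, chan[1L])
  encoder <- lapply(1:3, function(s)
    list(blocks = mkBlocks(nb[s], chan[s], cfg@heads[s]),
         merge = lyPatchMerge(chan[s])))
  bottleneck <- mkBlocks(nb[4L], chan[4L], cfg@heads[4L])
  decoder <- lapply(3:1, function(s)
    list(expand = lyPatchExpand(chan[s + 1L]),
         fuse = lyFuse(chan[s]),
         blocks = mkBlocks(cfg@decoderDepths[4L - s], chan[s], cfg@heads[s])))
  final <- lyFinalExpand(chan[1L], cfg@patchSize, cfg@numClasses)
  model <- list(config = cfg, embed = embed, encoder = encoder,
                bottleneck = bottleneck, decoder = decoder, final = final)
  model$params <- list(embed = embed$params,
                       encoder = lapply(encoder, function(s)
                         list(blocks = lapply(s$blocks, `[[`, "params"),
                              merge = s$merge$params)),
                       bottleneck = lapply(bottleneck, `[[`, "params"),
                       decoder = lapply(decoder, function(s)
                         list(expand = s$expand$params, fuse = s$fuse$params,
                              blocks = lapply(s$blocks, `[[`, "params"))),
                       final = final$params)
  if (init == "zeros")
    for (p in collectParams(model$params)) p$value[] <- 0
  cache <- new.env(parent = emptyenv())
  model$forward <- function(volume, training = FALSE) {
    stopifnot(length(dim(volume)) == 4L)
    if (dim(volume)[1L] != cfg@inChannels)
      stop("volume has ", dim(volume)[1L], " channels; model expects ",
           cfg@inChannels)
    ext <- dim(volume)[2:4]
    if (any(ext %% (cfg@patchSize * 8L) != 0L))
      stop("input extents must be divisible by patchSize * 8 ",
           "(three merge levels); got ", paste(ext, collapse = "x"))
    grids <- lapply(0:3, function(s) ext %/% cfg@patchSize %/% (2L^s))
    cache$grids <- grids
    x <- embed$forward(volume, training)
    skips <- vector("list", 3L)
    for (s in 1:3) {
      for (b in encoder[[s]]$blocks) x <- b$forward(x, grids[[s]], training)
      skips[[s]] <- x
      x <- encoder[[s]]$merge$forward(x, grids[[s]], training)
    }
    for (b in bottleneck) x <- b$forward(x, grids[[4L]], training)
    for (i in 1:3) {
      s <- 4L - i
      x <- decoder[[i]]$expand$forward(x, grids[[s + 1L]], training)
      x <- decoder[[i]]$fuse$forward(x, skips[[s]], training)
      for (b in decoder[[i]]$blocks) x <- b$forward(x, grids[[s]], training)
    }
    final$forward(x, grids[[1L]], training)
  }
  model$backward <- function(dscores) {
    grids <- cache$grids
    dy <- final$backward(dscores)
    dskips <- vector("list", 3L)
    for (i in 3:1) {
      s <- 4L - i
      for (b in rev(decoder[[i]]$blocks)) dy <- b$backward(dy)
      df <- decoder[[i]]$fuse$backward(dy)
      dskips[[s]] <- df$enc
      dy <- decoder[[i]]$expand$backward(df$dec)
    }
    for (b in rev(bottleneck)) dy <- b$backward(dy)
    for (s in 3:1) {
      dy <- encoder[[s]]$merge$backward(dy)
      dy <- dy + dskips[[s]]
      for (b in rev(encoder[[s]]$blocks)) dy <- b$backward(dy)
    }
    embed$backward(dy)
  }
  class(model) <- "vitSegModel"
  model
}

#' Forward pass on a volume
#'
#' @param model a model from [buildModel()].
#' @param volume numeric array (C_in, D, H, W); extents divisible by
#'   \code{patchSize * 8}.
#' @param training logical; enables dropout.
#' @return per-class score array (numClasses, D, H, W).
#' @export
forwardVolume <- function(model, volume, training = FALSE)
  model$forward(volume, training)

#' Predict a label volume
#'
#' Runs the forward pass in inference mode, applies a per-voxel softmax and
#' decodes the arg-max class, remapping class indices back to the BraTS
#' label alphabet \{0, 1, 2, 4\} when the model has four classes.
#'
#' @inheritParams forwardVolume
#' @param labels label value for each class index; default BraTS.
#' @return integer label array (D, H, W).
#' @export
predictLabels <- function(model, volume, labels = c(0L, 1L, 2L, 4L)) {
  sc <- model$forward(volume, training = FALSE)
  cls <- apply(sc, c(2L, 3L, 4L), which.max)
  if (length(labels) != dim(sc)[1L])
    labels <- seq_len(dim(sc)[1L]) - 1L
  array(labels[cls], dim(sc)[2:4])
}

## ---- analytic accountant ---------------------------------------------------

#' Layer-by-layer architecture plan
#'
#' Walks the architecture for one configuration and input extent, emitting
#' one row per layer with its learnable-parameter count and forward
#' multiply-accumulate count (one MAC = one FLOP; normalization, softmax and
#' activations excluded).
#'
#' @param config a [ModelConfig-class].
#' @param inputExtent integer(3) input (D, H, W) in voxels.
#' @return data.frame with columns \code{layer}, \code{stage},
#'   \code{params}, \code{flops}.
#' @export
architecturePlan <- function(config, inputExtent = c(128L, 128L, 128L)) {
  cfg <- config
  ext <- as.integer(inputExtent)
  chan <- stageChannels(cfg)
  nb <- stageBlocks(cfg)
  g1 <- ext %/% cfg@patchSize
  grids <- lapply(0:3, function(s) g1 %/% (2L^s))
  rows <- list()
  add <- function(layer, stage, params, flops)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, stage = stage,
                                             params = params, flops = flops)
  wspan <- cfg@window
  dspan <- cfg@window * cfg@dilation
  addBlock <- function(stage, c, h, grid, tag) {
    om <- prod(grid)
    p <- pmin(cfg@window, grid)
    r <- pmax(1L, pmin(cfg@dilation, grid %/% p))
    N <- prod(p)
    hid <- round(c * cfg@mlpRatio)
    k3 <- cfg@dipeKernel^3
    add(paste0(tag, ".dipe"), stage, k3 * c + c, om * k3 * c)
    for (part in c("wmsa", "dwmsa")) {
      span <- if (part == "wmsa") wspan else dspan
      add(paste0(tag, ".", part, ".norm"), stage, 2 * c, 0)
      add(paste0(tag, ".", part), stage,
          3 * c^2 + (if (cfg@qkvBias) 3 * c else 0) + c^2 + c +
            prod(2L * span - 1L) * h,
          complexityEstimate(om, c, N, "windowed"))
      add(paste0(tag, ".", part, ".mlp.norm"), stage, 2 * c, 0)
      add(paste0(tag, ".", part, ".mlp"), stage,
          c * hid + hid + hid * c + c, 2 * om * c * hid)
    }
  }
  add("embed", 0L, prod(cfg@patchSize) * cfg@inChannels * chan[1L] +
        chan[1L] + 2L * chan[1L],
      prod(g1) * prod(cfg@patchSize) * cfg@inChannels * chan[1L])
  for (s in 1:3) {
    for (b in seq_len(nb[s]))
      addBlock(s, chan[s], cfg@heads[s], grids[[s]],
               sprintf("enc%d.block%d", s, b))
    c <- chan[s]
    add(sprintf("enc%d.merge", s), s, 16L * c + 16 * c^2,
        prod(grids[[s + 1L]]) * 16 * c^2)
  }
  for (b in seq_len(nb[4L]))
    addBlock(4L, chan[4L], cfg@heads[4L], grids[[4L]],
             sprintf("bottleneck.block%d", b))
  for (i in 1:3) {
    s <- 4L - i
    c <- chan[s + 1L]
    add(sprintf("dec%d.expand", s), s, 4 * c^2 + c,
        prod(grids[[s + 1L]]) * 4 * c^2)
    cd <- chan[s]
    add(sprintf("dec%d.fuse", s), s, 2 * cd^2,
        prod(grids[[s]]) * 2 * cd^2)
    for (b in seq_len(cfg@decoderDepths[i]))
      addBlock(s, cd, cfg@heads[s], grids[[s]],
               sprintf("dec%d.block%d", s, b))
  }
  add("final", 0L,
      chan[1L] * prod(cfg@patchSize) * cfg@numClasses +
        prod(cfg@patchSize) * cfg@numClasses,
      prod(g1) * chan[1L] * prod(cfg@patchSize) * cfg@numClasses)
  do.call(rbind, rows)
}

.flopConvention <- paste("1 FLOP = 1 multiply-accumulate;",
                         "normalization/softmax/activations excluded")

#' Count learnable parameters
#'
#' Instantiates the model and sums all learnable scalars. The count is
#' independent of the input extent: relative-position-bias tables are sized
#' from the configured window and dilation, not the runtime grid.
#'
#' @param config a [ModelConfig-class].
#' @return a [CostReport-class] (FLOPs NA).
#' @export
countParameters <- function(config) {
  n <- nParams(buildModel(config, init = "zeros")$params)
  new("CostReport", paramCount = n, flopCount = NA_real_,
      inputExtent = rep(NA_integer_, 3L), convention = .flopConvention)
}

#' Analytic FLOP count for one forward pass
#'
#' Sums multiply-accumulates over the embedding, every attention layer
#' (windowed complexity form), MLPs, patch merges/expands, skip fusions and
#' the terminal expansion at the given input extent.
#'
#' @param config a [ModelConfig-class].
#' @param inputExtent integer(3) input (D, H, W) in voxels.
#' @return a [CostReport-class] with parameters and FLOPs.
#' @examples
#' rep128 <- countFlops(modelConfig(), c(128, 128, 128))
#' flopsG(rep128); perSliceFlopsG(rep128)
#' @export
countFlops <- function(config, inputExtent = c(128L, 128L, 128L)) {
  plan <- architecturePlan(config, inputExtent)
  new("CostReport", paramCount = sum(plan$params),
      flopCount = sum(plan$flops),
      inputExtent = as.integer(inputExtent), convention = .flopConvention)
}

#' Describe a model configuration
#'
#' Parameter count, per-volume and per-slice FLOPs under the documented
#' multiply-accumulate convention, as a [CostReport-class] (and optionally
#' as JSON).
#'
#' @param config a [ModelConfig-class].
#' @param inputExtent integer(3) input (D, H, W).
#' @param json logical; return a JSON string instead of the object.
#' @return [CostReport-class] or JSON string.
#' @export
describeModel <- function(config, inputExtent = c(128L, 128L, 128L),
                          json = FALSE) {
  rep <- countFlops(config, inputExtent)
  if (!json) return(rep)
  jsonlite::toJSON(list(
    params = rep@paramCount, params_M = paramsM(rep),
    flops = rep@flopCount, flops_G = flopsG(rep),
    flops_per_slice_G = perSliceFlopsG(rep),
    input = as.integer(inputExtent), convention = rep@convention),
    auto_unbox = TRUE, digits = NA)
}
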