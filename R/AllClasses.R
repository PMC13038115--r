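#' Model configuration
#'
#' Architectural hyperparameters of the U-shaped 3D vision-transformer.
#' Channel width doubles and every spatial extent halves at each of the three
#' encoder merges, so stage channels are \code{embedDim * 2^(0:3)} and the
#' bottleneck width ("feature size") is \code{8 * embedDim}.
#'
#' The \code{depths} vector follows the published convention for this
#' architecture family: entries 1--3 give the number of alternating
#' (windowed + dilated-window) attention blocks in encoder stages 1--3, and
#' entry 4 gives the number of attention layers in the bottleneck (so the
#' default \code{c(2, 2, 6, 2)} means a bottleneck of one alternating block).
#' The decoder runs \code{decoderDepths} alternating blocks per stage,
#' one per resolution by default.
#'
#' All per-axis quantities (\code{window}, \code{dilation}, \code{patchSize})
#' are in (D, H, W) order. The default window \code{c(2, 8, 8)} keeps the
#' short window axis on depth, matching the asymmetric \code{c(2, 4, 4)}
#' patch size that leaves depth tokens densest.
#'
#' @slot embedDim integer, stage-1 channel width C.
#' @slot depths integer(4), see Details above.
#' @slot decoderDepths integer(3), alternating blocks per decoder stage
#'   (order: deepest first).
#' @slot window integer(3), patches per window along (D, H, W).
#' @slot dilation integer(3), dilation factors r along (D, H, W); clamped at
#'   run time so the dilated span fits the token grid.
#' @slot heads integer(4), attention heads per stage.
#' @slot patchSize integer(3), voxels per embedding patch along (D, H, W).
#' @slot inChannels integer, input image channels (3: T1ce, T2, FLAIR).
#' @slot numClasses integer, output classes (4: background, NCR/NET, ED, ET).
#' @slot mlpRatio numeric, MLP hidden expansion.
#' @slot dropout numeric, dropout probability on MLP and projection paths.
#' @slot qkvBias logical, bias on the query/key/value projection.
#' @slot dipeKernel integer, depthwise position-encoding kernel extent.
#'
#' @seealso [modelConfig()], [countParameters()], [buildModel()]
#' @export
setClass("ModelConfig", representation(
  embedDim = "integer", depths = "integer", decoderDepths = "integer",
  window = "integer", dilation = "integer", heads = "integer",
  patchSize = "integer", inChannels = "integer", numClasses = "integer",
  mlpRatio = "numeric", dropout = "numeric", qkvBias = "logical",
  dipeKernel = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  chan <- object@embedDim * 2L^(0:3)
  if (length(object@depths) != 4L || any(object@depths < 1L))
    msg <- c(msg, "depths must be four positive integers")
  if (object@depths[4L] %% 2L != 0L)
    msg <- c(msg, "the bottleneck entry of depths counts attention layers and must be even")
  if (length(object@heads) != 4L || any(chan %% object@heads != 0L))
    msg <- c(msg, "heads must divide the channel count of their stage")
  if (length(object@window) != 3L || any(object@window < 1L))
    msg <- c(msg, "window must be three positive integers")
  if (length(object@dilation) != 3L || any(object@dilation < 1L))
    msg <- c(msg, "dilation must be three positive integers")
  if (length(object@patchSize) != 3L || any(object@patchSize < 1L))
    msg <- c(msg, "patchSize must be three positive integers")
  if (object@dropout < 0 || object@dropout > 1)
    msg <- c(msg, "dropout must lie in [0, 1]")
  if (object@mlpRatio <= 0) msg <- c(msg, "mlpRatio must be positive")
  if (object@dipeKernel %% 2L != 1L)
    msg <- c(msg, "dipeKernel must be odd")
  if (length(msg)) msg else TRUE
})

#' Construct a model configuration
#'
#' Defaults reproduce the published full-size configuration: embedding width
#' 96 (feature size 768), depths \code{c(2, 2, 6, 2)}, window \code{c(2, 8, 8)}
#' in (D, H, W) (elsewhere often quoted as \code{[8, 8, 2]} in (H, W, D)),
#' heads \code{c(3, 6, 12, 24)}, patch size \code{c(2, 4, 4)}, three input
#' modalities, four output classes, dropout 0.2.
#'
#' @param embedDim stage-1 channel width.
#' @param depths blocks per stage, see [ModelConfig-class].
#' @param decoderDepths alternating blocks per decoder stage.
#' @param window window extent in patches, (D, H, W).
#' @param dilation dilation factors, (D, H, W).
#' @param heads heads per stage.
#' @param patchSize embedding patch extent in voxels, (D, H, W).
#' @param inChannels input channels.
#' @param numClasses output classes.
#' @param mlpRatio MLP expansion ratio.
#' @param dropout dropout probability.
#' @param qkvBias logical, bias on the qkv projection.
#' @param dipeKernel depthwise position-encoding kernel extent (odd).
#' @return A validated [ModelConfig-class] object.
#' @examples
#' cfg <- modelConfig()
#' stageChannels(cfg)
#' @export
modelConfig <- function(embedDim = 96L, depths = c(2L, 2L, 6L, 2L),
                        decoderDepths = c(1L, 1L, 1L),
                        window = c(2L, 8L, 8L), dilation = c(2L, 2L, 2L),
                        heads = c(3L, 6L, 12L, 24L), patchSize = c(2L, 4L, 4L),
                        inChannels = 3L, numClasses = 4L, mlpRatio = 4,
                        dropout = 0.2, qkvBias = TRUE, dipeKernel = 3L) {
  new("ModelConfig", embedDim = as.integer(embedDim),
      depths = as.integer(depths), decoderDepths = as.integer(decoderDepths),
      window = as.integer(window), dilation = as.integer(dilation),
      heads = as.integer(heads), patchSize = as.integer(patchSize),
      inChannels = as.integer(inChannels), numClasses = as.integer(numClasses),
      mlpRatio = as.numeric(mlpRatio), dropout = as.numeric(dropout),
      qkvBias = isTRUE(qkvBias), dipeKernel = as.integer(dipeKernel))
}

#' @describeIn modelConfig channel width of each of the four stages.
#' @param object,x a \code{ModelConfig}.
#' @export
stageChannels <- function(object) object@embedDim * 2L^(0:3)

#' Alternating-attention block counts per stage
#'
#' Translates the \code{depths} slot (see [ModelConfig-class]) into the
#' number of alternating windowed/dilated attention blocks run at each of
#' the four resolutions (three encoder stages + bottleneck).
#'
#' @param object a [ModelConfig-class].
#' @return integer(4) block counts.
#' @export
stageBlocks <- function(object)
  c(object@depths[1:3], object@depths[4L] %/% 2L)

#' @export
setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig (3D windowed/dilated-window vision transformer U-Net)\n")
  cat(sprintf("  embed dim C: %d   feature size 8C: %d\n",
              object@embedDim, 8L * object@embedDim))
  cat(sprintf("  depths: [%s]  (blocks per stage: [%s])\n",
              paste(object@depths, collapse = ","),
              paste(stageBlocks(object), collapse = ",")))
  cat(sprintf("  decoder blocks: [%s]\n",
              paste(object@decoderDepths, collapse = ",")))
  cat(sprintf("  window (D,H,W): [%s]   dilation: [%s]\n",
              paste(object@window, collapse = ","),
              paste(object@dilation, collapse = ",")))
  cat(sprintf("  heads: [%s]   patch (D,H,W): [%s]\n",
              paste(object@heads, collapse = ","),
              paste(object@patchSize, collapse = ",")))
  cat(sprintf("  in channels: %d   classes: %d   dropout: %.2f\n",
              object@inChannels, object@numClasses, object@dropout))
  invisible(object)
})

#' Cost report
#'
#' Parameter and floating-point-operation accounting for one model
#' configuration at one input extent. The FLOP convention is one
#' multiply-accumulate = one FLOP; normalization, softmax and elementwise
#' activations are excluded. Per-slice FLOPs divide the per-volume count by
#' the input depth.
#'
#' @slot paramCount numeric, learnable scalars (exact count).
#' @slot flopCount numeric, multiply-accumulates for one forward pass
#'   (NA when only parameters were counted).
#' @slot inputExtent integer(3) or NA, the (D, H, W) extent used.
#' @slot convention character, the counting convention.
#' @export
setClass("CostReport", representation(
  paramCount = "numeric", flopCount = "numeric", inputExtent = "integer",
  convention = "character"))

setValidity("CostReport", function(object) {
  if (length(object@paramCount) != 1L || object@paramCount < 0)
    return("paramCount must be one non-negative number")
  if (length(object@flopCount) != 1L)
    return("flopCount must be length one (possibly NA)")
  TRUE
})

#' @describeIn CostReport-class parameter count in millions.
#' @param object a \code{CostReport}.
#' @export
paramsM <- function(object) object@paramCount / 1e6

#' @describeIn CostReport-class per-volume FLOPs in giga-operations.
#' @export
flopsG <- function(object) object@flopCount / 1e9

#' @describeIn CostReport-class per-slice FLOPs in giga-operations
#'   (per-volume count divided by the input depth).
#' @export
perSliceFlopsG <- function(object) {
  if (anyNA(object@inputExtent)) return(NA_real_)
  object@flopCount / 1e9 / object@inputExtent[1L]
}

#' @export
setMethod("show", "CostReport", function(object) {
  cat("CostReport\n")
  cat(sprintf("  parameters: %.2f M (%s scalars)\n", paramsM(object),
              format(object@paramCount, big.mark = ",")))
  if (!is.na(object@flopCount)) {
    cat(sprintf("  FLOPs per volume: %.2f G at input [%s]\n", flopsG(object),
                paste(object@inputExtent, collapse = "x")))
    cat(sprintf("  FLOPs per slice:  %.4f G\n", perSliceFlopsG(object)))
  }
  cat(sprintf("  convention: %s\n", object@convention))
  invisible(object)
})
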