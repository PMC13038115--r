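# Patch embedding / merging / expanding, skip fusion, the end-to-end
# forward pass, and the parameter/FLOP accountant.

test_that("patch embedding produces the documented token grid", {
  # full-size geometry: (3,128,128,128) with patch (2,4,4) -> 64x32x32 tokens
  p <- c(2L, 4L, 4L)
  W <- matrix(0, prod(p) * 3L, 96L)
  x <- array(0, c(3L, 128L, 128L, 128L))
  y <- patchEmbed(x, p, W)
  expect_equal(dim(y), c(96L, 64L, 32L, 32L))
  expect_equal(prod(dim(y)[2:4]), 65536L)
  # per-voxel degenerate patching: token count equals voxel count
  x2 <- randomFeature(2L, c(4L, 4L, 4L))
  y2 <- patchEmbed(x2, c(1L, 1L, 1L), diag(2))
  expect_equal(dim(y2), dim(x2))
  # constant volume yields constant tokens with the projected value
  xc <- array(2, c(1L, 4L, 4L, 4L))
  Wc <- matrix(seq_len(8) / 10, 8, 1)
  yc <- patchEmbed(xc, c(2L, 2L, 2L), Wc)
  expect_true(all(abs(yc - 2 * sum(Wc)) < 1e-12))
  expect_error(patchEmbed(x2, c(3L, 1L, 1L), diag(2)), "divisible")
})

test_that("patch merging follows the channel/resolution schedule", {
  # schedule step (96, 64,32,32) -> (192, 32,16,16)
  x <- array(0, c(96L, 64L, 32L, 32L))
  W <- matrix(0, 8L * 96L, 192L)
  y <- patchMerge(x, W)
  expect_equal(dim(y), c(192L, 32L, 16L, 16L))
  # token count drops by exactly 8
  expect_equal(prod(dim(x)[2:4]) / prod(dim(y)[2:4]), 8)
  # selector matrix picks a chosen concatenated neighbor
  xs <- randomFeature(1L, c(4L, 4L, 4L), seed = 2L)
  child <- 3L                      # (d,h,w) offset (0,1,0) in child order
  sel <- matrix(0, 8L, 1L); sel[child, 1L] <- 1
  ys <- patchMerge(xs, sel)
  expect_equal(ys[1L, 1L, 1L, 1L], xs[1L, 1L, 2L, 1L])
  expect_equal(ys[1L, 2L, 1L, 2L], xs[1L, 3L, 2L, 3L])
  expect_error(patchMerge(randomFeature(1L, c(3L, 4L, 4L))), "even")
})

test_that("patch expansion doubles resolution, halves channels, localizes", {
  # schedule step (768, 16,8,8) -> (384, 32,16,16)
  x <- array(0, c(768L, 16L, 8L, 8L))
  W <- matrix(0, 768L, 4L * 768L)
  y <- patchExpand(x, W)
  expect_equal(dim(y), c(384L, 32L, 16L, 16L))
  # merge-then-expand restores the spatial shape (channels per schedule)
  xm <- randomFeature(4L, c(4L, 4L, 4L), seed = 3L)
  m <- patchMerge(xm, matrix(rnorm(32L * 8L), 32L, 8L))
  e <- patchExpand(m, matrix(rnorm(8L * 32L), 8L, 32L))
  expect_equal(dim(e)[2:4], dim(xm)[2:4])
  expect_equal(dim(e)[1L], dim(m)[1L] / 2L)
  # one-hot token spreads mass only into its own 2x2x2 child block
  xo <- array(0, c(2L, 4L, 4L, 4L))
  xo[1L, 2L, 3L, 4L] <- 1                      # token (parent) at (2,3,4)
  yo <- patchExpand(xo, matrix(1, 2L, 8L))
  nz <- which(yo != 0, arr.ind = TRUE)
  expect_true(all(nz[, 2L] %in% 3:4))          # children of parent d = 2
  expect_true(all(nz[, 3L] %in% 5:6))
  expect_true(all(nz[, 4L] %in% 7:8))
})

test_that("skip fusion restores decoder channels and honors null skips", {
  dec <- randomFeature(4L, c(2L, 2L, 2L), seed = 4L)
  enc <- randomFeature(4L, c(2L, 2L, 2L), seed = 5L)
  # averaging default on identical inputs: identity
  expect_equal(skipFuse(dec, dec), dec)
  # zero encoder features with a pass-through selector
  sel <- rbind(diag(4L), matrix(0, 4L, 4L))
  expect_equal(skipFuse(dec, 0 * enc, sel), dec)
  # channel count equals the decoder channel count at all three skip levels
  for (c in c(4L, 8L, 16L))
    expect_equal(dim(skipFuse(randomFeature(c, c(2L, 2L, 2L)),
                              randomFeature(c, c(2L, 2L, 2L))))[1L], c)
  expect_error(skipFuse(dec, randomFeature(4L, c(2L, 2L, 4L))), "shape")
})

test_that("end-to-end forward maps (3,D,H,W) to (numClasses,D,H,W)", {
  cfg <- microConfig(patchSize = c(2L, 4L, 4L), window = c(2L, 8L, 8L))
  set.seed(1)
  m <- buildModel(cfg)
  x <- randomFeature(3L, c(32L, 32L, 32L), seed = 6L)
  sc <- forwardVolume(m, x)
  expect_equal(dim(sc), c(4L, 32L, 32L, 32L))
  expect_identical(sc, forwardVolume(m, x))       # inference determinism
  # argmax decoding yields a valid BraTS label volume
  lab <- predictLabels(m, x)
  expect_true(all(lab %in% c(0L, 1L, 2L, 4L)))
  expect_equal(dim(lab), c(32L, 32L, 32L))
  expect_error(forwardVolume(m, randomFeature(3L, c(30L, 32L, 32L))),
               "divisible")
  expect_error(forwardVolume(m, randomFeature(2L, c(32L, 32L, 32L))),
               "channels")
})

test_that("encoder/decoder schedule mirrors exactly through merge levels", {
  # stage channels double while each extent halves; verified via the plan
  cfg <- modelConfig()
  for (ext in list(c(128L, 128L, 128L), c(64L, 64L, 64L))) {
    plan <- architecturePlan(cfg, ext)
    # qkv weight of stage s has 3 * (96 * 2^(s-1))^2 entries + bias
    for (s in 1:4) {
      c <- 96L * 2L^(s - 1L)
      nm <- if (s < 4) sprintf("enc%d.block1.wmsa", s)
            else "bottleneck.block1.wmsa"
      row <- plan[plan$layer == nm, ]
      expect_equal(row$params,
                   4 * c^2 + 4 * c + prod(2L * cfg@window - 1L) *
                     cfg@heads[s])
    }
  }
  # parameters are independent of the input extent
  expect_equal(sum(architecturePlan(cfg, c(64L, 64L, 64L))$params),
               sum(architecturePlan(cfg, c(128L, 128L, 128L))$params))
})

test_that("accountant equals an independent per-layer hand count on a
           micro configuration", {
  cfg <- microConfig(embedDim = 8L, heads = c(1L, 2L, 4L, 8L))
  ext <- c(16L, 16L, 16L)
  # independent layer walk (straight re-derivation, no shared code)
  C <- 8L; chan <- C * 2^(0:3); heads <- c(1L, 2L, 4L, 8L)
  p <- c(2L, 2L, 2L); win <- c(2L, 2L, 2L); r <- c(2L, 2L, 2L)
  blocks <- c(1L, 1L, 1L, 1L)                   # depths (1,1,1,2)
  dipePar <- function(c) 27 * c + c
  subPar <- function(c, h, span) 2 * c + 3 * c^2 + 3 * c + c^2 + c +
    prod(2 * span - 1) * h + 2 * c + 8 * c^2 + 5 * c
  blockPar <- function(c, h) dipePar(c) + subPar(c, h, win) +
    subPar(c, h, win * r)
  total <- prod(p) * 3 * C + C + 2 * C                       # embed + norm
  for (s in 1:3) total <- total + blocks[s] * blockPar(chan[s], heads[s]) +
    16 * chan[s] + 16 * chan[s]^2                            # merge
  total <- total + blockPar(chan[4], heads[4])               # bottleneck
  for (s in 3:1) total <- total +
    4 * chan[s + 1]^2 + chan[s + 1] +                        # expand
    2 * chan[s]^2 +                                          # fuse
    blockPar(chan[s], heads[s])                              # decoder block
  total <- total + C * prod(p) * 4 + prod(p) * 4             # final
  expect_equal(countParameters(cfg)@paramCount, total)
  # and the instantiated model carries exactly that many scalars
  m <- buildModel(cfg, init = "zeros")
  expect_equal(ViTSeg3D:::nParams(m$params), total)
  # FLOP plan sums the documented per-layer conventions
  plan <- architecturePlan(cfg, ext)
  expect_equal(countFlops(cfg, ext)@flopCount, sum(plan$flops))
})

test_that("accountant FLOPs scale linearly with the input volume", {
  cfg <- modelConfig()
  f64 <- countFlops(cfg, c(64L, 64L, 64L))@flopCount
  f128 <- countFlops(cfg, c(128L, 128L, 128L))@flopCount
  # ~linear in the voxel count (window clamping at coarse stages makes the
  # small-input count slightly sub-linear)
  expect_equal(f128 / f64, 8, tolerance = 0.02)
  # per-slice = per-volume / depth
  rep <- countFlops(cfg, c(128L, 128L, 128L))
  expect_equal(perSliceFlopsG(rep), flopsG(rep) / 128)
})

test_that("gradients reach every parameter that can influence the loss", {
  cfg <- microConfig(patchSize = c(2L, 4L, 4L), window = c(2L, 8L, 8L),
                     heads = c(1L, 2L, 4L, 8L))
  set.seed(2)
  m <- buildModel(cfg)
  case <- tinyCase(seed = 2L, extents = c(32L, 32L, 32L))
  x <- zscoreNormalize(stackModalities(case))
  logits <- m$forward(x, training = FALSE)
  Y <- smoothLabels(case$labels, epsilon = 0.1)
  lg <- ViTSeg3D:::hybridLossGrad(logits, Y)
  params <- ViTSeg3D:::collectParams(m$params)
  ViTSeg3D:::zeroGrads(params)
  m$backward(ViTSeg3D:::tokensToFeature(lg$grad, dim(logits)[2:4]))
  gn <- vapply(params, function(p) sum(abs(p$grad)), numeric(1))
  expect_true(all(gn > 0))
})

test_that("describeModel emits consistent JSON", {
  cfg <- microConfig()
  js <- jsonlite::fromJSON(describeModel(cfg, c(16L, 16L, 16L), json = TRUE))
  expect_equal(js$params, countParameters(cfg)@paramCount)
  expect_equal(js$flops_per_slice_G, js$flops_G / 16)
})
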