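# Window partitioning, dilated partitioning, windowed attention, the
# alternating block, position encoding, and the complexity formulas.

test_that("position encoding residual path and hand-convolved values", {
  x <- randomFeature(3L, c(4L, 4L, 4L))
  # zero kernel: identity
  expect_identical(dipeEncode(x, array(0, c(3, 3, 3))), x)
  # identity kernel (center weight 1): doubles the input
  k <- array(0, c(3, 3, 3)); k[2, 2, 2] <- 1
  expect_equal(dipeEncode(x, k), 2 * x)
  # single voxel, single channel, center weight c: v * (1 + c)
  v <- 1.7; cc <- -0.3
  x1 <- array(v, c(1, 1, 1, 1))
  k1 <- array(0, c(3, 3, 3)); k1[2, 2, 2] <- cc
  expect_equal(as.numeric(dipeEncode(x1, k1)), v * (1 + cc))
  # hand convolution on a 3-voxel line with an off-center weight
  xl <- array(c(1, 2, 3), c(1, 3, 1, 1))
  kl <- array(0, c(3, 3, 3)); kl[1, 2, 2] <- 1   # neighbor at d-1
  out <- dipeEncode(xl, kl)
  expect_equal(as.numeric(out), c(1, 2, 3) + c(0, 1, 2))
  expect_error(dipeEncode(x, array(0, c(3, 3, 3, 5))), "per input channel")
})

test_that("standard window partition enumerates and inverts exactly", {
  x <- randomFeature(2L, c(4L, 4L, 4L))
  pw <- partitionWindows(x, c(2L, 2L, 2L))
  expect_equal(dim(pw$blocks), c(8L, 2L, 8L))
  # patches (0,0,0) and (1,1,1) share the first window
  idx000 <- 1L                       # token (0,0,0)
  idx111 <- 1L + 1L + 4L + 16L      # token (1,1,1) on a 4x4x4 grid
  expect_true(all(c(idx000, idx111) %in% pw$index[, 1L]))
  # every patch in exactly one window
  expect_setequal(as.vector(pw$index), seq_len(64L))
  # degenerate partition: one window holding everything
  pw1 <- partitionWindows(x, c(4L, 4L, 4L))
  expect_equal(ncol(pw1$index), 1L)
  expect_equal(nrow(pw1$index), 64L)
  # bit-for-bit round trip
  expect_identical(reverseWindows(pw), x)
  expect_error(partitionWindows(x, c(3L, 2L, 2L), padding = "strict"),
               "not divisible")
})

test_that("dilated partition groups residue classes and inverts", {
  # 1D slice of extent 4 with p = 2, r = 2: windows {0,2} and {1,3}
  x <- array(1:4, c(1, 4, 1, 1))
  pd <- partitionDilatedWindows(x, c(2L, 1L, 1L), c(2L, 1L, 1L))
  expect_equal(ncol(pd$index), 2L)
  expect_equal(sort(pd$index[, 1L]), c(1L, 3L))
  expect_equal(sort(pd$index[, 2L]), c(2L, 4L))
  # r = 1 degenerates to the standard partition, token for token
  y <- randomFeature(3L, c(4L, 6L, 2L), seed = 3L)
  a <- partitionDilatedWindows(y, c(2L, 3L, 2L), c(1L, 1L, 1L))
  b <- partitionWindows(y, c(2L, 3L, 2L))
  expect_identical(a$blocks, b$blocks)
  expect_identical(a$index, b$index)
  # 6^3 map, 3^3 unit, r = 2: within-window patches are spaced 2 apart
  z <- randomFeature(1L, c(6L, 6L, 6L), seed = 4L)
  pz <- partitionDilatedWindows(z, c(3L, 3L, 3L), c(2L, 2L, 2L))
  expect_equal(nrow(pz$index), 27L)
  expect_equal(ncol(pz$index), 8L)
  co <- ViTSeg3D:::tokenCoords(pz$index[, 1L] - 1L, c(6L, 6L, 6L))
  expect_setequal(unique(co[, 1L]), c(0L, 2L, 4L))
  expect_setequal(unique(co[, 2L]), c(0L, 2L, 4L))
  expect_setequal(unique(co[, 3L]), c(0L, 2L, 4L))
  expect_identical(reverseWindows(pz), z)
})

test_that("dilated windows cover every patch exactly once (property)", {
  set.seed(10)
  for (i in 1:8) {
    grid <- sample(c(2L, 4L, 6L, 8L), 3L, replace = TRUE)
    p <- pmin(c(2L, 2L, 2L), grid)
    r <- pmax(1L, pmin(sample(1:2, 3L, replace = TRUE), grid %/% p))
    while (any(grid %% (p * r) != 0L)) r <- pmax(1L, r - 1L)
    x <- randomFeature(2L, grid, seed = i)
    pd <- partitionDilatedWindows(x, p, r)
    expect_setequal(as.vector(pd$index), seq_len(prod(grid)))
    expect_equal(nrow(pd$index), prod(p))
    expect_identical(reverseWindows(pd), x)
    ps <- partitionWindows(x, p)
    expect_identical(reverseWindows(ps), x)
  }
})

test_that("window attention matches closed forms and the softmax oracle", {
  C <- 4L
  set.seed(5)
  Wq <- matrix(rnorm(C * 3 * C, sd = 0.5), C, 3 * C)
  # one-patch window: softmax over a single key is 1 -> output = V
  x1 <- matrix(rnorm(C), 1, C)
  r1 <- windowAttention(x1, Wq, heads = 2L,
                        bias = matrix(5, 1, 1))   # bias irrelevant
  expect_equal(r1$output, x1 %*% Wq[, (2 * C + 1):(3 * C)])
  expect_equal(as.numeric(r1$weights), rep(1, 2))
  # identical keys, zero bias: uniform mean of the V rows
  xs <- matrix(rnorm(C), 1, C)[rep(1, 5), ]
  xs2 <- xs + 0
  rs <- windowAttention(xs2, Wq, heads = 1L)
  V <- xs2 %*% Wq[, (2 * C + 1):(3 * C)]
  expect_equal(rs$output, matrix(colMeans(V), 5, C, byrow = TRUE))
  expect_true(all(abs(apply(rs$weights, c(1, 3), sum) - 1) < 1e-6))
  # 2-patch window with scalar head reproduces a hand-computed softmax
  Wid <- cbind(diag(1), diag(1), diag(1))   # C = 1: Q = K = V = x
  x2 <- matrix(c(1, 0), 2, 1)
  r2 <- windowAttention(x2, Wid, heads = 1L)
  w11 <- exp(1) / (exp(1) + exp(0))         # d = 1 so scale = 1
  expect_equal(r2$weights[1, , 1], c(w11, 1 - w11))
  expect_equal(r2$output[1, 1], w11 * 1 + (1 - w11) * 0)
  expect_error(windowAttention(matrix(NA_real_, 2, 2), Wq[1:2, 1:6]),
               "non-finite")
  expect_error(windowAttention(matrix(1, 2, 4), Wq, heads = 3L),
               "not divisible")
})

test_that("windowed attention equals dense attention on whole-grid windows", {
  for (grid in list(c(2L, 2L, 2L), c(3L, 2L, 4L), c(6L, 6L, 6L))) {
    C <- 6L
    x <- randomFeature(C, grid, seed = sum(grid))
    set.seed(sum(grid))
    Wq <- matrix(rnorm(C * 3 * C, sd = 0.3), C, 3 * C)
    bq <- rnorm(3 * C, sd = 0.1)
    pw <- partitionWindows(x, grid)      # a single window = all patches
    tokens <- matrix(pw$blocks[, , 1L], nrow(pw$index), C)
    got <- windowAttention(tokens, Wq, bq, heads = 3L)
    want <- denseAttentionOracle(tokens, Wq, bq, heads = 3L)
    expect_equal(got$output, want, tolerance = 1e-10)
    expect_true(all(abs(apply(got$weights, c(1, 3), sum) - 1) < 1e-6))
  }
})

test_that("alternating block preserves shape, is deterministic, and zeroes
           to the identity", {
  blk <- buildVitBlock(4L, 2L, c(2L, 2L, 2L), c(2L, 2L, 2L), dropout = 0)
  x <- randomFeature(4L, c(4L, 4L, 4L), seed = 9L)
  y1 <- vitBlockForward(blk, x)
  expect_equal(dim(y1), dim(x))
  expect_identical(y1, vitBlockForward(blk, x))   # inference determinism
  # arbitrary valid sizes, including ones requiring padding
  for (grid in list(c(2L, 4L, 6L), c(3L, 5L, 2L), c(4L, 4L, 4L))) {
    xi <- randomFeature(4L, grid, seed = sum(grid))
    expect_equal(dim(vitBlockForward(blk, xi)), c(4L, grid))
  }
  # all weights zero: pure residual chain
  for (p in ViTSeg3D:::collectParams(blk$params)) p$value[] <- 0
  expect_equal(vitBlockForward(blk, x), x)
  expect_error(vitBlockForward(blk, randomFeature(3L, c(4L, 4L, 4L))),
               "channels")
})

test_that("complexity formulas behave and match an instrumented counter", {
  # N = omega: plain formula evaluation, no special-casing
  expect_equal(complexityEstimate(64, 8, 64, "windowed"),
               4 * 64 * 64 + 2 * 64 * 64 * 8)
  # linearity of the window-attention term in omega
  f1 <- complexityEstimate(100, 8, 8) - 4 * 100 * 64
  f2 <- complexityEstimate(200, 8, 8) - 4 * 200 * 64
  expect_equal(f2, 2 * f1)
  # windowed never exceeds dense for N < omega
  set.seed(2)
  for (i in 1:20) {
    om <- sample(8:512, 1); C <- sample(1:64, 1); N <- sample(seq_len(om), 1)
    expect_lte(complexityEstimate(om, C, N), complexityEstimate(om, C, NULL,
                                                               "dense"))
  }
  # instrumented multiply-accumulate counter on an executed attention pass
  # (omega = 64, C = 8, N = 8): tally the dimensions of every matrix product
  grid <- c(4L, 4L, 4L); C <- 8L
  x <- randomFeature(C, grid, seed = 1L)
  pw <- partitionWindows(x, c(2L, 2L, 2L))
  set.seed(1)
  Wq <- matrix(rnorm(C * 3 * C, sd = 0.3), C, 3 * C)
  macs <- 0
  for (w in seq_len(ncol(pw$index))) {
    tokens <- matrix(pw$blocks[, , w], nrow(pw$index), C)
    macs <- macs + nrow(tokens) * C * (3 * C)        # qkv projection
    N <- nrow(tokens); d <- C                        # single head
    macs <- macs + N * N * d                         # Q K^T
    macs <- macs + N * N * d                         # A V
    macs <- macs + N * C * C                         # output projection
    invisible(windowAttention(tokens, Wq, projWeight = diag(C)))
  }
  expect_equal(macs, complexityEstimate(prod(grid), C, 8, "windowed"))
})
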