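# Minimal reverse-mode neural-network core. Every layer is a closure-based
# module: a list with $forward()/$backward() plus $params, a named list of
# parameter environments (each holding $value and $grad). A module caches
# whatever its backward pass needs from the most recent forward call, so a
# training step is forward -> loss gradient -> backward in strict reverse
# order. Feature maps travel as token matrices (tokens x channels) with the
# token order being the column-major linearization of the (D, H, W) grid.

newParam <- function(value, name = "") {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- array(0, dim = dim(value) %||% length(value))
  e$name <- name
  class(e) <- "nnParam"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

initWeight <- function(nr, nc, sd = 0.02)
  matrix(rnorm(nr * nc, sd = sd), nr, nc)

# flatten all parameter environments below a module (or list of modules)
collectParams <- function(x) {
  out <- list()
  walk <- function(m) {
    if (inherits(m, "nnParam")) { out[[length(out) + 1L]] <<- m; return() }
    if (is.list(m)) for (el in m)
      if (is.list(el) || inherits(el, "nnParam")) walk(el)
  }
  walk(x)
  out
}

nParams <- function(x) sum(vapply(collectParams(x),
                                  function(p) length(p$value), numeric(1)))

zeroGrads <- function(x) {
  for (p in collectParams(x)) p$grad[] <- 0
  invisible(NULL)
}

## ---- elementary layers -----------------------------------------------------

lyLinear <- function(din, dout, bias = TRUE, name = "linear") {
  W <- newParam(initWeight(din, dout), paste0(name, ".W"))
  b <- if (bias) newParam(numeric(dout), paste0(name, ".b"))
  cache <- new.env(parent = emptyenv())
  list(
    kind = "linear",
    params = if (bias) list(W = W, b = b) else list(W = W),
    forward = function(x, training = FALSE) {
      cache$x <- x
      y <- x %*% W$value
      if (!is.null(b)) y <- sweep(y, 2L, b$value, "+")
      y
    },
    backward = function(dy) {
      W$grad <- W$grad + crossprod(cache$x, dy)
      if (!is.null(b)) b$grad <- b$grad + colSums(dy)
      dy %*% t(W$value)
    })
}

lyLayerNorm <- function(dim, eps = 1e-5, name = "ln") {
  g <- newParam(rep(1, dim), paste0(name, ".g"))
  b <- newParam(numeric(dim), paste0(name, ".b"))
  cache <- new.env(parent = emptyenv())
  list(
    kind = "layernorm",
    params = list(g = g, b = b),
    forward = function(x, training = FALSE) {
      mu <- rowMeans(x)
      xc <- x - mu
      inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
      xhat <- xc * inv
      cache$xhat <- xhat; cache$inv <- inv
      sweep(sweep(xhat, 2L, g$value, "*"), 2L, b$value, "+")
    },
    backward = function(dy) {
      xhat <- cache$xhat; inv <- cache$inv
      g$grad <- g$grad + colSums(dy * xhat)
      b$grad <- b$grad + colSums(dy)
      dxh <- sweep(dy, 2L, g$value, "*")
      inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    })
}

geluF <- function(x) x * pnorm(x)
geluB <- function(x, dy) dy * (pnorm(x) + x * dnorm(x))

lyDropout <- function(p) {
  cache <- new.env(parent = emptyenv())
  list(
    kind = "dropout", params = list(),
    forward = function(x, training = FALSE) {
      if (!training || p <= 0) { cache$mask <- NULL; return(x) }
      m <- (runif(length(x)) >= p) / (1 - p)
      dim(m) <- dim(x)
      cache$mask <- m
      x * m
    },
    backward = function(dy) if (is.null(cache$mask)) dy else dy * cache$mask)
}

lyMLP <- function(dim, ratio = 4, dropout = 0, name = "mlp") {
  hidden <- as.integer(round(dim * ratio))
  fc1 <- lyLinear(dim, hidden, name = paste0(name, ".fc1"))
  fc2 <- lyLinear(hidden, dim, name = paste0(name, ".fc2"))
  dr1 <- lyDropout(dropout); dr2 <- lyDropout(dropout)
  cache <- new.env(parent = emptyenv())
  list(
    kind = "mlp",
    params = list(fc1 = fc1$params, fc2 = fc2$params),
    forward = function(x, training = FALSE) {
      h <- fc1$forward(x, training)
      cache$h <- h
      dr2$forward(fc2$forward(dr1$forward(geluF(h), training), training),
                  training)
    },
    backward = function(dy) {
      dh <- dr1$backward(fc2$backward(dr2$backward(dy)))
      fc1$backward(geluB(cache$h, dh))
    })
}

## ---- spatial helpers -------------------------------------------------------

# shift a (D,H,W,C) array by integer offsets s (neighbor at +s), zero padding
shiftArray3 <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (s[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - s[ax]) + s[ax]
      dst[[ax]] <- seq_len(d[ax] - s[ax])
    } else {
      src[[ax]] <- seq_len(d[ax] + s[ax])
      dst[[ax]] <- seq_len(d[ax] + s[ax]) - s[ax]
    }
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]], ] <- a[src[[1]], src[[2]], src[[3]], ,
                                           drop = FALSE]
  out
}

# depthwise 3D convolution of (D,H,W,C) with per-channel kernel (k,k,k,C)
depthwiseConv3 <- function(a, kernel) {
  k <- dim(kernel)[1L]
  half <- (k - 1L) %/% 2L
  d <- dim(a)
  out <- array(0, d)
  for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
    kv <- kernel[i, j, l, ]
    if (all(kv == 0)) next
    sh <- shiftArray3(a, c(i - 1L - half, j - 1L - half, l - 1L - half))
    out <- out + sweep(sh, 4L, kv, "*")
  }
  out
}

## ---- dynamic position encoding (depthwise conv + residual) -----------------

lyDIPE <- function(channels, kernel = 3L, name = "dipe") {
  k <- newParam(array(rnorm(kernel^3 * channels, sd = 0.02),
                      c(kernel, kernel, kernel, channels)),
                paste0(name, ".kernel"))
  b <- newParam(numeric(channels), paste0(name, ".bias"))
  cache <- new.env(parent = emptyenv())
  list(
    kind = "dipe",
    params = list(kernel = k, bias = b),
    forward = function(x, grid, training = FALSE) {
      a <- array(x, c(grid, ncol(x)))
      cache$a <- a; cache$grid <- grid
      conv <- depthwiseConv3(a, k$value)
      conv <- sweep(conv, 4L, b$value, "+")
      x + matrix(conv, nrow(x), ncol(x))
    },
    backward = function(dy) {
      grid <- cache$grid
      dya <- array(dy, c(grid, ncol(dy)))
      ksz <- dim(k$value)[1L]
      half <- (ksz - 1L) %/% 2L
      dk <- array(0, dim(k$value))
      dconv <- array(0, dim(dya))
      for (i in seq_len(ksz)) for (j in seq_len(ksz)) for (l in seq_len(ksz)) {
        off <- c(i - 1L - half, j - 1L - half, l - 1L - half)
        sh <- shiftArray3(cache$a, off)
        dk[i, j, l, ] <- apply(sh * dya, 4L, sum)
        kv <- k$value[i, j, l, ]
        if (!all(kv == 0))
          dconv <- dconv + sweep(shiftArray3(dya, -off), 4L, kv, "*")
      }
      k$grad <- k$grad + dk
      b$grad <- b$grad + colSums(dy)
      dy + matrix(dconv, nrow(dy), ncol(dy))
    })
}

## ---- softmax ---------------------------------------------------------------

softmaxRows <- function(s) {
  m <- apply(s, 1L, max)
  finite <- is.finite(m)
  e <- exp(s - ifelse(finite, m, 0))
  e[!is.finite(s)] <- 0
  z <- rowSums(e)
  out <- e / ifelse(z > 0, z, 1)
  out
}
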