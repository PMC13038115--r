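# Feature maps are numeric arrays in (C, D, H, W) order (a leading batch axis
# is handled by the callers that support it). Internally the network works on
# token matrices (tokens x channels) whose row order is the column-major
# linearization of the (D, H, W) grid (depth fastest).

featureToTokens <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  tok <- matrix(aperm(x, c(2L, 3L, 4L, 1L)), prod(d[2:4]), d[1L])
  attr(tok, "grid") <- d[2:4]
  tok
}

tokensToFeature <- function(tok, grid) {
  a <- array(tok, c(grid, ncol(tok)))
  aperm(a, c(4L, 1L, 2L, 3L))
}

# coordinates (0-based) of 0-based token indices on a (D,H,W) grid
tokenCoords <- function(t0, grid) {
  cbind(d = t0 %% grid[1L],
        h = (t0 %/% grid[1L]) %% grid[2L],
        w = t0 %/% (grid[1L] * grid[2L]))
}

checkFinite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(TRUE)
}

# symmetric padding bookkeeping: index of each original token inside the
# zero-padded grid
padTokenMap <- function(grid, padded) {
  lo <- (padded - grid) %/% 2L
  t0 <- 0:(prod(grid) - 1L)
  co <- tokenCoords(t0, grid)
  as.integer((co[, 1L] + lo[1L]) +
             padded[1L] * ((co[, 2L] + lo[2L]) +
                           padded[2L] * (co[, 3L] + lo[3L]))) + 1L
}
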