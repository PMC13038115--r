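# Voxel-wise focal loss, dice loss, their weighted hybrid, label smoothing,
# and the analytic logit gradient used by the optimizer.

asProbMatrix <- function(x, nclasses = NULL) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 4L)        # (classes, D, H, W)
    return(matrix(aperm(x, c(2L, 3L, 4L, 1L)), prod(d[2:4]), d[1L]))
  stop("expected a voxels x classes matrix or a (classes, D, H, W) array")
}

checkProb <- function(P, tol = 1e-6) {
  if (any(P < -tol | P > 1 + tol))
    stop("probabilities must lie in [0, 1]")
  s <- rowSums(P)
  if (any(abs(s - 1) > 1e-4))
    stop("per-voxel class probabilities must sum to 1")
  invisible(TRUE)
}

#' Per-voxel class probabilities from logits
#'
#' Numerically stable softmax (max-subtraction) over the class axis.
#'
#' @param logits voxels x classes matrix or (classes, D, H, W) array.
#' @return matrix (voxels x classes) of probabilities; rows sum to 1.
#' @export
softmaxProbabilities <- function(logits) softmaxRows(asProbMatrix(logits))

#' One-hot encode and optionally smooth a label volume
#'
#' @param labels integer array or vector of class values.
#' @param classes the class alphabet, in channel order (default BraTS
#'   \code{c(0, 1, 2, 4)}).
#' @param epsilon label-smoothing factor: targets become
#'   \code{(1 - epsilon) * onehot + epsilon / J}.
#' @return matrix (voxels x classes); rows sum to 1.
#' @export
smoothLabels <- function(labels, classes = c(0L, 1L, 2L, 4L), epsilon = 0) {
  v <- as.integer(labels)
  if (!all(v %in% classes))
    stop("labels contain values outside the class alphabet {",
         paste(classes, collapse = ","), "}")
  J <- length(classes)
  Y <- matrix(0, length(v), J)
  Y[cbind(seq_along(v), match(v, classes))] <- 1
  if (epsilon > 0) Y <- Y * (1 - epsilon) + epsilon / J
  Y
}

#' Voxel-wise focal loss
#'
#' Cross-entropy modulated by \code{(1 - P)^gamma} to down-weight easy
#' voxels, with a class-balance factor \code{alpha}:
#' \deqn{-\frac{1}{I}\sum_i\sum_j \alpha (1 - P_{ij})^\gamma Y_{ij}
#'   \log P_{ij}.}
#' With \code{gamma = 0}, \code{alpha = 1} this is the mean cross-entropy.
#'
#' @param P predicted probabilities, voxels x classes matrix (or
#'   (classes, D, H, W) array); rows sum to 1.
#' @param Y target probabilities of the same shape (one-hot, possibly
#'   smoothed).
#' @param alpha balance factor (default 0.25).
#' @param gamma focusing exponent (default 2, >= 0).
#' @param eps probability floor inside the logarithm.
#' @return scalar loss, >= 0.
#' @export
focalLoss <- function(P, Y, alpha = 0.25, gamma = 2, eps = 1e-12) {
  P <- asProbMatrix(P); Y <- asProbMatrix(Y)
  if (!identical(dim(P), dim(Y))) stop("P and Y shapes differ")
  checkProb(P)
  stopifnot(gamma >= 0, alpha >= 0)
  Pc <- pmax(P, eps)
  -mean(rowSums(alpha * (1 - Pc)^gamma * Y * log(Pc)))
}

#' Voxel-wise dice loss
#'
#' One minus the soft dice overlap
#' \eqn{2\sum PY / (\sum P^2 + \sum Y^2)}. By default the overlap is
#' computed per class and averaged over classes (background included);
#' \code{classwise = FALSE} instead evaluates one global ratio with the
#' sums running over all voxels and classes.
#'
#' @inheritParams focalLoss
#' @param classwise average per-class dice terms (default) or use a single
#'   global ratio.
#' @param excludeBackground drop class 1 (the first column) from the
#'   class-wise average.
#' @param smooth additive smoothing guarding empty classes.
#' @return scalar in [0, 1] for binary targets.
#' @export
diceLoss <- function(P, Y, classwise = TRUE, excludeBackground = FALSE,
                     smooth = 1e-5) {
  P <- asProbMatrix(P); Y <- asProbMatrix(Y)
  if (!identical(dim(P), dim(Y))) stop("P and Y shapes differ")
  if (classwise) {
    cols <- if (excludeBackground) 2:ncol(P) else seq_len(ncol(P))
    d <- vapply(cols, function(j) {
      S <- sum(P[, j] * Y[, j])
      (2 * S + smooth) / (sum(P[, j]^2) + sum(Y[, j]^2) + smooth)
    }, numeric(1))
    1 - mean(d)
  } else {
    1 - (2 * sum(P * Y) + smooth) / (sum(P^2) + sum(Y^2) + smooth)
  }
}

#' Hybrid dice + focal loss
#'
#' \code{lambdaDice * diceLoss + lambdaFocal * focalLoss}; the default
#' weights (1, 1) simply sum the two components.
#'
#' @inheritParams focalLoss
#' @param lambdaDice,lambdaFocal non-negative component weights, not both 0.
#' @param alpha,gamma focal-loss parameters.
#' @param classwise,excludeBackground passed to [diceLoss()].
#' @return scalar loss.
#' @export
hybridLoss <- function(P, Y, lambdaDice = 1, lambdaFocal = 1, alpha = 0.25,
                       gamma = 2, classwise = TRUE,
                       excludeBackground = FALSE) {
  stopifnot(lambdaDice >= 0, lambdaFocal >= 0)
  if (lambdaDice == 0 && lambdaFocal == 0)
    stop("at least one loss weight must be positive")
  d <- if (lambdaDice > 0)
    diceLoss(P, Y, classwise, excludeBackground) else 0
  f <- if (lambdaFocal > 0) focalLoss(P, Y, alpha, gamma) else 0
  lambdaDice * d + lambdaFocal * f
}

# Analytic gradient of the hybrid loss with respect to the logits.
# Returns list(loss, grad) with grad shaped like the logit matrix.
hybridLossGrad <- function(logits, Y, lambdaDice = 1, lambdaFocal = 1,
                           alpha = 0.25, gamma = 2, classwise = TRUE,
                           excludeBackground = FALSE, smooth = 1e-5,
                           eps = 1e-12) {
  Z <- asProbMatrix(logits); Y <- asProbMatrix(Y)
  P <- softmaxRows(Z)
  I <- nrow(P); J <- ncol(P)
  dP <- matrix(0, I, J)
  loss <- 0
  if (lambdaFocal > 0) {
    Pc <- pmax(P, eps)
    loss <- loss + lambdaFocal *
      (-mean(rowSums(alpha * (1 - Pc)^gamma * Y * log(Pc))))
    gfl <- -(alpha * Y / I) *
      ((1 - Pc)^gamma / Pc -
         (if (gamma > 0) gamma * (1 - Pc)^(gamma - 1) * log(Pc) else 0))
    gfl[P < eps & Y == 0] <- 0
    dP <- dP + lambdaFocal * gfl
  }
  if (lambdaDice > 0) {
    if (classwise) {
      cols <- if (excludeBackground) 2:J else seq_len(J)
      dsum <- 0
      for (j in cols) {
        S <- sum(P[, j] * Y[, j])
        den <- sum(P[, j]^2) + sum(Y[, j]^2) + smooth
        dsum <- dsum + (2 * S + smooth) / den
        dP[, j] <- dP[, j] - lambdaDice / length(cols) *
          (2 * Y[, j] * den - (2 * S + smooth) * 2 * P[, j]) / den^2
      }
      loss <- loss + lambdaDice * (1 - dsum / length(cols))
    } else {
      S <- sum(P * Y)
      den <- sum(P^2) + sum(Y^2) + smooth
      loss <- loss + lambdaDice * (1 - (2 * S + smooth) / den)
      dP <- dP - lambdaDice *
        (2 * Y * den - (2 * S + smooth) * 2 * P) / den^2
    }
  }
  # chain through the softmax: dZ_ij = P_ij (dP_ij - sum_k dP_ik P_ik)
  dZ <- P * (dP - rowSums(dP * P))
  list(loss = loss, grad = dZ)
}
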