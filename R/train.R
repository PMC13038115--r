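# Training loop: Adam with decoupled-from-nothing classic L2 (added to the
# gradient), global-norm gradient clipping, reduce-on-plateau learning-rate
# scheduling driven by validation DSC, DSC-based early stopping, and a
# per-epoch run log.

#' Training configuration
#'
#' Defaults follow the standard recipe for this architecture: Adam, initial
#' learning rate 1e-3, weight decay 1e-5, 140 epochs at batch size 2,
#' plateau factor 0.5 with patience 5 on validation DSC, label smoothing
#' 0.1, gradient clipping at global norm 1.
#'
#' @param epochs training epochs.
#' @param batchSize cases per optimizer step.
#' @param lr initial learning rate.
#' @param weightDecay L2 penalty added to gradients.
#' @param plateauFactor learning-rate multiplier on plateau.
#' @param plateauPatience epochs without validation-DSC improvement before
#'   the rate is reduced.
#' @param gradClipNorm global gradient-norm bound.
#' @param earlyStopPatience epochs without improvement before stopping.
#' @param labelSmoothing smoothing factor for the targets.
#' @param lambdaDice,lambdaFocal hybrid-loss weights.
#' @param alpha,gamma focal-loss parameters.
#' @param seed RNG seed for shuffling, dropout and initialization.
#' @return a \code{TrainConfig} list.
#' @export
trainConfig <- function(epochs = 140L, batchSize = 2L, lr = 1e-3,
                        weightDecay = 1e-5, plateauFactor = 0.5,
                        plateauPatience = 5L, gradClipNorm = 1,
                        earlyStopPatience = 15L, labelSmoothing = 0.1,
                        lambdaDice = 1, lambdaFocal = 1, alpha = 0.25,
                        gamma = 2, seed = 1L) {
  stopifnot(epochs >= 0L, batchSize >= 1L, lr > 0, weightDecay >= 0,
            plateauFactor > 0, plateauFactor <= 1, plateauPatience >= 1L,
            earlyStopPatience >= 1L, labelSmoothing >= 0,
            labelSmoothing < 1)
  structure(as.list(environment()), class = "TrainConfig")
}

## ---- optimizer pieces ------------------------------------------------------

adamState <- function(params)
  lapply(params, function(p)
    list(m = array(0, dim(p$value) %||% length(p$value)),
         v = array(0, dim(p$value) %||% length(p$value))))

adamStep <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (weightDecay > 0) g <- g + weightDecay * p$value
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    state[[i]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Clip the global gradient norm
#'
#' Scales all gradients uniformly so their joint Euclidean norm does not
#' exceed \code{maxNorm}.
#'
#' @param params list of parameter environments (internal layout).
#' @param maxNorm the bound.
#' @return the pre-clip global norm, invisibly useful for logging.
#' @export
clipGradNorm <- function(params, maxNorm = 1) {
  total <- sqrt(sum(vapply(params, function(p) sum(p$grad^2), numeric(1))))
  if (is.finite(total) && total > maxNorm && total > 0) {
    sc <- maxNorm / total
    for (p in params) p$grad <- p$grad * sc
  }
  total
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Tracks a monitored metric (maximized by default, e.g. validation DSC)
#' and multiplies the learning rate by \code{factor} after \code{patience}
#' consecutive epochs without improvement.
#'
#' @param lr initial learning rate.
#' @param factor multiplier applied on plateau (0 < factor <= 1).
#' @param patience epochs of stagnation tolerated before a reduction.
#' @param mode \code{"max"} or \code{"min"}.
#' @return closure list with \code{$step(metric)} returning the current
#'   learning rate and \code{$lr()}.
#' @export
plateauScheduler <- function(lr, factor = 0.5, patience = 5L,
                             mode = c("max", "min")) {
  mode <- match.arg(mode)
  best <- if (mode == "max") -Inf else Inf
  bad <- 0L
  cur <- lr
  list(
    step = function(metric) {
      improved <- if (mode == "max") metric > best else metric < best
      if (improved) { best <<- metric; bad <<- 0L }
      else {
        bad <<- bad + 1L
        if (bad >= patience) { cur <<- cur * factor; bad <<- 0L }
      }
      cur
    },
    lr = function() cur)
}

## ---- data plumbing ---------------------------------------------------------

prepareCase <- function(case, normalize = TRUE) {
  x <- stackModalities(case)
  if (normalize) x <- zscoreNormalize(x)
  list(x = x, y = case$labels)
}

foregroundDice <- function(model, prepared) {
  scores <- vapply(prepared, function(pc) {
    pred <- predictLabels(model, pc$x)
    pm <- regionMasks(pred); tm <- regionMasks(pc$y)
    c(dsc(pm$WT, tm$WT), dsc(pm$TC, tm$TC), dsc(pm$ET, tm$ET))
  }, numeric(3))
  rowMeans(matrix(scores, nrow = 3L))
}

snapshotParams <- function(params) lapply(params, function(p) p$value)
restoreParams <- function(params, snap)
  for (i in seq_along(params)) params[[i]]$value <- snap[[i]]

#' Train a model on a set of cases
#'
#' Runs the full optimization recipe: shuffled mini-batches, hybrid
#' dice+focal loss on smoothed targets, Adam with L2 weight decay, global
#' gradient-norm clipping, reduce-on-plateau learning rate and DSC-based
#' early stopping on the validation set. The best-validation-DSC parameter
#' snapshot is restored at the end.
#'
#' @param model a model from [buildModel()].
#' @param cases list of training \code{CaseRecord}s.
#' @param valCases validation cases (defaults to \code{cases}).
#' @param config a [trainConfig()].
#' @param normalize z-score the inputs.
#' @param verbose print per-epoch progress.
#' @return list with \code{model}, \code{log} (per-epoch data.frame:
#'   epoch, trainLoss, valDSC_WT/TC/ET, valDSC, lr, gradNorm, seconds),
#'   \code{bestEpoch} and \code{stoppedEarly}.
#' @export
trainModel <- function(model, cases, valCases = NULL, config = trainConfig(),
                       normalize = TRUE, verbose = FALSE) {
  if (length(cases) == 0L) stop("empty training set")
  if (is.null(valCases)) valCases <- cases
  classes <- c(0L, 1L, 2L, 4L)[seq_len(model$config@numClasses)]
  if (model$config@numClasses == 4L) classes <- c(0L, 1L, 2L, 4L)
  prepTr <- lapply(cases, prepareCase, normalize = normalize)
  prepVal <- lapply(valCases, prepareCase, normalize = normalize)
  params <- collectParams(model$params)
  state <- adamState(params)
  sched <- plateauScheduler(config$lr, config$plateauFactor,
                            config$plateauPatience, "max")
  bestVal <- -Inf; bestSnap <- snapshotParams(params); bestEpoch <- 0L
  bad <- 0L; stepT <- 0L
  log <- list()
  stoppedEarly <- FALSE
  if (!is.null(config$seed)) set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(length(prepTr))
    lr <- sched$lr()
    losses <- c(); norms <- c()
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + config$batchSize - 1L, length(ord))]
      zeroGrads(params)
      bl <- 0
      for (b in batch) {
        pc <- prepTr[[b]]
        logits <- model$forward(pc$x, training = TRUE)
        Y <- smoothLabels(pc$y, classes, config$labelSmoothing)
        lg <- hybridLossGrad(logits, Y, config$lambdaDice,
                             config$lambdaFocal, config$alpha, config$gamma)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch)
        bl <- bl + lg$loss
        model$backward(tokensToFeature(lg$grad / length(batch),
                                       dim(logits)[2:4]))
      }
      norms <- c(norms, clipGradNorm(params, config$gradClipNorm))
      stepT <- stepT + 1L
      state <- adamStep(params, state, lr, stepT,
                        weightDecay = config$weightDecay)
      losses <- c(losses, bl / length(batch))
      i <- i + config$batchSize
    }
    vd <- foregroundDice(model, prepVal)
    valDSC <- mean(vd)
    lrNext <- sched$step(valDSC)
    if (valDSC > bestVal) {
      bestVal <- valDSC; bestSnap <- snapshotParams(params)
      bestEpoch <- epoch; bad <- 0L
    } else bad <- bad + 1L
    log[[epoch]] <- data.frame(
      epoch = epoch, trainLoss = mean(losses),
      valDSC_WT = vd[1L], valDSC_TC = vd[2L], valDSC_ET = vd[3L],
      valDSC = valDSC, lr = lr,
      gradNorm = mean(pmin(norms, config$gradClipNorm)),
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  valDSC %.4f  lr %.2e",
                      epoch, mean(losses), valDSC, lr))
    if (bad >= config$earlyStopPatience) { stoppedEarly <- TRUE; break }
    invisible(lrNext)
  }
  restoreParams(params, bestSnap)
  list(model = model, log = do.call(rbind, log), bestEpoch = bestEpoch,
       stoppedEarly = stoppedEarly)
}

#' Evaluate a model on labelled cases
#'
#' Predicts every case and reports the seven metrics per region and case,
#' plus the across-case mean per region and the region average ("Avg.").
#'
#' @param model a trained model.
#' @param cases list of \code{CaseRecord}s.
#' @param normalize z-score the inputs as during training.
#' @param tau NSD tolerance (mm).
#' @return list with \code{perCase} and \code{summary} data.frames.
#' @export
evaluateModel <- function(model, cases, normalize = TRUE, tau = 1) {
  per <- lapply(cases, function(cs) {
    pc <- prepareCase(cs, normalize)
    rep <- evaluateSegmentation(predictLabels(model, pc$x), pc$y,
                                spacing = cs$spacing, tau = tau)
    cbind(case = cs$id, rep)
  })
  perCase <- do.call(rbind, per)
  agg <- stats::aggregate(perCase[, !(names(perCase) %in%
                                        c("case", "region"))],
                          by = list(region = perCase$region), FUN = mean)
  summary <- rbind(agg, regionAverage(agg))
  list(perCase = perCase, summary = summary)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the configuration and all parameter values.
#'
#' @param model a model from [buildModel()].
#' @param path file path.
#' @return \code{loadCheckpoint} returns a rebuilt model.
#' @export
saveCheckpoint <- function(model, path) {
  params <- collectParams(model$params)
  saveRDS(list(config = model$config,
               values = lapply(params, function(p) p$value)), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- buildModel(ck$config, init = "zeros")
  params <- collectParams(model$params)
  stopifnot(length(params) == length(ck$values))
  for (i in seq_along(params)) params[[i]]$value <- ck$values[[i]]
  model
}
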