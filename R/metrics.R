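# Evaluation metrics on binary region masks: overlap (DSC), confusion-count
# rates (sensitivity / specificity / precision), and surface metrics (HD95,
# NSD, MASD) built on an exact Euclidean distance transform. Includes the
# standard BraTS region grouping WT / TC / ET.

#' Group a BraTS label volume into evaluation region masks
#'
#' Enhancing tumor ET = class 4; tumor core TC = classes \{1, 4\}; whole
#' tumor WT = classes \{1, 2, 4\}. The regions nest: ET is contained in TC
#' is contained in WT.
#'
#' @param labels integer array with values in \{0, 1, 2, 4\}.
#' @return named list of logical arrays \code{WT}, \code{TC}, \code{ET}.
#' @export
regionMasks <- function(labels) {
  v <- as.integer(labels)
  bad <- setdiff(unique(v), c(0L, 1L, 2L, 4L))
  if (length(bad))
    stop("unknown label values: ", paste(bad, collapse = ", "))
  shape <- dim(labels) %||% length(labels)
  mk <- function(classes) array(v %in% classes, shape)
  list(WT = mk(c(1L, 2L, 4L)), TC = mk(c(1L, 4L)), ET = mk(4L))
}

#' Dice similarity coefficient
#'
#' \eqn{2|P \cap Y| / (|P| + |Y|)}; equivalently the F1 score
#' \eqn{2TP / (2TP + FP + FN)} over voxels. Two empty masks score 1.
#'
#' @param P,Y logical arrays of equal shape (prediction, reference).
#' @return scalar in [0, 1].
#' @export
dsc <- function(P, Y) {
  stopifnot(identical(dim(P), dim(Y)))
  sp <- sum(P); sy <- sum(Y)
  if (sp + sy == 0) return(1)
  2 * sum(P & Y) / (sp + sy)
}

#' Voxel-wise confusion counts
#'
#' @param P,Y logical arrays of equal shape.
#' @return list with \code{TP}, \code{FP}, \code{FN}, \code{TN} (their sum
#'   is the voxel count).
#' @export
confusionCounts <- function(P, Y) {
  stopifnot(identical(dim(P), dim(Y)))
  list(TP = sum(P & Y), FP = sum(P & !Y), FN = sum(!P & Y),
       TN = sum(!P & !Y))
}

rateOrZero <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": zero denominator; returning 0")
    return(0)
  }
  num / den
}

#' Sensitivity (recall): TP / (TP + FN)
#' @param counts a list from [confusionCounts()].
#' @return scalar in [0, 1]; 0 with a warning when undefined.
#' @export
sensitivity <- function(counts)
  rateOrZero(counts$TP, counts$TP + counts$FN, "sensitivity")

#' Specificity: TN / (TN + FP)
#' @inheritParams sensitivity
#' @export
specificity <- function(counts)
  rateOrZero(counts$TN, counts$TN + counts$FP, "specificity")

#' Precision (positive predictive value): TP / (TP + FP)
#' @inheritParams sensitivity
#' @export
precisionScore <- function(counts)
  rateOrZero(counts$TP, counts$TP + counts$FP, "precision")

## ---- surfaces and distances ------------------------------------------------

#' Boundary voxels of a mask
#'
#' A mask voxel is a boundary voxel when at least one of its six
#' face-neighbors is background; voxels on the array edge count the outside
#' as background.
#'
#' @param mask logical 3D array.
#' @return logical array marking the boundary voxels.
#' @export
surfaceVoxels <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  bgNeighbor <- array(FALSE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- array(TRUE, d)       # outside counts as background
    idxDst <- idxSrc <- lapply(d, seq_len)
    if (s > 0) { idxDst[[ax]] <- seq_len(d[ax] - 1L)
                 idxSrc[[ax]] <- seq_len(d[ax] - 1L) + 1L }
    else       { idxDst[[ax]] <- seq_len(d[ax] - 1L) + 1L
                 idxSrc[[ax]] <- seq_len(d[ax] - 1L) }
    nb[idxDst[[1L]], idxDst[[2L]], idxDst[[3L]]] <-
      !mask[idxSrc[[1L]], idxSrc[[2L]], idxSrc[[3L]]]
    bgNeighbor <- bgNeighbor | nb
  }
  mask & bgNeighbor
}

# mm distance from every voxel to the nearest TRUE voxel of `mask`
edtDistance <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  sq <- .edt3d_cpp(as.logical(mask), as.integer(d), as.numeric(spacing))
  array(sqrt(sq), d)
}

#' Directed surface distances between two masks
#'
#' Distances (mm) from every boundary voxel of \code{from} to the nearest
#' boundary voxel of \code{to}, using the exact Euclidean distance
#' transform with anisotropic voxel spacing.
#'
#' @param from,to logical 3D arrays of equal shape.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return numeric vector of distances (length = number of boundary voxels
#'   of \code{from}).
#' @export
surfaceDistances <- function(from, to, spacing = c(1, 1, 1)) {
  bf <- surfaceVoxels(from)
  bt <- surfaceVoxels(to)
  if (!any(bf)) return(numeric(0))
  if (!any(bt)) return(rep(Inf, sum(bf)))
  edtDistance(bt, spacing)[bf]
}

emptyMaskSentinel <- function(what) {
  warning(what, ": empty mask; returning NaN")
  NaN
}

#' 95th-percentile Hausdorff distance
#'
#' The larger of the two directed 95th-percentile surface distances between
#' prediction and reference boundaries, in mm. Symmetric by construction.
#'
#' @param P,Y logical 3D arrays (prediction, reference).
#' @param spacing numeric(3) voxel spacing in mm.
#' @return distance in mm; NaN with a warning if either mask is empty.
#' @export
hd95 <- function(P, Y, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(P), dim(Y)))
  if (!any(P) || !any(Y)) return(emptyMaskSentinel("hd95"))
  d1 <- surfaceDistances(P, Y, spacing)
  d2 <- surfaceDistances(Y, P, spacing)
  max(quantile(d1, 0.95, names = FALSE),
      quantile(d2, 0.95, names = FALSE))
}

#' Mean absolute surface distance
#'
#' Symmetric average of the mean nearest-boundary distances in both
#' directions: \eqn{(\overline{d}(Y \to P) + \overline{d}(P \to Y)) / 2},
#' in mm.
#'
#' @inheritParams hd95
#' @return distance in mm; NaN with a warning if either mask is empty.
#' @export
masd <- function(P, Y, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(P), dim(Y)))
  if (!any(P) || !any(Y)) return(emptyMaskSentinel("masd"))
  (mean(surfaceDistances(Y, P, spacing)) +
     mean(surfaceDistances(P, Y, spacing))) / 2
}

#' Normalized surface dice
#'
#' Fraction of boundary voxels lying within a tolerance \code{tau} (mm) of
#' the other mask's boundary:
#' \eqn{(|B_Y \cap R_P| + |B_P \cap R_Y|) / (|B_Y| + |B_P|)}, where the
#' border region \eqn{R} is the tolerance-dilation of a boundary. Two empty
#' masks score 1; exactly one empty mask scores 0.
#'
#' @inheritParams hd95
#' @param tau tolerance in mm (default 1).
#' @return scalar in [0, 1].
#' @export
nsd <- function(P, Y, tau = 1, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(P), dim(Y)), tau >= 0)
  bp <- surfaceVoxels(P); by <- surfaceVoxels(Y)
  np <- sum(bp); ny <- sum(by)
  if (np + ny == 0) return(1)
  if (np == 0 || ny == 0) return(0)
  tol <- tau + 1e-9
  rp <- edtDistance(bp, spacing) <= tol
  ry <- edtDistance(by, spacing) <= tol
  (sum(by & rp) + sum(bp & ry)) / (ny + np)
}

## ---- full report -----------------------------------------------------------

#' Seven-metric report over the WT/TC/ET regions
#'
#' Computes DSC, HD95, sensitivity, specificity, precision, NSD and MASD for
#' each of the three BraTS evaluation regions of a predicted versus a
#' reference label volume.
#'
#' @param pred,truth integer label arrays (values in \{0, 1, 2, 4\}) of
#'   equal shape.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param tau NSD tolerance in mm.
#' @return data.frame (class \code{MetricReport}) with one row per region.
#' @export
evaluateSegmentation <- function(pred, truth, spacing = c(1, 1, 1),
                                 tau = 1) {
  pm <- regionMasks(pred)
  tm <- regionMasks(truth)
  rows <- lapply(names(pm), function(r) {
    P <- pm[[r]]; Y <- tm[[r]]
    cc <- confusionCounts(P, Y)
    data.frame(region = r, DSC = dsc(P, Y),
               HD95 = suppressWarnings(hd95(P, Y, spacing)),
               SE = suppressWarnings(sensitivity(cc)),
               SP = suppressWarnings(specificity(cc)),
               Pres = suppressWarnings(precisionScore(cc)),
               NSD = nsd(P, Y, tau, spacing),
               MASD = suppressWarnings(masd(P, Y, spacing)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("MetricReport", "data.frame")
  out
}

#' Average a per-region metric table over regions
#'
#' Arithmetic mean of each numeric column — the "Avg." column analog of the
#' usual benchmark tables.
#'
#' @param report a data.frame with a \code{region} column and numeric
#'   metric columns (e.g. from [evaluateSegmentation()]).
#' @return one-row data.frame of column means.
#' @export
regionAverage <- function(report) {
  num <- vapply(report, is.numeric, logical(1))
  out <- as.data.frame(lapply(report[num], mean))
  cbind(region = "Avg", out)
}
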