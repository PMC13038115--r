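# Published BraTS 2020 benchmark figures bundled for arithmetic
# cross-checks: peer-model efficiency (FLOPs / parameters at 128^3 input),
# per-region segmentation scores reported for this architecture, its
# four-fold cross-validation results, and peer surface metrics. All values
# are literature-reported numbers, carried as data so that relative
# improvements and region averages can be recomputed rather than quoted.

#' Published benchmark figures
#'
#' Returns the bundled BraTS 2020 reference tables:
#' \describe{
#'   \item{efficiency}{per-model FLOPs per volume / per slice (G) and
#'     parameters (M) at a 128^3 input, peer models only.}
#'   \item{regions}{per-region DSC (\%) and HD95 (mm) reported for this
#'     architecture.}
#'   \item{folds}{four-fold cross-validation DSC (\%) and HD95 (mm) per
#'     region.}
#'   \item{rates}{per-region sensitivity, specificity and precision.}
#'   \item{surface}{per-region NSD and MASD for this architecture and the
#'     peer models reporting them.}
#' }
#'
#' @return named list of data.frames.
#' @export
publishedBenchmarks <- function() {
  efficiency <- data.frame(
    model = c("Swin-Unet", "TransBTS", "TransUnet", "UNETR", "Swin-UNETR",
              "nnFormer", "mmFormer", "CoTr", "UNet-Former", "CSWin-UNet",
              "this"),
    flopsPerVolumeG = c(249.61, 333.07, 361.61, 153.52, 394.84, 421.51,
                        742.32, 659.32, 159.51, 195.84, 115.51),
    flopsPerSliceG = c(1.94, 2.59, 2.82, 1.19, 3.08, 3.29, 5.79, 5.15,
                       1.24, 1.53, 0.902),
    paramsM = c(27.17, 32.99, 96.07, 92.51, 61.98, 149.59, 106.01, 149.61,
                58.96, 85, 50.56))
  regions <- data.frame(
    region = c("TC", "WT", "ET"),
    DSC = c(82.49, 91.03, 80.91),
    HD95 = c(4.65, 4.23, 5.74))
  folds <- data.frame(
    fold = rep(1:4, each = 3L),
    region = rep(c("TC", "WT", "ET"), 4L),
    DSC = c(80.41, 90.54, 78.32,
            82.67, 91.53, 80.61,
            82.91, 91.43, 79.96,
            79.63, 89.42, 80.18),
    HD95 = c(4.91, 4.23, 5.35,
             4.87, 4.12, 5.26,
             4.63, 4.10, 5.61,
             4.61, 4.29, 5.83))
  rates <- data.frame(
    region = c("TC", "WT", "ET"),
    SE = c(0.781, 0.912, 0.701),
    SP = c(0.968, 0.981, 0.949),
    Pres = c(0.883, 0.926, 0.852))
  surface <- data.frame(
    model = rep(c("TransBTS", "UNETR", "nnFormer", "Swin-UNETR", "this"),
                each = 3L),
    region = rep(c("TC", "WT", "ET"), 5L),
    NSD = c(37.48, 46.09, 33.61,
            37.67, 41.31, 35.20,
            38.17, 40.22, 34.41,
            38.31, 43.89, 35.80,
            40.79, 48.21, 38.10),
    MASD = c(1.39, 2.48, 1.86,
             1.29, 2.25, 2.11,
             1.41, 2.04, 1.57,
             1.31, 2.34, 2.23,
             0.89, 0.86, 0.92))
  list(efficiency = efficiency, regions = regions, folds = folds,
       rates = rates, surface = surface)
}

#' Relative improvement over a baseline, in percent
#'
#' \code{(baseline - value) / baseline * 100}: the percentage by which
#' \code{value} undercuts \code{baseline} (positive = cheaper/better for
#' costs and distances).
#'
#' @param baseline reference value (> 0).
#' @param value the compared value.
#' @return percentage.
#' @examples
#' relativeImprovement(200, 50)   # 75
#' @export
relativeImprovement <- function(baseline, value) {
  stopifnot(baseline > 0)
  (baseline - value) / baseline * 100
}
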