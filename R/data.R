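# BraTS-style case handling: NIfTI I/O, modality stacking, cropping,
# tumor-fraction filtering, case splitting, and a synthetic nested-ellipsoid
# tumor phantom generator that emulates the multimodal layout (four
# modalities sharing one geometry, labels in {0, 1, 2, 4}).

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specify a synthetic tumor phantom
#'
#' A phantom is a nested-ellipsoid stand-in for a multimodal brain-tumor
#' case: a necrotic core (label 1) inside an enhancing shell (label 4)
#' inside an edema halo (label 2), embedded in an ellipsoidal "brain" of
#' unit baseline intensity on a zero background. Region radii default to a
#' geometry whose halo occupies \code{tumorFraction} of the grid; modality
#' intensities follow the qualitative MRI contrasts of the four BraTS
#' modalities (T1ce-bright enhancement, T2/FLAIR-bright edema, T1-dark
#' necrosis).
#'
#' @param extents integer(3) grid extents (D, H, W).
#' @param tumorFraction target fraction of voxels inside the whole tumor.
#' @param center tumor center in voxel coordinates (defaults to the grid
#'   center).
#' @param radii optional list with numeric(3) semi-axes \code{core},
#'   \code{shell}, \code{halo} (voxels); derived from \code{tumorFraction}
#'   when missing.
#' @param intensities 4 x 4 matrix of modality means, rows T1, T1ce, T2,
#'   FLAIR; columns brain, core, shell, halo.
#' @param noiseSd Gaussian noise standard deviation.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param seed RNG seed making the phantom reproducible.
#' @return a \code{PhantomSpec} list.
#' @export
phantomSpec <- function(extents = c(64L, 64L, 64L), tumorFraction = 0.05,
                        center = NULL, radii = NULL, intensities = NULL,
                        noiseSd = 0.1, spacing = c(1, 1, 1), seed = 1L) {
  extents <- as.integer(extents)
  stopifnot(length(extents) == 3L, all(extents >= 8L),
            tumorFraction > 0, tumorFraction < 1)
  if (is.null(center)) center <- (extents + 1) / 2
  if (is.null(radii)) {
    aniso <- c(1, 1.15, 0.9)
    base <- (3 * tumorFraction * prod(extents) / (4 * pi * prod(aniso)))^(1 / 3)
    halo <- base * aniso
    radii <- list(core = 0.45 * halo, shell = 0.7 * halo, halo = halo)
  }
  if (!all(radii$core < radii$shell) || !all(radii$shell < radii$halo))
    stop("phantom radii must nest: core < shell < halo on every axis")
  if (any(radii$halo >= extents / 2))
    stop("halo radii do not fit the grid")
  if (is.null(intensities)) {
    intensities <- rbind(
      T1    = c(1.0, 0.6, 0.9, 0.8),
      T1ce  = c(1.0, 0.5, 1.8, 0.9),
      T2    = c(1.0, 1.4, 1.2, 1.6),
      FLAIR = c(1.0, 1.1, 1.2, 1.8))
    colnames(intensities) <- c("brain", "core", "shell", "halo")
  }
  structure(list(extents = extents, tumorFraction = tumorFraction,
                 center = center, radii = radii, intensities = intensities,
                 noiseSd = noiseSd, spacing = as.numeric(spacing),
                 seed = seed),
            class = "PhantomSpec")
}

#' Generate a synthetic multimodal tumor case
#'
#' Renders the nested-ellipsoid phantom described by a [phantomSpec()]:
#' labels 1 (core), 4 (shell), 2 (halo) on background 0, plus four noisy
#' modality volumes sharing the geometry. Deterministic for a fixed seed.
#'
#' @param spec a \code{PhantomSpec}.
#' @param id case identifier string.
#' @return a \code{CaseRecord}: list with \code{id}, \code{modalities}
#'   (named list T1, T1ce, T2, FLAIR of 3D arrays), \code{labels} and
#'   \code{spacing}.
#' @export
generatePhantom <- function(spec, id = "phantom-001") {
  stopifnot(inherits(spec, "PhantomSpec"))
  e <- spec$extents
  co <- tokenCoords(0:(prod(e) - 1L), e) + 1L
  inEll <- function(r, c0) {
    z <- ((co[, 1L] - c0[1L]) / r[1L])^2 +
      ((co[, 2L] - c0[2L]) / r[2L])^2 +
      ((co[, 3L] - c0[3L]) / r[3L])^2
    z <= 1
  }
  labels <- integer(prod(e))
  labels[inEll(spec$radii$halo, spec$center)] <- 2L
  labels[inEll(spec$radii$shell, spec$center)] <- 4L
  labels[inEll(spec$radii$core, spec$center)] <- 1L
  brain <- inEll(0.45 * e, (e + 1) / 2)
  dim(labels) <- e
  regionIdx <- ifelse(labels == 0L, 1L,
                      ifelse(labels == 1L, 2L, ifelse(labels == 4L, 3L, 4L)))
  modalities <- withSeed(spec$seed, {
    out <- list()
    for (m in rownames(spec$intensities)) {
      v <- spec$intensities[m, regionIdx] +
        rnorm(prod(e), sd = spec$noiseSd)
      v[!brain] <- 0
      out[[m]] <- array(v, e)
    }
    out
  })
  structure(list(id = id, modalities = modalities, labels = labels,
                 spacing = spec$spacing),
            class = "CaseRecord")
}

#' Generate a suite of phantoms with varied geometry
#'
#' Convenience wrapper producing \code{n} cases whose tumor fraction and
#' center jitter deterministically with the seed.
#'
#' @param n number of cases.
#' @param extents grid extents (D, H, W).
#' @param seed base seed; case i uses \code{seed + i}.
#' @param tumorFraction mean target tumor fraction.
#' @return list of \code{CaseRecord}s.
#' @export
generatePhantomSuite <- function(n, extents = c(32L, 32L, 32L), seed = 1L,
                                 tumorFraction = 0.05) {
  lapply(seq_len(n), function(i) {
    fr <- withSeed(seed + i, runif(1, 0.7, 1.3)) * tumorFraction
    generatePhantom(phantomSpec(extents, tumorFraction = fr,
                                seed = seed + i),
                    id = sprintf("phantom-%03d", i))
  })
}

## ---- preprocessing ---------------------------------------------------------

#' Stack the model's input modalities
#'
#' Combines T1ce, T2 and FLAIR (T1 is excluded) into one three-channel
#' volume in that channel order.
#'
#' @param case a \code{CaseRecord}.
#' @return numeric array (3, D, H, W).
#' @export
stackModalities <- function(case) {
  mods <- case$modalities[c("T1ce", "T2", "FLAIR")]
  if (any(vapply(mods, is.null, logical(1))))
    stop("case must provide T1ce, T2 and FLAIR modalities")
  d <- dim(mods[[1L]])
  for (m in mods) if (!identical(dim(m), d))
    stop("modalities do not share one geometry")
  if (!is.null(case$labels) && !identical(dim(case$labels), d))
    stop("labels do not share the modality geometry")
  out <- array(0, c(3L, d))
  for (i in 1:3) out[i, , , ] <- mods[[i]]
  out
}

#' Per-channel z-score normalization over nonzero voxels
#'
#' Standard BraTS-style intensity normalization: each channel is centered
#' and scaled using the mean and standard deviation of its nonzero
#' (brain) voxels only; zero background stays zero.
#'
#' @param x numeric array (C, D, H, W).
#' @return normalized array of the same shape.
#' @export
zscoreNormalize <- function(x) {
  stopifnot(length(dim(x)) == 4L)
  for (c in seq_len(dim(x)[1L])) {
    v <- x[c, , , ]
    nz <- v != 0
    if (!any(nz)) next
    mu <- mean(v[nz]); sd <- stats::sd(v[nz])
    if (!is.finite(sd) || sd == 0) sd <- 1
    v[nz] <- (v[nz] - mu) / sd
    x[c, , , ] <- v
  }
  x
}

#' Crop an image/label pair
#'
#' Crops the image (and labels, when given) to \code{size}, centered by
#' default; \code{center = "tumor"} centers on the label centroid instead
#' (clamped so the crop stays inside the volume).
#'
#' @param x numeric array, (C, D, H, W) or (D, H, W).
#' @param labels optional integer array (D, H, W), cropped identically.
#' @param size integer(3) output extents.
#' @param center \code{"center"} or \code{"tumor"}.
#' @return list with \code{image} and \code{labels} (NULL if not supplied).
#' @export
cropVolume <- function(x, labels = NULL, size = c(128L, 128L, 128L),
                       center = c("center", "tumor")) {
  center <- match.arg(center)
  size <- as.integer(size)
  spatialDims <- if (length(dim(x)) == 4L) dim(x)[2:4] else dim(x)
  if (any(size > spatialDims))
    stop("crop size exceeds the input extents")
  mid <- if (center == "tumor") {
    if (is.null(labels)) stop("tumor-centered crop requires labels")
    fg <- which(labels != 0, arr.ind = TRUE)
    if (nrow(fg) == 0) (spatialDims + 1) / 2 else colMeans(fg)
  } else (spatialDims + 1) / 2
  start <- round(mid - size / 2)
  start <- pmin(pmax(start, 1L), spatialDims - size + 1L)
  idx <- lapply(1:3, function(a) seq.int(start[a], length.out = size[a]))
  img <- if (length(dim(x)) == 4L)
    x[, idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  else x[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  lab <- if (!is.null(labels))
    labels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
  list(image = img, labels = lab)
}

#' Fraction of tumor-related voxels in a label volume
#' @param labels integer array; tumor-related means any label != 0.
#' @return scalar fraction.
#' @export
tumorFraction <- function(labels) mean(labels != 0)

#' Filter cases by minimum tumor fraction
#'
#' Keeps a case iff the fraction of non-background label voxels is at least
#' \code{threshold} (boundary inclusive), the standard screen against cases
#' with insufficient tumor representation.
#'
#' @param cases list of \code{CaseRecord}s.
#' @param threshold minimum tumor fraction (default 0.01 = 1\%).
#' @return the retained cases (same order).
#' @export
tumorFractionFilter <- function(cases, threshold = 0.01) {
  keep <- vapply(cases, function(cs) tumorFraction(cs$labels) >= threshold,
                 logical(1))
  cases[keep]
}

## ---- splits ----------------------------------------------------------------

#' Train/validation split of cases
#'
#' Disjoint, exhaustive, seed-reproducible split at the case level; the
#' training side receives \code{round(ratio * n)} cases.
#'
#' @param cases list (or vector) of cases/ids; length >= 2.
#' @param ratio training fraction (default 0.75).
#' @param seed RNG seed.
#' @return list with \code{train} and \code{validation} subsets.
#' @export
splitCases <- function(cases, ratio = 0.75, seed = 1L) {
  n <- length(cases)
  stopifnot(n >= 2L, ratio > 0, ratio < 1)
  ntr <- round(ratio * n)
  ntr <- min(max(ntr, 1L), n - 1L)
  idx <- withSeed(seed, sample.int(n))
  list(train = cases[sort(idx[seq_len(ntr)])],
       validation = cases[sort(idx[(ntr + 1L):n])])
}

#' k-fold cross-validation splits
#'
#' Each case appears in exactly one validation fold; folds are disjoint,
#' exhaustive and seed-reproducible.
#'
#' @param cases list (or vector) of cases/ids; length >= k.
#' @param k number of folds (default 4).
#' @param seed RNG seed.
#' @return list of k lists, each with \code{train} and \code{validation}.
#' @export
kfoldSplits <- function(cases, k = 4L, seed = 1L) {
  n <- length(cases)
  stopifnot(n >= k, k >= 2L)
  idx <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[idx] <- rep(seq_len(k), length.out = n)   # round-robin over shuffle
  lapply(seq_len(k), function(f)
    list(train = cases[fold != f], validation = cases[fold == f]))
}

## ---- NIfTI I/O -------------------------------------------------------------

#' Write a case as BraTS-style NIfTI files
#'
#' Emits \code{<id>_<modality>.nii.gz} for each modality plus
#' \code{<id>_seg.nii.gz}, carrying the voxel spacing in the header.
#'
#' @param case a \code{CaseRecord}.
#' @param dir output directory (created if needed).
#' @return the case id, invisibly.
#' @export
writeCase <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(arr, suffix) {
    img <- RNifti::asNifti(arr, reference = NULL)
    RNifti::pixdim(img) <- case$spacing
    RNifti::writeNifti(img, file.path(dir,
                                      paste0(case$id, "_", suffix, ".nii.gz")))
  }
  for (m in names(case$modalities))
    wr(case$modalities[[m]], tolower(m))
  wr(case$labels, "seg")
  invisible(case$id)
}

#' Read a BraTS-style NIfTI case
#'
#' @param dir directory holding \code{<id>_<modality>.nii.gz} files.
#' @param id case identifier.
#' @return a \code{CaseRecord}.
#' @export
readCase <- function(dir, id) {
  rd <- function(suffix) {
    f <- file.path(dir, paste0(id, "_", suffix, ".nii.gz"))
    if (!file.exists(f)) stop("missing file: ", f)
    img <- RNifti::readNifti(f)
    list(arr = array(as.numeric(img), dim(img)),
         spacing = RNifti::pixdim(img))
  }
  mods <- list(T1 = rd("t1"), T1ce = rd("t1ce"), T2 = rd("t2"),
               FLAIR = rd("flair"))
  seg <- rd("seg")
  structure(list(id = id,
                 modalities = lapply(mods, `[[`, "arr"),
                 labels = array(as.integer(round(seg$arr)), dim(seg$arr)),
                 spacing = as.numeric(seg$spacing)),
            class = "CaseRecord")
}
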