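# Region grouping and the seven evaluation metrics, cross-checked against
# brute-force oracles on small grids.

test_that("region grouping nests ET within TC within WT", {
  empty <- array(0L, c(3L, 3L, 3L))
  m0 <- regionMasks(empty)
  expect_true(!any(m0$WT) && !any(m0$TC) && !any(m0$ET))
  one <- empty; one[2L, 2L, 2L] <- 4L
  m1 <- regionMasks(one)
  expect_equal(sum(m1$WT), 1L); expect_equal(sum(m1$TC), 1L)
  expect_equal(sum(m1$ET), 1L)
  # toy counts {1: 2, 2: 3, 4: 1} -> |ET| = 1, |TC| = 3, |WT| = 6
  toy <- array(0L, c(2L, 3L, 1L))
  toy[1:2] <- 1L; toy[3:5] <- 2L; toy[6L] <- 4L
  mt <- regionMasks(toy)
  expect_equal(c(sum(mt$ET), sum(mt$TC), sum(mt$WT)), c(1L, 3L, 6L))
  expect_true(all(which(mt$ET) %in% which(mt$TC)))
  expect_true(all(which(mt$TC) %in% which(mt$WT)))
  expect_error(regionMasks(array(3L, c(2L, 2L, 2L))), "unknown label")
})

test_that("overlap and set formulations of the dice coefficient agree", {
  a <- randomMask(c(4L, 4L, 4L), seed = 1L)
  expect_equal(dsc(a, a), 1)
  b <- array(FALSE, dim(a)); b[!a] <- TRUE     # complement: disjoint
  b[1] <- b[1] && !a[1]
  expect_equal(dsc(a, !a), 0)
  # |P intersect Y| = 2, |P| = 3, |Y| = 3 -> 2/3, matching the count form
  P <- array(FALSE, c(3L, 3L, 1L)); P[c(1, 2, 3)] <- TRUE
  Y <- array(FALSE, c(3L, 3L, 1L)); Y[c(2, 3, 4)] <- TRUE
  expect_equal(dsc(P, Y), 2 / 3)
  cc <- confusionCounts(P, Y)
  expect_equal(2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN), 2 / 3)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 9L)
  # both-empty convention
  e <- array(FALSE, c(2L, 2L, 2L))
  expect_equal(dsc(e, e), 1)
  # property: the two formulations agree on random masks
  for (i in 1:25) {
    g <- sample(2:8, 3L, replace = TRUE)
    P <- randomMask(g, runif(1, 0.1, 0.9), seed = i)
    Y <- randomMask(g, runif(1, 0.1, 0.9), seed = i + 100)
    cc <- confusionCounts(P, Y)
    lhs <- dsc(P, Y)
    rhs <- if (2 * cc$TP + cc$FP + cc$FN == 0) 1 else
      2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN)
    expect_equal(lhs, rhs)
  }
})

test_that("confusion-count rates and their zero-denominator conventions", {
  cc <- list(TP = 3L, FP = 1L, FN = 1L, TN = 9L)
  expect_equal(sensitivity(cc), 0.75)
  expect_equal(specificity(cc), 0.9)
  expect_equal(precisionScore(cc), 0.75)
  perfect <- confusionCounts(array(TRUE, c(2L, 2L, 2L)),
                             array(TRUE, c(2L, 2L, 2L)))
  expect_equal(sensitivity(perfect), 1)
  expect_equal(precisionScore(perfect), 1)
  expect_warning(sp0 <- specificity(perfect), "zero denominator")
  expect_equal(sp0, 0)
})

test_that("surface distances match the O(n^2) pairwise oracle", {
  set.seed(7)
  for (i in 1:6) {
    g <- sample(5:12, 3L, replace = TRUE)
    sp <- if (i %% 2 == 0) c(1, 1, 1) else c(0.7, 1.2, 2)
    P <- array(FALSE, g); Y <- array(FALSE, g)
    # random blobs (thresholded distance from random centers)
    cp <- sapply(g, function(n) sample(n, 1))
    cy <- sapply(g, function(n) sample(n, 1))
    co <- which(array(TRUE, g), arr.ind = TRUE)
    P[rowSums((t(t(co) - cp))^2) <= runif(1, 2, 9)] <- TRUE
    Y[rowSums((t(t(co) - cy))^2) <= runif(1, 2, 9)] <- TRUE
    if (!any(P) || !any(Y)) next
    expect_equal(sort(surfaceDistances(P, Y, sp)),
                 sort(bruteSurfaceDistances(P, Y, sp)), tolerance = 1e-10)
    # production hd95/masd equal their brute-force recomputation
    d1 <- bruteSurfaceDistances(P, Y, sp); d2 <- bruteSurfaceDistances(Y, P, sp)
    expect_equal(hd95(P, Y, sp),
                 max(quantile(d1, 0.95, names = FALSE),
                     quantile(d2, 0.95, names = FALSE)))
    expect_equal(masd(P, Y, sp), (mean(d2) + mean(d1)) / 2)
  }
})

test_that("hd95 closed forms: coincident, separated points, symmetry", {
  a <- randomMask(c(5L, 5L, 5L), 0.4, seed = 2L)
  if (any(a)) expect_equal(hd95(a, a), 0)
  # two single-voxel masks separated by k voxels along one axis
  for (k in c(1L, 3L)) {
    P <- array(FALSE, c(8L, 3L, 3L)); P[2L, 2L, 2L] <- TRUE
    Y <- array(FALSE, c(8L, 3L, 3L)); Y[2L + k, 2L, 2L] <- TRUE
    expect_equal(hd95(P, Y), k)
    expect_equal(hd95(P, Y), hd95(Y, P))
  }
  expect_warning(v <- hd95(array(FALSE, c(2L, 2L, 2L)),
                           array(TRUE, c(2L, 2L, 2L))), "empty")
  expect_true(is.nan(v))
})

test_that("normalized surface dice: tolerance behavior on a shifted cube", {
  g <- c(8L, 8L, 8L)
  mkCube <- function(o) {
    m <- array(FALSE, g); m[o + 1:3, o + 1:3, o + 1:3] <- TRUE; m
  }
  Y <- mkCube(1L); P <- mkCube(2L)      # shift by 1 voxel diagonal-ish? no:
  expect_equal(nsd(Y, Y, tau = 0), 1)
  # axis shift by exactly one voxel
  P1 <- array(FALSE, g); P1[2:4 + 1L, 2:4, 2:4] <- TRUE
  Y1 <- array(FALSE, g); Y1[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nsd(P1, Y1, tau = 1), 1)
  # tau = 0: fraction of exactly-coincident boundary voxels, via brute force
  bp <- which(surfaceVoxels(P1), arr.ind = TRUE)
  by <- which(surfaceVoxels(Y1), arr.ind = TRUE)
  hit <- function(A, B) sum(apply(A, 1L, function(v)
    any(colSums((t(B) - v)^2) == 0)))
  expect_equal(nsd(P1, Y1, tau = 0),
               (hit(by, bp) + hit(bp, by)) / (nrow(by) + nrow(bp)))
  expect_lt(nsd(P1, Y1, tau = 0), 1)
  # monotone non-decreasing in tau
  taus <- c(0, 0.5, 1, 1.5, 3)
  vals <- vapply(taus, function(t) nsd(P1, Y1, tau = t), numeric(1))
  expect_true(all(diff(vals) >= 0))
  # empty conventions
  e <- array(FALSE, g)
  expect_equal(nsd(e, e), 1)
  expect_equal(nsd(P1, e), 0)
})

test_that("mean absolute surface distance: planes and symmetry", {
  g <- c(7L, 5L, 5L)
  P <- array(FALSE, g); P[2L, , ] <- TRUE      # plane d = 2
  Y <- array(FALSE, g); Y[5L, , ] <- TRUE      # plane d = 5, distance 3
  expect_equal(masd(P, Y), 3)
  expect_equal(masd(P, Y), masd(Y, P))
  expect_equal(masd(P, P), 0)
  # spacing scales distances
  expect_equal(masd(P, Y, spacing = c(2, 1, 1)), 6)
  # MASD never exceeds the worst-case surface distance
  set.seed(9)
  for (i in 1:5) {
    A <- randomMask(c(6L, 6L, 6L), 0.3, seed = i)
    B <- randomMask(c(6L, 6L, 6L), 0.3, seed = i + 50)
    if (!any(A) || !any(B)) next
    dmax <- max(c(surfaceDistances(A, B), surfaceDistances(B, A)))
    expect_lte(masd(A, B), dmax + 1e-12)
  }
})

test_that("metrics are invariant under simultaneous axis permutation", {
  A <- randomMask(c(5L, 6L, 7L), 0.35, seed = 11L)
  B <- randomMask(c(5L, 6L, 7L), 0.35, seed = 12L)
  perm <- c(3L, 1L, 2L)
  Ap <- aperm(A, perm); Bp <- aperm(B, perm)
  expect_equal(dsc(A, B), dsc(Ap, Bp))
  expect_equal(hd95(A, B), hd95(Ap, Bp))
  expect_equal(masd(A, B), masd(Ap, Bp))
  expect_equal(nsd(A, B, tau = 1), nsd(Ap, Bp, tau = 1))
})

test_that("full report covers three regions and a coherent average", {
  lab <- generatePhantom(phantomSpec(c(24L, 24L, 24L), tumorFraction = 0.1,
                                     seed = 5L))$labels
  rep <- evaluateSegmentation(lab, lab)
  expect_equal(rep$region, c("WT", "TC", "ET"))
  expect_equal(rep$DSC, rep(1, 3))
  expect_equal(rep$HD95, rep(0, 3))
  expect_equal(rep$NSD, rep(1, 3))
  expect_equal(rep$MASD, rep(0, 3))
  avg <- regionAverage(rep)
  expect_equal(avg$DSC, 1)
  expect_equal(avg$MASD, 0)
})
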