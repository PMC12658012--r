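# Dice, surface extraction, ASD, HD95 and the ROI restriction, checked
# against brute-force oracles.

test_that("Dice score counts overlap and handles empty masks", {
  m <- array(0L, c(4, 4, 4)); m[1:2, 1:2, 1:2] <- 1L     # 8 voxels
  a <- voxelMask(m)
  expect_equal(diceScore(a, a), 1)
  b <- array(0L, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- 1L
  expect_equal(diceScore(a, voxelMask(b)), 0)            # disjoint
  # |A| = 8, |B| = 8, |A inter B| = 4 -> 0.5
  cArr <- array(0L, c(4, 4, 4)); cArr[1:2, 1:2, 2:3] <- 1L
  expect_equal(diceScore(a, voxelMask(cArr)), 0.5)
  # symmetry and empty/empty convention
  expect_equal(diceScore(voxelMask(cArr), a), 0.5)
  e <- voxelMask(array(0L, c(4, 4, 4)))
  expect_equal(diceScore(e, e), 1)
  expect_equal(diceScore(a, e), 0)
  expect_error(diceScore(a, voxelMask(array(0L, c(5, 5, 5)))),
               class = "fibseg_grid_mismatch")
})

test_that("surface voxels are the 6-connected boundary, in mm", {
  # 3x3x3 solid cube: the 26 shell voxels touch background through a
  # face; the center voxel is 6-connected-interior (brute force agrees)
  m <- array(0L, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(surfacePoints(voxelMask(m))), 26)
  expect_equal(nrow(oracleSurfacePoints(voxels(voxelMask(m)))), 26)
  # a 5^3 cube keeps only the shell: 125 - 27 interior
  m2 <- array(1L, c(5, 5, 5))
  expect_equal(nrow(surfacePoints(voxelMask(m2))), 125 - 27)
  # single voxel -> its center
  m3 <- array(0L, c(3, 3, 3)); m3[2, 3, 1] <- 1L
  p <- surfacePoints(voxelMask(m3, spacing = c(2, 2, 2), origin = c(1, 1, 1)))
  expect_equal(unname(p[1, ]), c(1, 1, 1) + c(1, 2, 0) * 2)
  # agrees with the brute-force oracle on random masks
  set.seed(11)
  for (r in 1:5) {
    arr <- randomMask(c(6, 7, 5), 0.4)
    if (sum(arr) == 0) next
    got <- surfacePoints(voxelMask(arr, spacing = c(1, 2, 3)))
    want <- oracleSurfacePoints(arr, spacing = c(1, 2, 3))
    expect_equal(got[order(got[,1], got[,2], got[,3]), , drop = FALSE],
                 unname(want[order(want[,1], want[,2], want[,3]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("ASD measures plate separation and scales with spacing", {
  # two parallel 1-voxel plates 4 mm apart
  m1 <- array(0L, c(9, 5, 5)); m1[2, , ] <- 1L
  m2 <- array(0L, c(9, 5, 5)); m2[6, , ] <- 1L
  a <- voxelMask(m1); b <- voxelMask(m2)
  expect_equal(avgSurfaceDistance(a, b), 4)
  expect_equal(avgSurfaceDistance(a, a), 0)
  # doubling the spacing doubles the distance
  a2 <- voxelMask(m1, spacing = c(2, 2, 2)); b2 <- voxelMask(m2, spacing = c(2, 2, 2))
  expect_equal(avgSurfaceDistance(a2, b2), 8)
  expect_equal(hausdorff95(a2, b2), 8)
})

test_that("HD95 is the interpolated 95th percentile of pooled distances", {
  # constructed multiset: 100 distances of 1 mm and 100 of 3 mm -> 3 mm
  d <- c(rep(1, 100), rep(3, 100))
  expect_equal(unname(quantile(d, 0.95, type = 7)), 3)
  # same convention inside hausdorff95: identical masks give 0
  m <- array(0L, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- 1L
  expect_equal(hausdorff95(voxelMask(m), voxelMask(m)), 0)
})

test_that("ASD and HD95 match the all-pairs brute-force oracle on random masks", {
  set.seed(101)
  nPairs <- 0
  for (r in 1:45) {
    a <- randomMask(); b <- randomMask()
    if (sum(a) == 0 || sum(b) == 0) next
    nPairs <- nPairs + 1
    sp <- c(0.8, 1.1, 2.3)
    ma <- voxelMask(a, spacing = sp); mb <- voxelMask(b, spacing = sp)
    want <- oracleSurfaceMetrics(a, b, sp)
    expect_lt(abs(avgSurfaceDistance(ma, mb) - want$asd), 1e-9)
    expect_lt(abs(hausdorff95(ma, mb) - want$hd95), 1e-9)
    # ordering invariant: ASD <= HD95 <= HD100
    expect_lte(avgSurfaceDistance(ma, mb), hausdorff95(ma, mb) + 1e-12)
    expect_lte(hausdorff95(ma, mb), hausdorff95(ma, mb, probs = 1) + 1e-12)
    expect_lt(abs(hausdorff95(ma, mb, probs = 1) - want$hdmax), 1e-9)
    # symmetry
    expect_equal(avgSurfaceDistance(mb, ma), avgSurfaceDistance(ma, mb))
    expect_equal(hausdorff95(mb, ma), hausdorff95(ma, mb))
  }
  expect_gte(nPairs, 40)
})

test_that("the ROI window derives from the ground-truth z-extent", {
  # bone spanning z = 0..350 mm -> window [70, 280]
  m <- array(0L, c(4, 4, 71)); m[2, 2, ] <- 1L        # spacing 5 mm: 0..350
  gt <- voxelMask(m, spacing = c(1, 1, 5))
  pred <- voxelMask(m, spacing = c(1, 1, 5))
  roi <- roiRestrict(gt, pred, cropMm = 70)
  expect_true(roi$valid)
  expect_equal(roi$window, c(70, 280))
  zKept <- which(apply(voxels(roi$gt), 3, sum) > 0)
  expect_equal(range((zKept - 1) * 5), c(70, 280))
  # idempotent for the fixed gt window
  roi2 <- roiRestrict(roi$gt, roi$pred, cropMm = 0)
  expect_identical(voxels(roi2$gt), voxels(roi$gt))
  # crop 0 is the identity
  roi0 <- roiRestrict(gt, pred, cropMm = 0)
  expect_identical(voxels(roi0$gt), voxels(gt))
  # z-extent of exactly 2*crop flags the ROI invalid
  m2 <- array(0L, c(4, 4, 29)); m2[2, 2, ] <- 1L      # 0..140 mm
  gt2 <- voxelMask(m2, spacing = c(1, 1, 5))
  roi3 <- roiRestrict(gt2, gt2, cropMm = 70)
  expect_false(roi3$valid)
})

test_that("evaluatePair reports whole-bone and ROI metrics with validity flags", {
  p <- tinyPhantomParams()
  ph <- generatePhantom(p)
  gt <- ph@leftFibula
  rep1 <- evaluatePair(gt, gt, cropMm = 70)
  expect_equal(rep1$DS, 1); expect_equal(rep1$ROI_DS, 1)
  expect_equal(rep1$ASD_mm, 0); expect_equal(rep1$HD95_mm, 0)
  expect_equal(rep1$ROI_ASD_mm, 0); expect_equal(rep1$ROI_HD95_mm, 0)
  # deleting the proximal bulge hurts the whole bone more than the ROI
  pred <- voxels(gt)
  zTop <- gridDim(gt)[3] - round(0.12 * gridDim(gt)[3]):0
  pred[, , zTop] <- 0L
  predM <- voxelMask(pred, spacing(gt), origin(gt))
  rep2 <- evaluatePair(gt, predM, cropMm = 70)
  expect_gt(rep2$ROI_DS, rep2$DS)
  expect_equal(rep2$ROI_DS, 1)
  # empty prediction: DS 0, surface metrics flagged invalid
  rep3 <- evaluatePair(gt, voxelMask(array(0L, gridDim(gt)), spacing(gt), origin(gt)))
  expect_equal(rep3$DS, 0)
  expect_false(rep3$surface_valid)
  expect_true(is.na(rep3$ASD_mm))
})
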