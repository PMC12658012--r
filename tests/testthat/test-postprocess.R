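# Post-processing chain: binarization, erosion, Gaussian smoothing,
# iso-surface extraction, component filtering, left/right labeling.

test_that("binarization thresholds at >= and is monotone", {
  p <- array(c(0.4, 0.5, 0.6, 0, 1, 0.2, 0.8, 0.5), c(2, 2, 2))
  m <- binarizeProb(p, 0.5)
  expect_equal(as.integer(m[1:3]), c(0L, 1L, 1L))
  expect_true(all(binarizeProb(p, 0) == 1))
  expect_true(all(binarizeProb(p, 1.01) == 0))
  # monotone: raising the threshold never adds voxels
  for (thr in c(0.2, 0.5, 0.9))
    expect_true(all(binarizeProb(p, thr + 0.05) <= binarizeProb(p, thr)))
  # CTVolume in, VoxelMask out with the same geometry
  v <- ctVolume(p, spacing = c(1, 2, 3))
  expect_s4_class(binarizeProb(v), "VoxelMask")
  expect_equal(spacing(binarizeProb(v)), c(1, 2, 3))
})

test_that("box erosion matches the brute-force oracle", {
  # 3x3x3 solid cube erodes to its center voxel
  m <- array(0L, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- 1L
  e <- erodeMask(m)
  expect_equal(sum(e), 1)
  expect_equal(e[3, 3, 3], 1L)
  # random masks against the oracle; erosion is anti-extensive
  set.seed(21)
  for (r in 1:5) {
    arr <- randomMask(c(7, 6, 8), 0.6)
    got <- erodeMask(arr)
    expect_identical(got, oracleErode(arr))
    expect_true(all(got <= arr))
  }
  # empty stays empty; border voxels always erode away
  expect_equal(sum(erodeMask(array(0L, c(4, 4, 4)))), 0)
  expect_equal(sum(erodeMask(array(1L, c(4, 4, 4)))), 2^3)
})

test_that("Gaussian smoothing conserves mass and respects symmetry", {
  # sigma 0 is the identity
  m <- randomMask(c(6, 6, 6))
  expect_equal(smoothMask(m, sigmaVox = 0), m * 1.0)
  # single interior voxel: field symmetric under axis permutations
  s <- array(0L, c(9, 9, 9)); s[5, 5, 5] <- 1L
  f <- smoothMask(s, sigmaVox = 1)
  expect_equal(f, aperm(f, c(2, 1, 3)), tolerance = 1e-12)
  expect_equal(f, aperm(f, c(3, 2, 1)), tolerance = 1e-12)
  expect_true(all(f >= 0 & f <= 1))
  # mass conservation for an interior blob
  blob <- array(0L, c(16, 16, 16)); blob[6:11, 6:11, 6:11] <- 1L
  fb <- smoothMask(blob, sigmaVox = 1)
  expect_lt(abs(sum(fb) / sum(blob) - 1), 0.001)
  # anisotropy: sigma in mm converts per axis
  mk <- voxelMask(blob, spacing = c(1, 2, 4))
  fmm <- smoothMask(mk, sigmaMm = 2)
  expect_s4_class(fmm, "CTVolume")
})

test_that("iso-surface extraction recovers physical volume and scales", {
  m <- array(0L, c(16, 16, 16)); m[4:13, 4:13, 4:13] <- 1L  # 10 mm cube
  msk <- voxelMask(m, spacing = c(1, 1, 1))
  mesh <- extractMesh(smoothMask(msk, sigmaVox = 0.5), 0.5)
  expect_lt(abs(meshVolume(mesh) / 1000 - 1), 0.1)
  # watertight: every edge is used by exactly two triangles
  Fc <- faces(mesh)
  ed <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
  # doubling the spacing doubles every vertex coordinate
  msk2 <- voxelMask(m, spacing = c(2, 2, 2))
  mesh2 <- extractMesh(smoothMask(msk2, sigmaVox = 0.5), 0.5)
  expect_equal(sort(vertices(mesh2)[, 3]), sort(2 * vertices(mesh)[, 3]),
               tolerance = 1e-12)
  # a field with no crossing has no surface
  expect_error(extractMesh(array(0, c(4, 4, 4)), 0.5),
               class = "fibseg_empty_surface")
  expect_error(extractMesh(array(1, c(4, 4, 4)), 0.5),
               class = "fibseg_empty_surface")
})

twoBlobMask <- function() {
  m <- array(0L, c(24, 10, 10))
  m[2:5, 2:5, 2:5] <- 1L          # 64 voxels, right side (low LR index)
  m[15:20, 2:7, 2:7] <- 1L        # 216 voxels, left side
  m[22, 9, 9] <- 1L               # speck
  voxelMask(m, spacing = c(1, 1, 1))
}

test_that("component filtering keeps the k largest and flags shortfalls", {
  cc <- keepLargestComponents(twoBlobMask(), k = 2)
  expect_false(cc$shortfall)
  expect_equal(cc$sizes, c(216L, 64L))                 # descending
  # idempotent
  un <- voxels(cc$components[[1]]) | voxels(cc$components[[2]])
  again <- keepLargestComponents(voxelMask(array(as.integer(un), dim(un))), k = 2)
  expect_equal(again$sizes, cc$sizes)
  # single component with k = 2: shortfall, never padded
  one <- array(0L, c(8, 8, 8)); one[2:4, 2:4, 2:4] <- 1L
  sf <- keepLargestComponents(voxelMask(one), k = 2)
  expect_true(sf$shortfall)
  expect_length(sf$components, 1)
  # empty input: empty result plus flag
  e <- keepLargestComponents(voxelMask(array(0L, c(4, 4, 4))), k = 1)
  expect_true(e$shortfall); expect_length(e$components, 0)
  # minFrac discards debris relative to the largest component
  deb <- keepLargestComponents(twoBlobMask(), k = 3, minFrac = 0.25)
  expect_equal(length(deb$components), 2)              # speck dropped
  expect_true(deb$shortfall)
  # ties broken stably by the left-right centroid
  tie <- array(0L, c(12, 4, 4)); tie[2:3, 2:3, 2:3] <- 1L; tie[9:10, 2:3, 2:3] <- 1L
  tt <- keepLargestComponents(voxelMask(tie), k = 2)
  expect_equal(tt$sizes, c(8L, 8L))
  expect_lt(fibseg:::.centroidLR(tt$components[[1]]),
            fibseg:::.centroidLR(tt$components[[2]]))
})

test_that("left/right labeling follows the axis convention and mirrors", {
  cc <- keepLargestComponents(twoBlobMask(), k = 2)
  lr <- labelLeftRight(cc$components)
  # the component with the greater LR coordinate is the left fibula
  expect_gt(fibseg:::.centroidLR(lr$left), fibseg:::.centroidLR(lr$right))
  expect_equal(sum(voxels(lr$left)), 216)
  # order invariance
  lr2 <- labelLeftRight(rev(cc$components))
  expect_identical(voxels(lr2$left), voxels(lr$left))
  # mirroring the scene swaps the labels
  mcc <- keepLargestComponents(mirrorLR(twoBlobMask()), k = 2)
  mlr <- labelLeftRight(mcc$components)
  expect_identical(voxels(mlr$left), voxels(mirrorLR(lr$right)))
  expect_identical(voxels(mlr$right), voxels(mirrorLR(lr$left)))
  # ambiguous centroids raise a labeling error
  same <- voxelMask(array(1L, c(2, 2, 2)))
  expect_error(labelLeftRight(list(same, same)), class = "fibseg_label_error")
  expect_error(labelLeftRight(cc$components[1]), class = "fibseg_param_error")
})

test_that("mesh post-processing keeps the phantom fibula volume within 25 percent", {
  # fine-resolution phantom: erosion removes one voxel radially, so the
  # bone must be thick in voxel units for the shrinkage bound to hold
  p <- phantomParams(gridDim = c(144L, 144L, 128L), spacing = c(1, 1, 2),
                     fibulaRadiusMm = 11, bulgeRadiusMm = 12, tibiaRadiusMm = 14,
                     fibulaOffsetMm = c(24, 14), noiseSd = 0)
  ph <- generatePhantom(p)
  mask <- ph@leftFibula
  mesh <- postprocessMask(mask, erodeIterations = 1, sigmaVox = 1)
  expect_s4_class(mesh, "SurfaceMesh")
  maskVol <- sum(voxels(mask)) * prod(spacing(mask))
  expect_lt(abs(meshVolume(mesh) / maskVol - 1), 0.25)
  # meshes live in physical coordinates within the field of view
  expect_true(all(vertices(mesh) >= 0))
  expect_true(all(sweep(vertices(mesh), 2, gridDim(mask) * spacing(mask)) <= 0))
})
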