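# NIfTI and STL round trips, manifest handling, eligibility filtering
# and train/validation splitting.

test_that("NIfTI volumes round-trip with spacing and origin", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  v <- ctVolume(array(17, c(16, 16, 16)), spacing = c(1, 1, 1))
  writeVolume(v, f)
  r <- readVolume(f)
  expect_equal(voxels(r), voxels(v))
  expect_equal(spacing(r), c(1, 1, 1))
  # anisotropic spacing and a nonzero origin survive bit-exactly
  set.seed(3)
  v2 <- ctVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
                 spacing = c(0.8, 0.8, 1.5), origin = c(-12.5, 4, 100))
  f2 <- withr::local_tempfile(fileext = ".nii")
  writeVolume(v2, f2)
  r2 <- readVolume(f2)
  # NIfTI-1 headers hold pixdim/origin as float32: equal to single
  # precision on first write, then bit-stable across further round trips
  expect_equal(spacing(r2), c(0.8, 0.8, 1.5), tolerance = 1e-6)
  expect_equal(origin(r2), c(-12.5, 4, 100), tolerance = 1e-6)
  expect_equal(voxels(r2), voxels(v2))
  f3 <- withr::local_tempfile(fileext = ".nii")
  writeVolume(r2, f3)
  r3 <- readVolume(f3)
  expect_identical(spacing(r3), spacing(r2))
  expect_identical(origin(r3), origin(r2))
})

test_that("non-volumetric NIfTI input is rejected", {
  f <- withr::local_tempfile(fileext = ".nii")
  img <- RNifti::asNifti(matrix(0, 8, 8))            # 2D image
  RNifti::writeNifti(img, f)
  expect_error(readVolume(f), class = "fibseg_shape_error")
  expect_error(readVolume("does-not-exist.nii"), class = "fibseg_io_error")
})

test_that("masks round-trip as 0/1 and non-binary files are rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  m <- voxelMask(randomMask(c(8, 8, 8)), spacing = c(2, 2, 2.5))
  writeMask(m, f)
  r <- readMask(f)
  expect_identical(voxels(r), voxels(m))
  f2 <- withr::local_tempfile(fileext = ".nii")
  writeVolume(ctVolume(array(0.5, c(4, 4, 4))), f2)
  expect_error(readMask(f2), class = "fibseg_format_error")
})

unitCubeMesh <- function(shift = c(0, 0, 0)) {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(V) <- NULL
  V <- sweep(V, 2, shift, "+")
  Fc <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7),
              c(1,2,5), c(2,6,5), c(3,7,4), c(4,7,8),
              c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))
  surfaceMesh(V, Fc)
}

test_that("binary STL round-trips vertices and faces", {
  f <- withr::local_tempfile(fileext = ".stl")
  mesh <- unitCubeMesh()
  writeMesh(mesh, f)
  r <- readMesh(f)
  expect_equal(nrow(faces(r)), 12)
  expect_equal(nrow(vertices(r)), 8)
  expect_equal(meshVolume(r), 1, tolerance = 1e-6)
  # translated cube: vertices shifted by exactly the translation
  f2 <- withr::local_tempfile(fileext = ".stl")
  writeMesh(unitCubeMesh(shift = c(10, -4, 2.5)), f2)
  r2 <- readMesh(f2)
  expect_equal(sort(vertices(r2)[, 1]), sort(vertices(r)[, 1] + 10),
               tolerance = 1e-6)
  expect_equal(meshVolume(r2), 1, tolerance = 1e-6)
  # float32 storage keeps small-coordinate precision well under 1e-5 mm
  expect_lt(max(abs(sort(as.numeric(vertices(r))) -
                    sort(as.numeric(vertices(mesh))))), 1e-5)
})

test_that("empty and corrupt STL files are handled explicitly", {
  f <- withr::local_tempfile(fileext = ".stl")
  empty <- surfaceMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_warning(writeMesh(empty, f), "empty mesh")
  expect_equal(nrow(faces(readMesh(f))), 0)
  # corrupt: declared triangle count disagrees with the file size
  f2 <- withr::local_tempfile(fileext = ".stl")
  con <- file(f2, "wb")
  writeBin(raw(80), con)
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(raw(60), con)                    # not 5 * 50 bytes
  close(con)
  expect_error(readMesh(f2), class = "fibseg_format_error")
  # degenerate faces are rejected by the class validity
  V <- matrix(rnorm(9), 3, 3)
  expect_error(surfaceMesh(V, rbind(c(1, 1, 2))), "degenerate")
  expect_error(surfaceMesh(V, rbind(c(1, 2, 4))), "range")
})

cohortManifest <- function(nRight = 13, nLeft = 26, nBoth = 36) {
  n <- nRight + nLeft + nBoth
  side <- rep(c("right", "left", "both"), c(nRight, nLeft, nBoth))
  data.frame(
    case_id = sprintf("c%03d", seq_len(n)),
    image = sprintf("img%03d.nii.gz", seq_len(n)),
    left_mask = ifelse(side %in% c("left", "both"), "l.nii.gz", NA),
    right_mask = ifelse(side %in% c("right", "both"), "r.nii.gz", NA),
    split = "unassigned", stringsAsFactors = FALSE)
}

test_that("manifests round-trip through CSV", {
  m <- cohortManifest(2, 3, 4)
  f <- withr::local_tempfile(fileext = ".csv")
  writeManifest(m, f)
  r <- readManifest(f)
  expect_equal(r$case_id, m$case_id)
  expect_equal(is.na(r$left_mask), is.na(m$left_mask))
  # duplicated ids and mask-less records are invalid
  bad <- m; bad$case_id[2] <- bad$case_id[1]
  expect_error(writeManifest(bad, f), class = "fibseg_format_error")
  bad2 <- m; bad2$left_mask[3] <- NA; bad2$right_mask[3] <- NA
  expect_error(writeManifest(bad2, f), class = "fibseg_format_error")
})

test_that("eligibility filtering reproduces the cohort arithmetic", {
  m <- cohortManifest(13, 26, 36)
  # per-fibula enumeration: 13 + 26 + 2*36 = 111 second-step samples
  s2 <- filterEligible(m, "step2")
  expect_equal(nrow(s2), 111)
  expect_false(anyDuplicated(s2$case_id) > 0)
  u1 <- filterEligible(m, "unilateral_step1")
  expect_equal(nrow(u1), 111)
  # bilateral step 1 keeps only both-sided records: 36 of 75 (52% excluded)
  b1 <- filterEligible(m, "bilateral_step1")
  expect_equal(nrow(b1), 36)
  expect_equal(round(100 * (nrow(m) - nrow(b1)) / nrow(m)), 52)
  # coverage: every bilateral-eligible case is a step-2 source
  expect_true(all(b1$case_id %in% s2$source_case))
  # degenerate cohort
  expect_error(filterEligible(cohortManifest(1, 1, 0), "bilateral_step1"),
               class = "fibseg_empty_manifest")
})

test_that("manifest splitting is seeded, disjoint and exhaustive", {
  m <- cohortManifest(0, 0, 22)
  s <- splitManifest(m, c(9, 1), seed = 5)
  expect_equal(sum(s$split == "train"), 20)
  expect_equal(sum(s$split == "val"), 2)
  # n = 10 at 9:1 -> 9 / 1
  s10 <- splitManifest(cohortManifest(0, 0, 10), c(9, 1), seed = 5)
  expect_equal(sum(s10$split == "train"), 9)
  expect_equal(sum(s10$split == "val"), 1)
  # determinism and seed sensitivity
  expect_identical(splitManifest(m, c(9, 1), seed = 5)$split, s$split)
  expect_false(identical(splitManifest(m, c(9, 1), seed = 6)$split, s$split))
  # partition property
  expect_setequal(unique(s$split), c("train", "val"))
  expect_error(splitManifest(m[1, ], c(9, 1), 1), class = "fibseg_split_error")
})
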