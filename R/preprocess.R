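# Geometric and intensity preprocessing shared by both pipelines:
# HU normalization, fixed-grid resampling, mid-plane splitting and
# mirroring, bounding boxes, cropping.

#' Normalize Hounsfield units to [0, 1]
#'
#' Clips intensities to the standard CT range \eqn{[-1024, 3071]} HU and
#' maps it linearly to \eqn{[0, 1]}: \eqn{(clip(h) + 1024) / 4095}. No
#' per-image standardization is applied.
#'
#' @param volume a [CTVolume-class] (HU) or a numeric array.
#' @return the same type with intensities in `[0, 1]`.
#' @examples
#' normalizeHU(array(c(-1024, 3071), c(2, 1, 1)))
#' @export
normalizeHU <- function(volume) {
  f <- function(h) (pmin(pmax(h, -1024), 3071) + 1024) / 4095
  if (is(volume, "CTVolume")) {
    volume@voxels <- f(volume@voxels)
    volume
  } else f(volume)
}

# internal: continuous 1-based source index per target index along one axis,
# with voxel centers aligned so that the physical extent is preserved
.srcIndex <- function(nOut, nIn) {
  (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
}

#' Resample a volume or mask to a target grid
#'
#' Resamples onto a grid of `targetDim` voxels covering the same physical
#' extent; spacing is rescaled accordingly. Images use trilinear
#' interpolation, masks nearest-neighbour (so they stay binary); with
#' `interpolation = "auto"` the rule follows the class of `x`.
#'
#' @param x a [CTVolume-class], [VoxelMask-class] or 3D array.
#' @param targetDim integer(3) target extents.
#' @param interpolation `"auto"`, `"trilinear"` or `"nearest"`.
#' @return same class as `x`, with `gridDim(x) == targetDim`.
#' @export
resampleGrid <- function(x, targetDim,
                         interpolation = c("auto", "trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  targetDim <- as.integer(targetDim)
  if (length(targetDim) != 3 || any(targetDim < 1))
    .fibsegError("fibseg_shape_error", "target dimensions must be three integers >= 1")
  isVol <- is(x, "CTVolume"); isMask <- is(x, "VoxelMask")
  arr <- if (isVol || isMask) voxels(x) else x
  if (interpolation == "auto")
    interpolation <- if (isMask) "nearest" else "trilinear"
  d <- dim(arr)
  src <- lapply(1:3, function(a) .srcIndex(targetDim[a], d[a]))
  out <- if (interpolation == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(floor(src[[a]] + 0.5), 1), d[a]))
    arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(a) pmin(pmax(floor(src[[a]]), 1), d[a]))
    hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, d[a]))
    w <- lapply(1:3, function(a) pmin(pmax(src[[a]] - lo[[a]], 0), 1))
    acc <- array(0, targetDim)
    for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
      i1 <- if (c1) hi[[1]] else lo[[1]]
      i2 <- if (c2) hi[[2]] else lo[[2]]
      i3 <- if (c3) hi[[3]] else lo[[3]]
      w1 <- if (c1) w[[1]] else 1 - w[[1]]
      w2 <- if (c2) w[[2]] else 1 - w[[2]]
      w3 <- if (c3) w[[3]] else 1 - w[[3]]
      wt <- outer(outer(w1, w2), w3)
      if (any(wt > 0)) acc <- acc + wt * arr[i1, i2, i3, drop = FALSE]
    }
    acc
  }
  dim(out) <- targetDim
  if (isVol || isMask) {
    sOut <- spacing(x) * d / targetDim
    oOut <- origin(x) + (sOut - spacing(x)) / 2
    if (isMask) voxelMask(array(as.integer(out), targetDim), sOut, oOut)
    else ctVolume(out, sOut, oOut)
  } else out
}

#' Mirror along the left-right axis
#'
#' Pure grid flip along axis 1 (the patient left-right axis), i.e. a
#' mirror about the field-of-view mid-plane -- not the anatomical
#' mid-sagittal plane. No interpolation is involved; spacing is
#' unchanged. Applied to right fibulae so a single network can be trained
#' on left-side anatomy only.
#'
#' @param x a [CTVolume-class], [VoxelMask-class] or 3D array.
#' @return same type, flipped along axis 1.
#' @export
mirrorLR <- function(x) {
  arr <- if (is(x, "ScanGrid")) voxels(x) else x
  out <- arr[dim(arr)[1]:1, , , drop = FALSE]
  if (is(x, "ScanGrid")) { x@voxels <- out; x } else out
}

#' Split a volume at the field-of-view mid-plane
#'
#' Splits along the left-right axis into a left half (upper indices,
#' since the axis increases toward patient left) and a right half (lower
#' indices). For an odd extent the left half takes the extra column. The
#' two halves partition the grid exactly and carry their own origins.
#'
#' @param x a [CTVolume-class], [VoxelMask-class] or 3D array.
#' @return `list(left = , right = )` of the same type as `x`.
#' @export
splitHalves <- function(x) {
  arr <- if (is(x, "ScanGrid")) voxels(x) else x
  n <- dim(arr)[1]
  if (n < 2) .fibsegError("fibseg_shape_error", "left-right axis must have length >= 2")
  nr <- n %/% 2                       # right half; left gets the remainder
  right <- arr[seq_len(nr), , , drop = FALSE]
  left <- arr[(nr + 1):n, , , drop = FALSE]
  if (is(x, "ScanGrid")) {
    sp <- spacing(x); og <- origin(x)
    mk <- is(x, "VoxelMask")
    list(
      left = .makeHalf(left, sp, og + c(nr * sp[1], 0, 0), mk),
      right = .makeHalf(right, sp, og, mk))
  } else list(left = left, right = right)
}

.makeHalf <- function(arr, sp, og, mask) {
  if (mask) voxelMask(arr, sp, og) else ctVolume(arr, sp, og)
}

#' Reassemble the two halves produced by [splitHalves()]
#'
#' @param left,right the two halves (same type, matching trailing dims).
#' @return the reassembled object.
#' @export
joinHalves <- function(left, right) {
  la <- if (is(left, "ScanGrid")) voxels(left) else left
  ra <- if (is(right, "ScanGrid")) voxels(right) else right
  d <- dim(la); d[1] <- d[1] + dim(ra)[1]
  out <- array(if (is.integer(la)) 0L else 0, d)
  out[seq_len(dim(ra)[1]), , ] <- ra
  out[(dim(ra)[1] + 1):d[1], , ] <- la
  if (is(right, "ScanGrid")) { right@voxels <- out; right } else out
}

#' Bounding box of a mask, with a physical margin
#'
#' The tightest axis-aligned box containing all foreground voxels,
#' expanded by `marginMm` (converted to voxels per axis, rounded up) and
#' clipped to the grid. An empty mask raises a catchable
#' `fibseg_empty_mask` error -- this is the failure surface of a
#' fragmented first-step prediction, which downstream code must be able
#' to intercept rather than crash on.
#'
#' @param mask a [VoxelMask-class] (or 0/1 array with `spacing` given).
#' @param marginMm isotropic margin in mm (default 0).
#' @param spacing used only when `mask` is a bare array.
#' @return a [BBox-class].
#' @export
maskBBox <- function(mask, marginMm = 0, spacing = c(1, 1, 1)) {
  arr <- if (is(mask, "ScanGrid")) voxels(mask) else mask
  if (is(mask, "ScanGrid")) spacing <- spacing(mask)
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    .fibsegError("fibseg_empty_mask", "cannot compute the bounding box of an empty mask")
  mv <- as.integer(ceiling(marginMm / spacing))
  d <- dim(arr)
  new("BBox",
      lo = pmax(1L, apply(idx, 2, min) - mv),
      hi = pmin(as.integer(d), apply(idx, 2, max) + mv),
      refDim = as.integer(d))
}

#' Crop a volume or mask to a bounding box
#'
#' @param x a [CTVolume-class], [VoxelMask-class] or 3D array.
#' @param bbox a [BBox-class] on the grid of `x`.
#' @return same type as `x`, restricted to the box (origin updated).
#' @export
cropGrid <- function(x, bbox) {
  arr <- if (is(x, "ScanGrid")) voxels(x) else x
  if (!identical(as.integer(dim(arr)), bbox@refDim))
    .fibsegError("fibseg_range_error", "bbox reference grid does not match the input grid")
  out <- arr[bbox@lo[1]:bbox@hi[1], bbox@lo[2]:bbox@hi[2],
             bbox@lo[3]:bbox@hi[3], drop = FALSE]
  if (is(x, "ScanGrid")) {
    og <- origin(x) + (bbox@lo - 1L) * spacing(x)
    if (is(x, "VoxelMask")) voxelMask(out, spacing(x), og)
    else ctVolume(out, spacing(x), og)
  } else out
}

#' Place a cropped mask back onto the full grid
#'
#' Writes the mask into a zero grid of `fullDim` at the position of
#' `bbox`; the inverse of [cropGrid()] for masks that lie inside the box.
#'
#' @param mask [VoxelMask-class] or 0/1 array with the extents of `bbox`.
#' @param bbox the [BBox-class] used for cropping.
#' @param fullDim integer(3) extents of the full grid.
#' @param spacing,origin geometry of the full grid (taken from `mask`'s
#'   crop geometry when omitted and `mask` is a [VoxelMask-class]).
#' @return a [VoxelMask-class] on the full grid.
#' @export
uncropMask <- function(mask, bbox, fullDim, spacing = NULL, origin = NULL) {
  arr <- if (is(mask, "ScanGrid")) voxels(mask) else mask
  fullDim <- as.integer(fullDim)
  if (!identical(as.integer(dim(arr)), bbox@hi - bbox@lo + 1L))
    .fibsegError("fibseg_range_error", "mask extents do not match the bounding box")
  if (!identical(bbox@refDim, fullDim))
    .fibsegError("fibseg_range_error", "bbox out of bounds for the stated full grid")
  out <- array(0L, fullDim)
  out[bbox@lo[1]:bbox@hi[1], bbox@lo[2]:bbox@hi[2], bbox@lo[3]:bbox@hi[3]] <- arr
  if (is.null(spacing)) {
    spacing <- if (is(mask, "ScanGrid")) spacing(mask) else c(1, 1, 1)
  }
  if (is.null(origin)) {
    origin <- if (is(mask, "ScanGrid"))
      origin(mask) - (bbox@lo - 1L) * spacing else c(0, 0, 0)
  }
  voxelMask(out, spacing, origin)
}
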