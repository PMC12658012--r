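# Evaluation metrics: Dice score, symmetric average surface distance,
# 95th-percentile Hausdorff distance on anisotropic grids, and the
# surgery-specific region-of-interest restriction (removal of the
# proximal and distal 7 cm of the fibula, the parts preserved
# intraoperatively for knee and ankle stability).

.checkSameGrid <- function(a, b) {
  if (!identical(dim(voxels(a)), dim(voxels(b))))
    .fibsegError("fibseg_grid_mismatch", "masks are on different grids")
  if (!isTRUE(all.equal(spacing(a), spacing(b))))
    .fibsegError("fibseg_grid_mismatch", "masks have different voxel spacing")
}

#' Dice score between two masks
#'
#' Volumetric overlap \eqn{DS = 2|A \cap B| / (|A| + |B|)}. Two empty
#' masks agree perfectly and score 1.
#'
#' @param a,b [VoxelMask-class]es on the same grid.
#' @return scalar in `[0, 1]`.
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[1:2, , ] <- 1L
#' diceScore(voxelMask(m), voxelMask(m))
#' @export
diceScore <- function(a, b) {
  .checkSameGrid(a, b)
  va <- voxels(a); vb <- voxels(b)
  sa <- sum(va); sb <- sum(vb)
  if (sa + sb == 0) return(1)
  2 * sum(va * vb) / (sa + sb)
}

#' Surface voxels of a mask, as physical points
#'
#' A foreground voxel belongs to the surface when at least one of its six
#' face neighbours is background; voxels on the grid border count the
#' outside as background. Returns the voxel centers in millimetres.
#'
#' @param mask a non-empty [VoxelMask-class].
#' @return n x 3 numeric matrix of points (mm).
#' @export
surfacePoints <- function(mask) {
  arr <- voxels(mask)
  if (sum(arr) == 0)
    .fibsegError("fibseg_empty_mask", "surface of an empty mask is undefined")
  d <- dim(arr)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1) { interior[] <- FALSE; break }
    up <- array(0L, d); dn <- array(0L, d)
    idx <- function(r) switch(ax,
      arr[r, , , drop = FALSE], arr[, r, , drop = FALSE], arr[, , r, drop = FALSE])
    asn <- function(tgt, r, val) {
      if (ax == 1) tgt[r, , ] <- val else if (ax == 2) tgt[, r, ] <- val
      else tgt[, , r] <- val
      tgt
    }
    up <- asn(up, 1:(n - 1), idx(2:n))        # neighbour at +1 (0 beyond border)
    dn <- asn(dn, 2:n, idx(1:(n - 1)))        # neighbour at -1
    interior <- interior & (up == 1) & (dn == 1)
  }
  surf <- arr == 1 & !interior
  idx <- which(surf, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing(mask), "*"), 2, origin(mask), "+")
}

# internal: pooled directed nearest-neighbour surface distances (mm)
.surfaceDistances <- function(a, b) {
  pa <- surfacePoints(a); pb <- surfacePoints(b)
  c(.nn_min_dists(pa, pb), .nn_min_dists(pb, pa))
}

#' Symmetric average surface distance (mm)
#'
#' Mean of all directed nearest-neighbour distances between the two
#' surfaces, pooled over both directions.
#'
#' @param a,b non-empty [VoxelMask-class]es on the same grid.
#' @return distance in mm (0 for identical masks).
#' @export
avgSurfaceDistance <- function(a, b) {
  .checkSameGrid(a, b)
  mean(.surfaceDistances(a, b))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' The 95th percentile (linear interpolation) of the pooled directed
#' nearest-neighbour surface distances; a robust variant of the maximum
#' surface deviation. `probs = 1` gives the classical Hausdorff distance.
#'
#' @param a,b non-empty [VoxelMask-class]es on the same grid.
#' @param probs percentile in `[0, 1]` (default 0.95).
#' @return distance in mm.
#' @export
hausdorff95 <- function(a, b, probs = 0.95) {
  .checkSameGrid(a, b)
  quantile(.surfaceDistances(a, b), probs, type = 7, names = FALSE)
}

#' Restrict evaluation to the transplantable region of interest
#'
#' In fibula free flap surgery the proximal and distal 6-7 cm of the
#' bone are preserved for knee and ankle stability, so evaluation focuses
#' on the central part. The axial window
#' `[zmin(gt) + cropMm, zmax(gt) - cropMm]` is computed once from the
#' ground-truth extent along the inferior-superior axis (in mm) and then
#' applied identically to both masks, zeroing everything outside.
#'
#' @param gt non-empty ground-truth [VoxelMask-class].
#' @param pred prediction [VoxelMask-class] on the same grid.
#' @param cropMm length removed from each end (default 70 mm).
#' @return `list(gt, pred, valid, window)`; `valid` is `FALSE` (with both
#'   masks emptied) when the ground-truth z-extent is `<= 2 * cropMm`.
#' @export
roiRestrict <- function(gt, pred, cropMm = 70) {
  .checkSameGrid(gt, pred)
  ga <- voxels(gt)
  if (sum(ga) == 0)
    .fibsegError("fibseg_empty_mask", "ROI window requires a non-empty ground truth")
  zIdx <- which(apply(ga, 3, sum) > 0)
  zmm <- origin(gt)[3] + (zIdx - 1) * spacing(gt)[3]
  zmin <- min(zmm); zmax <- max(zmm)
  if (zmax - zmin <= 2 * cropMm) {
    empty <- gt; empty@voxels <- array(0L, dim(ga))
    emptyP <- pred; emptyP@voxels <- array(0L, dim(ga))
    return(list(gt = empty, pred = emptyP, valid = FALSE,
                window = c(NA_real_, NA_real_)))
  }
  win <- c(zmin + cropMm, zmax - cropMm)
  allZ <- origin(gt)[3] + (seq_len(dim(ga)[3]) - 1) * spacing(gt)[3]
  keep <- allZ >= win[1] & allZ <= win[2]
  zero <- function(m) {
    v <- voxels(m); v[, , !keep] <- 0L; m@voxels <- v; m
  }
  list(gt = zero(gt), pred = zero(pred), valid = TRUE, window = win)
}

#' Evaluate a prediction against ground truth
#'
#' Computes the Dice score, average surface distance and 95th-percentile Hausdorff
#' distance on the whole bone and restricted to the transplant region of
#' interest ([roiRestrict()]). Surface distances of an empty mask are
#' undefined and flagged invalid (`NA`) rather than forced to a number.
#'
#' @param gt,pred [VoxelMask-class]es on the same grid (`gt` non-empty).
#' @param cropMm ROI crop from each end in mm (default 70).
#' @return one-row `data.frame` with columns `DS`, `ASD_mm`, `HD95_mm`,
#'   `ROI_DS`, `ROI_ASD_mm`, `ROI_HD95_mm`, `surface_valid`, `roi_valid`.
#' @export
evaluatePair <- function(gt, pred, cropMm = 70) {
  .checkSameGrid(gt, pred)
  ds <- diceScore(gt, pred)
  surfValid <- sum(voxels(gt)) > 0 && sum(voxels(pred)) > 0
  asd <- if (surfValid) avgSurfaceDistance(gt, pred) else NA_real_
  hd <- if (surfValid) hausdorff95(gt, pred) else NA_real_
  roi <- roiRestrict(gt, pred, cropMm)
  if (roi$valid) {
    rds <- diceScore(roi$gt, roi$pred)
    rValid <- sum(voxels(roi$gt)) > 0 && sum(voxels(roi$pred)) > 0
    rasd <- if (rValid) avgSurfaceDistance(roi$gt, roi$pred) else NA_real_
    rhd <- if (rValid) hausdorff95(roi$gt, roi$pred) else NA_real_
  } else {
    rds <- NA_real_; rasd <- NA_real_; rhd <- NA_real_
  }
  data.frame(DS = ds, ASD_mm = asd, HD95_mm = hd,
             ROI_DS = rds, ROI_ASD_mm = rasd, ROI_HD95_mm = rhd,
             surface_valid = surfValid, roi_valid = roi$valid)
}
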