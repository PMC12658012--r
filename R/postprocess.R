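# From probability volumes to clean masks and surgical-quality meshes:
# binarize -> connected-component filtering -> binary erosion -> Gaussian
# smoothing -> iso-surface extraction -> left/right labeling.

#' Binarize a probability volume
#'
#' Voxel is foreground iff probability >= `threshold`.
#'
#' @param prob a [CTVolume-class] of probabilities or a 3D array.
#' @param threshold decision threshold (default 0.5).
#' @return a [VoxelMask-class] (array in, array out).
#' @export
binarizeProb <- function(prob, threshold = 0.5) {
  isVol <- is(prob, "CTVolume")
  arr <- if (isVol) voxels(prob) else prob
  out <- array(as.integer(arr >= threshold), dim(arr))
  if (isVol) voxelMask(out, spacing(prob), origin(prob)) else out
}

# internal: 1D min filter along an axis with zero (background) padding
.shiftMin <- function(arr, ax) {
  n <- dim(arr)[ax]
  if (n == 1) return(array(0L, dim(arr)))   # border counts as background
  pick <- function(r) switch(ax,
    arr[r, , , drop = FALSE], arr[, r, , drop = FALSE], arr[, , r, drop = FALSE])
  pad <- function(r, side) {
    out <- array(0L, dim(arr))
    if (ax == 1) out[r, , ] <- pick(side) else if (ax == 2) out[, r, ] <- pick(side)
    else out[, , r] <- pick(side)
    out
  }
  up <- pad(1:(n - 1), 2:n)
  dn <- pad(2:n, 1:(n - 1))
  pmin(arr, up, dn)
}

#' Binary erosion with a 3x3x3 box element
#'
#' Standard morphological erosion (separable min filter); voxels beyond
#' the grid border count as background, so the mask also shrinks at the
#' image edge. The first post-processing step applied to network output.
#'
#' @param mask a [VoxelMask-class] or 0/1 array.
#' @param iterations number of erosion passes (default 1).
#' @return same type as `mask`.
#' @export
erodeMask <- function(mask, iterations = 1L) {
  isMask <- is(mask, "VoxelMask")
  arr <- if (isMask) voxels(mask) else mask
  for (it in seq_len(iterations))
    for (ax in 1:3) arr <- .shiftMin(arr, ax)
  if (isMask) { mask@voxels <- arr; mask } else arr
}

#' Gaussian smoothing of a mask
#'
#' Separable Gaussian filter (zero padding) producing a smooth scalar
#' field in `[0, 1]` from which the iso-surface is extracted. The
#' bandwidth is anisotropy-aware: `sigmaMm` is converted to voxels per
#' axis using the spacing; alternatively `sigmaVox` fixes it in voxels.
#' With a zero sigma the field equals the mask.
#'
#' @param mask a [VoxelMask-class] (or 0/1 array with `spacing`).
#' @param sigmaMm Gaussian sigma in mm (scalar).
#' @param sigmaVox Gaussian sigma in voxels (used when `sigmaMm` is
#'   `NULL`; default 1 voxel per axis).
#' @param spacing used when `mask` is a bare array.
#' @return a [CTVolume-class] scalar field (array in, array out).
#' @export
smoothMask <- function(mask, sigmaMm = NULL, sigmaVox = 1,
                       spacing = c(1, 1, 1)) {
  isMask <- is(mask, "ScanGrid")
  arr <- if (isMask) voxels(mask) else mask
  if (isMask) spacing <- spacing(mask)
  sig <- if (!is.null(sigmaMm)) sigmaMm / spacing else rep(sigmaVox, 3)
  out <- arr * 1.0
  d <- dim(arr)
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    r <- max(1L, ceiling(3 * sig[ax]))
    kern <- dnorm(-r:r, 0, sig[ax]); kern <- kern / sum(kern)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in -r:r) {
      rows <- seq_len(n); cols <- rows + o
      ok <- cols >= 1 & cols <= n
      K[cbind(rows[ok], cols[ok])] <- kern[o + r + 1]
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(out, perm); dm <- dim(m)
    m <- K %*% matrix(m, nrow = n)
    dim(m) <- dm
    out <- aperm(m, order(perm))
  }
  if (isMask) ctVolume(out, spacing, origin(mask)) else out
}

#' Extract an iso-surface mesh from a scalar field
#'
#' Converts the (smoothed) field to a triangle mesh at `isoLevel`,
#' marching over the tetrahedral (Freudenthal) decomposition of each
#' grid cell -- a variant of the classic cube-marching iso-surface
#' algorithm without ambiguous cases, watertight by construction.
#' Vertices are emitted in physical millimetres (spacing and origin
#' applied); triangle normals point out of the `>= isoLevel` region.
#'
#' @param field a [CTVolume-class] scalar field (or array with
#'   `spacing` / `origin`).
#' @param isoLevel iso value (default 0.5).
#' @param spacing,origin used when `field` is a bare array.
#' @return a [SurfaceMesh-class].
#' @export
extractMesh <- function(field, isoLevel = 0.5, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  isVol <- is(field, "ScanGrid")
  arr <- if (isVol) voxels(field) else field
  if (isVol) { spacing <- spacing(field); origin <- origin(field) }
  if (all(arr < isoLevel) || all(arr >= isoLevel))
    .fibsegError("fibseg_empty_surface",
                 "the field does not cross the iso level: no surface to extract")
  res <- .march_tets(as.numeric(arr), as.integer(dim(arr)), isoLevel,
                     as.numeric(spacing), as.numeric(origin))
  surfaceMesh(res$vertices, res$faces)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedra (divergence theorem) volume; returned as an
#' absolute value in cubic millimetres.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return volume in cubic mm.
#' @export
meshVolume <- function(mesh) {
  V <- vertices(mesh); Fc <- faces(mesh)
  if (nrow(Fc) == 0) return(0)
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  cc <- V[Fc[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
         a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
         a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det)) / 6
}

#' Connected components of a mask
#'
#' 26-connected component labelling.
#'
#' @param mask a [VoxelMask-class] or 0/1 array.
#' @return list with `labels` (integer array, 0 = background) and
#'   `sizes` (voxel count per component, in label order).
#' @export
connectedComponents <- function(mask) {
  arr <- if (is(mask, "ScanGrid")) voxels(mask) else mask
  lab <- .cc_label26(as.integer(arr), as.integer(dim(arr)))
  n <- attr(lab, "n")
  labels <- array(as.integer(lab), dim(arr))
  sizes <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer(0)
  list(labels = labels, sizes = sizes)
}

#' Keep the k largest connected components
#'
#' Components are sized by voxel count (masks) or enclosed volume
#' (meshes) and returned in descending size order; ties are broken
#' stably by the centroid's left-right coordinate (ascending). The
#' working assumption of the bilateral pipeline -- that the two largest
#' components are the two fibulae -- fails when a bone is predicted as
#' fragments; when fewer than `k` qualifying components exist the result
#' carries `shortfall = TRUE` instead of being silently padded.
#' Components smaller than `minFrac` times the largest are treated as
#' debris and not considered candidates.
#'
#' @param x a [VoxelMask-class], 0/1 array, or list of
#'   [SurfaceMesh-class].
#' @param k number of components wanted (default 2: the two fibulae).
#' @param minFrac minimum size relative to the largest component for a
#'   component to qualify (default 0: keep all).
#' @return list with `components` (list of [VoxelMask-class] or meshes,
#'   largest first), `sizes`, and `shortfall` flag.
#' @export
keepLargestComponents <- function(x, k = 2L, minFrac = 0) {
  if (k < 1) .fibsegError("fibseg_param_error", "k must be >= 1")
  if (is.list(x) && !is(x, "ScanGrid")) {           # meshes
    sizes <- vapply(x, meshVolume, 0)
    cx <- vapply(x, function(m) mean(vertices(m)[, 1]), 0)
    ord <- order(-sizes, cx)
    keep <- ord[sizes[ord] >= minFrac * max(sizes, 0)]
    keep <- head(keep, k)
    return(list(components = x[keep], sizes = sizes[keep],
                shortfall = length(keep) < k))
  }
  cc <- connectedComponents(x)
  if (length(cc$sizes) == 0)
    return(list(components = list(), sizes = integer(0), shortfall = TRUE))
  sp <- if (is(x, "ScanGrid")) spacing(x) else c(1, 1, 1)
  og <- if (is(x, "ScanGrid")) origin(x) else c(0, 0, 0)
  cx <- vapply(seq_along(cc$sizes), function(l) {
    mean(which(cc$labels == l, arr.ind = TRUE)[, 1])
  }, 0)
  ord <- order(-cc$sizes, cx)
  qualifying <- ord[cc$sizes[ord] >= minFrac * max(cc$sizes)]
  keep <- head(qualifying, k)
  comps <- lapply(keep, function(l)
    voxelMask(array(as.integer(cc$labels == l), dim(cc$labels)), sp, og))
  list(components = comps, sizes = cc$sizes[keep],
       shortfall = length(keep) < k)
}

# internal: centroid along the left-right axis, in mm
.centroidLR <- function(comp) {
  if (is(comp, "SurfaceMesh")) return(mean(vertices(comp)[, 1]))
  arr <- voxels(comp)
  idx <- which(arr == 1, arr.ind = TRUE)
  origin(comp)[1] + (mean(idx[, 1]) - 1) * spacing(comp)[1]
}

#' Label two components as left and right fibula
#'
#' Under the package axis convention (grid axis 1 increases toward the
#' patient's left), the component with the greater left-right centroid
#' coordinate is the left fibula. Deterministic and independent of input
#' order; exactly equal centroids are ambiguous and raise an error.
#'
#' @param components list of two [VoxelMask-class] or
#'   [SurfaceMesh-class] objects.
#' @return `list(left = , right = )`.
#' @export
labelLeftRight <- function(components) {
  if (length(components) != 2)
    .fibsegError("fibseg_param_error", "exactly two components are required")
  cx <- vapply(components, .centroidLR, 0)
  if (cx[1] == cx[2])
    .fibsegError("fibseg_label_error",
                 "components have identical left-right centroids: labeling is ambiguous")
  list(left = components[[which.max(cx)]], right = components[[which.min(cx)]])
}

#' Post-process a predicted mask into a surface mesh
#'
#' The mesh-generation chain applied to each segmented fibula: largest
#' connected component, binary erosion, Gaussian smoothing, iso-surface
#' extraction.
#'
#' @param mask a [VoxelMask-class] (a single bone's prediction).
#' @param erodeIterations erosion passes (default 1).
#' @param sigmaVox Gaussian sigma in voxels (default 1).
#' @param isoLevel iso value for surface extraction (default 0.5).
#' @return a [SurfaceMesh-class], or `NULL` when the eroded+smoothed
#'   field no longer crosses the iso level (tiny fragments).
#' @export
postprocessMask <- function(mask, erodeIterations = 1L, sigmaVox = 1,
                            isoLevel = 0.5) {
  kept <- keepLargestComponents(mask, k = 1L)
  if (length(kept$components) == 0) return(NULL)
  m <- erodeMask(kept$components[[1]], erodeIterations)
  field <- smoothMask(m, sigmaVox = sigmaVox)
  tryCatch(extractMesh(field, isoLevel),
           fibseg_empty_surface = function(e) NULL)
}
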