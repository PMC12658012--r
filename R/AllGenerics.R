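# Generics and accessors for the core classes.

#' Access the voxel array of a volume or mask
#' @param x a [CTVolume-class] or [VoxelMask-class].
#' @return the underlying 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing in millimetres
#' @param x an object with a scan grid.
#' @return numeric(3), mm per voxel along each grid axis.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin (center of voxel 1,1,1) in millimetres
#' @param x an object with a scan grid.
#' @return numeric(3), mm.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Grid extents in voxels
#' @param x an object with a scan grid.
#' @return integer(3).
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Vertices of a surface mesh
#' @param x a [SurfaceMesh-class].
#' @return n x 3 numeric matrix (mm).
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Faces of a surface mesh
#' @param x a [SurfaceMesh-class].
#' @return m x 3 integer matrix of 1-based vertex indices.
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname voxels
#' @export
setMethod("voxels", "ScanGrid", function(x) x@voxels)
#' @rdname spacing
#' @export
setMethod("spacing", "ScanGrid", function(x) x@spacing)
#' @rdname origin
#' @export
setMethod("origin", "ScanGrid", function(x) x@origin)
#' @rdname gridDim
#' @export
setMethod("gridDim", "ScanGrid", function(x) dim(x@voxels))
#' @rdname vertices
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname faces
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f], origin (%g, %g, %g) mm\n",
              min(object@voxels), max(object@voxels),
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelMask %d x %d x %d voxels, %d foreground (%.2f%%), spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], sum(object@voxels),
              100 * mean(object@voxels),
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "BBox", function(object) {
  cat(sprintf("BBox [%d, %d] x [%d, %d] x [%d, %d] on a %d x %d x %d grid\n",
              object@lo[1], object@hi[1], object@lo[2], object@hi[2],
              object@lo[3], object@hi[3],
              object@refDim[1], object@refDim[2], object@refDim[3]))
})

setMethod("show", "UNetSpec", function(object) {
  plan <- unetLayers(object)
  cat(sprintf("UNetSpec: depth %d, base %d channels; %d encoder convs, %d pools, deepest %d feature maps\n",
              object@depth, object@baseChannels,
              sum(plan$path == "encoder"), object@depth, max(plan$cout)))
})

setMethod("show", "UNetWeights", function(object) {
  np <- sum(vapply(object@params, function(p) length(p$W) + length(p$b), 0))
  pv <- object@provenance
  cat(sprintf("UNetWeights: %d layers, %d parameters (stage: %s, seed: %s, epochs: %s)\n",
              length(object@params), np,
              if (is.null(pv$stage)) "untrained" else pv$stage,
              if (is.null(pv$seed)) "NA" else pv$seed,
              if (is.null(pv$epochs)) "0" else pv$epochs))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: left %s, right %s\n",
              object@status["left"], object@status["right"]))
})

setMethod("show", "PhantomCase", function(object) {
  d <- gridDim(object@image)
  cat(sprintf("PhantomCase %d x %d x %d: left fibula %d voxels, right fibula %d voxels\n",
              d[1], d[2], d[3], sum(voxels(object@leftFibula)),
              sum(voxels(object@rightFibula))))
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric(3), mm per voxel.
#' @param origin numeric(3), mm position of the center of voxel (1,1,1).
#' @return a validated [CTVolume-class].
#' @examples
#' v <- ctVolume(array(0, c(8, 8, 8)), spacing = c(1, 1, 2))
#' spacing(v)
#' @export
ctVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisTag = "LR-AP-IS")
}

#' Construct a VoxelMask
#'
#' @param voxels 3D array of 0/1 (logical arrays are converted).
#' @param spacing,origin grid geometry, as in [ctVolume()].
#' @return a validated [VoxelMask-class].
#' @export
voxelMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  new("VoxelMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), axisTag = "LR-AP-IS")
}

#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return a validated [SurfaceMesh-class].
#' @export
surfaceMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces)
}

# internal: mask/volume with same geometry as a template grid object
.likeGrid <- function(template, voxels, mask = FALSE) {
  if (mask) voxelMask(voxels, spacing(template), origin(template))
  else ctVolume(voxels, spacing(template), origin(template))
}

# internal: condition constructors for catchable error classes
.fibsegError <- function(class, msg, call = sys.call(-1)) {
  stop(structure(class = c(class, "fibsegError", "error", "condition"),
                 list(message = msg, call = call)))
}
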