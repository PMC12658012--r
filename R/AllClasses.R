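# Central S4 classes. Grid axis convention (fixed, validated, and relied on
# throughout): axis 1 is the patient left-right axis with the index
# increasing toward the patient's LEFT; axis 2 is anterior-posterior;
# axis 3 is inferior -> superior. All physical quantities are millimetres.

.AXIS_TAGS <- c("LR-AP-IS")

#' @rdname CTVolume-class
#' @export
setClass("ScanGrid",
  representation("VIRTUAL",
    spacing = "numeric",
    origin = "numeric",
    axisTag = "character"))

setValidity("ScanGrid", function(object) {
  msgs <- character()
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be three strictly positive values (mm)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be three finite values (mm)")
  if (length(object@axisTag) != 1 || !(object@axisTag %in% .AXIS_TAGS))
    msgs <- c(msgs, sprintf("axisTag must be one of: %s",
                            paste(.AXIS_TAGS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' CTVolume: a 3D scalar image with voxel spacing
#'
#' A 3D scalar grid (Hounsfield units, or normalized intensity after
#' [normalizeHU()]) together with per-axis voxel spacing and the physical
#' position of the center of voxel (1,1,1). Grid axis 1 is the patient
#' left-right axis (index increasing toward patient left), axis 3 is
#' inferior to superior.
#'
#' @slot voxels 3D numeric array.
#' @slot spacing numeric(3), mm per voxel along each grid axis.
#' @slot origin numeric(3), mm position of the center of voxel (1,1,1).
#' @slot axisTag declared axis convention; currently only `"LR-AP-IS"`.
#' @seealso [ctVolume()], [VoxelMask-class]
#' @export
setClass("CTVolume", contains = "ScanGrid",
  representation(voxels = "array"))

setValidity("CTVolume", function(object) {
  if (length(dim(object@voxels)) != 3)
    "voxels must be a rank-3 array" else TRUE
})

#' VoxelMask: a binary grid aligned to a CTVolume
#'
#' Binary (0/1) voxel grid sharing the geometry of its parent volume.
#' Holds ground-truth segmentations, network targets and predictions.
#'
#' @slot voxels 3D array with values in \{0, 1\}.
#' @slot spacing,origin,axisTag as in [CTVolume-class].
#' @seealso [voxelMask()], [diceScore()]
#' @export
setClass("VoxelMask", contains = "ScanGrid",
  representation(voxels = "array"))

setValidity("VoxelMask", function(object) {
  if (length(dim(object@voxels)) != 3)
    return("voxels must be a rank-3 array")
  v <- object@voxels
  if (!all(v == 0 | v == 1))
    return("mask values must all be 0 or 1")
  TRUE
})

#' SurfaceMesh: a triangle mesh in physical coordinates
#'
#' Triangle mesh with vertices in millimetres, the deliverable
#' representation of a segmented fibula for surgical planning, produced by
#' [extractMesh()] and serialized as binary STL by [writeMesh()].
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
  V <- object@vertices; Fc <- object@faces
  if (ncol(V) != 3) return("vertices must have three columns")
  if (nrow(Fc) > 0) {
    if (ncol(Fc) != 3) return("faces must have three columns")
    if (any(Fc < 1) || any(Fc > nrow(V)))
      return("face indices out of vertex range")
    if (any(Fc[, 1] == Fc[, 2] | Fc[, 1] == Fc[, 3] | Fc[, 2] == Fc[, 3]))
      return("degenerate faces: each face needs three distinct vertices")
  }
  TRUE
})

#' BBox: an axis-aligned voxel bounding box
#'
#' Inclusive 1-based voxel index ranges per axis on a stated reference
#' grid. Produced by [maskBBox()], consumed by [cropGrid()] and
#' [uncropMask()].
#'
#' @slot lo,hi integer(3), inclusive 1-based index range per axis.
#' @slot refDim integer(3), extents of the reference grid.
#' @export
setClass("BBox",
  representation(lo = "integer", hi = "integer", refDim = "integer"))

setValidity("BBox", function(object) {
  if (any(object@lo > object@hi)) return("lo must be <= hi per axis")
  if (any(object@lo < 1L) || any(object@hi > object@refDim))
    return("bounding box exceeds reference grid bounds")
  TRUE
})

#' UNetSpec: parameterization of the 3D U-Net
#'
#' Architecture family used by both pipeline stages: an encoder of
#' `2*depth + 2` convolutional layers (3x3x3 kernels, same padding, ReLU)
#' with `depth` 2x2x2 max-pooling steps, doubling the feature maps at
#' every pooling step, a mirrored decoder whose upsampling layers repeat
#' elements by a factor of 2 per axis, skip connections by channel
#' concatenation, and a sigmoid output. The default
#' `unetSpec(depth = 4, baseChannels = 16)` is the full-size network
#' (10 encoder convolutions, deepest layer 512 feature maps); smaller
#' values give proportionally reduced networks for desk-scale
#' experiments. The architecture is fully convolutional and therefore
#' resolution-agnostic: any input whose axes are divisible by
#' `2^depth` is accepted.
#'
#' @slot depth number of pooling steps.
#' @slot baseChannels feature maps after the first convolution.
#' @slot inChannels input channels (1 for CT).
#' @slot norm per-convolution normalization: `"none"` or `"instance"`.
#' @seealso [unetSpec()], [buildUNet()], [unetForward()]
#' @export
setClass("UNetSpec",
  representation(depth = "integer", baseChannels = "integer",
                 inChannels = "integer", norm = "character"),
  prototype(norm = "none"))

setValidity("UNetSpec", function(object) {
  if (object@depth < 1L) return("depth must be >= 1")
  if (length(object@norm) != 1 || !(object@norm %in% c("none", "instance")))
    return("norm must be 'none' or 'instance'")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  if (object@inChannels < 1L) return("inChannels must be >= 1")
  TRUE
})

#' UNetWeights: trained or initialized network parameters
#'
#' Ordered list of per-layer parameters (kernel matrix `W`, laid out as
#' `(27 * cin) x cout`, bias `b`, and — when the architecture uses instance
#' normalization — scale `g` and shift `be`) together with the generating
#' [UNetSpec-class] and a provenance record (stage, seed, epochs, source
#' of transfer-learned initialization).
#'
#' @slot spec the [UNetSpec-class] the parameters belong to.
#' @slot params named list of `list(W, b)` per convolution layer.
#' @slot provenance free-form list (stage, seed, epochs, transferredFrom).
#' @export
setClass("UNetWeights",
  representation(spec = "UNetSpec", params = "list", provenance = "list"))

#' PhantomParams: geometry and intensity of the synthetic CT phantom
#'
#' Parameters of the seeded lower-limb phantom: grid, two legs on opposite
#' sides of the field-of-view mid-plane, per leg a thick tibia-like
#' cylinder and a thin, laterally bowed fibula-like tube with enlarged
#' proximal and distal bulges, Hounsfield levels for air / soft tissue /
#' trabecular / cortical bone, and additive Gaussian noise. Defaults are
#' the package's study conditions for desk-scale experiments:
#' 64 x 64 x 160 voxels at (2, 2, 2.5) mm, proportioned like a
#' lower-extremity scan.
#'
#' @slot gridDim integer(3) voxel grid extents.
#' @slot spacing numeric(3) mm.
#' @slot legOffsetMm lateral distance of each leg axis from the mid-plane.
#' @slot fibulaRadiusMm shaft radius of the fibula tube.
#' @slot bulgeRadiusMm radius at the proximal/distal bulges.
#' @slot bulgeFrac fraction of bone length occupied by each bulge ramp.
#' @slot bowMm amplitude of the lateral bow of the fibula centerline.
#' @slot tibiaRadiusMm radius of the tibia cylinder.
#' @slot fibulaOffsetMm numeric(2): (lateral, anterior) offset of the
#'   fibula centerline from the leg axis.
#' @slot boneLengthFrac fibula length as a fraction of the z field of view.
#' @slot huAir,huSoft,huTrabecular,huCortical Hounsfield levels.
#' @slot noiseSd additive Gaussian noise (HU) before clipping.
#' @slot fractureGapsLeft,fractureGapsRight numeric vectors of z positions
#'   (mm, relative to the bone's inferior end) where a fracture gap
#'   interrupts the fibula; used to build fragmented fixtures.
#' @slot fractureWidthMm axial width of each fracture gap.
#' @slot seed RNG seed for the noise.
#' @seealso [phantomParams()], [generatePhantom()]
#' @export
setClass("PhantomParams",
  representation(
    gridDim = "integer", spacing = "numeric",
    legOffsetMm = "numeric", fibulaRadiusMm = "numeric",
    bulgeRadiusMm = "numeric", bulgeFrac = "numeric", bowMm = "numeric",
    tibiaRadiusMm = "numeric", fibulaOffsetMm = "numeric",
    boneLengthFrac = "numeric",
    huAir = "numeric", huSoft = "numeric", huTrabecular = "numeric",
    huCortical = "numeric", noiseSd = "numeric",
    fractureGapsLeft = "numeric", fractureGapsRight = "numeric",
    fractureWidthMm = "numeric", seed = "integer"))

setValidity("PhantomParams", function(object) {
  msgs <- character()
  if (object@fibulaRadiusMm >= object@tibiaRadiusMm)
    msgs <- c(msgs, "fibulaRadiusMm must be smaller than tibiaRadiusMm")
  if (object@legOffsetMm <= 0)
    msgs <- c(msgs, "legOffsetMm must be > 0 (legs on opposite sides of the mid-plane)")
  hu <- c(object@huAir, object@huSoft, object@huTrabecular, object@huCortical)
  if (any(hu < -1024) || any(hu > 3071))
    msgs <- c(msgs, "HU levels must lie within [-1024, 3071]")
  fov <- object@gridDim * object@spacing
  if (object@legOffsetMm + object@fibulaOffsetMm[1] +
      object@bulgeRadiusMm + object@bowMm > fov[1] / 2)
    msgs <- c(msgs, "grid too small to contain both legs at the stated radii")
  if (object@legOffsetMm - object@tibiaRadiusMm <= 0)
    msgs <- c(msgs, "tibia crosses the mid-plane: grid too small or legOffsetMm too low")
  if (length(msgs)) msgs else TRUE
})

#' PhantomCase: one synthetic CT with fibula ground truth
#'
#' @slot image [CTVolume-class] in Hounsfield units.
#' @slot leftFibula,rightFibula ground-truth [VoxelMask-class]es.
#' @slot params the generating [PhantomParams-class].
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomCase",
  representation(image = "CTVolume", leftFibula = "VoxelMask",
                 rightFibula = "VoxelMask", params = "PhantomParams"))

#' SegmentationResult: output of an end-to-end pipeline run
#'
#' Per-side full-grid masks and surface meshes plus machine-readable
#' status flags. A side is `"ok"` when it was produced normally,
#' `"shortfall"` when the first-step component filter found fewer
#' candidate bones than expected (the known bilateral failure mode), and
#' `"empty"` when the first step produced no foreground for that side.
#'
#' @slot leftMask,rightMask [VoxelMask-class] on the original CT grid, or
#'   `NULL` for a failed side.
#' @slot leftMesh,rightMesh [SurfaceMesh-class] or `NULL`.
#' @slot status named character(2): flags for `left` and `right`.
#' @slot log list of per-stage notes and timings.
#' @export
setClass("SegmentationResult",
  representation(leftMask = "ANY", rightMask = "ANY",
                 leftMesh = "ANY", rightMesh = "ANY",
                 status = "character", log = "list"))

setValidity("SegmentationResult", function(object) {
  if (!identical(sort(names(object@status)), c("left", "right")))
    return("status must be named 'left' and 'right'")
  if (!all(object@status %in% c("ok", "shortfall", "empty")))
    return("status values must be ok / shortfall / empty")
  TRUE
})
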