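# I/O: NIfTI-1 volumes and masks, binary STL meshes, CSV cohort
# manifests, and manifest eligibility filtering / splitting.

#' Read a volumetric image from NIfTI
#'
#' Reads a NIfTI-1 file into a [CTVolume-class]; spacing is taken from
#' the header's pixel dimensions and the origin from the qform/sform
#' translation. The grid must be rank 3 and is assumed to already follow
#' the package axis convention (axis 1 left-right toward patient left,
#' axis 3 inferior-superior).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a [CTVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    .fibsegError("fibseg_io_error", sprintf("file does not exist: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    .fibsegError("fibseg_format_error",
                 sprintf("not a readable NIfTI file: %s (%s)", path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) != 3)
    .fibsegError("fibseg_shape_error",
                 sprintf("expected a rank-3 volume, got rank %d: %s", length(d), path))
  xf <- RNifti::xform(img)
  ctVolume(array(as.numeric(img), d),
           spacing = RNifti::pixdim(img)[1:3],
           origin = as.numeric(xf[1:3, 4]))
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [CTVolume-class] or [VoxelMask-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  arr <- voxels(x)
  storage.mode(arr) <- "double"
  attr(arr, "pixdim") <- spacing(x)
  img <- RNifti::asNifti(arr)
  m <- diag(c(spacing(x), 1)); m[1:3, 4] <- origin(x)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' As [readVolume()], additionally checking that all values are 0 or 1.
#'
#' @param path path to the mask file.
#' @return a [VoxelMask-class].
#' @export
readMask <- function(path) {
  v <- readVolume(path)
  arr <- voxels(v)
  if (!all(arr %in% c(0, 1)))
    .fibsegError("fibseg_format_error",
                 sprintf("mask file contains values other than 0/1: %s", path))
  voxelMask(array(as.integer(arr), dim(arr)), spacing(v), origin(v))
}

#' @rdname writeVolume
#' @export
writeMask <- function(x, path) writeVolume(x, path)

#' Write a surface mesh as binary STL
#'
#' Binary STL stores one float32 vertex triple per triangle corner; an
#' empty mesh is written as a valid zero-triangle file with a warning.
#' Coordinates round-trip at float32 precision (about 1e-7 relative).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output `.stl` path.
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path) {
  V <- vertices(mesh); Fc <- faces(mesh)
  if (nrow(Fc) == 0)
    warning("writing an empty mesh (zero triangles) to ", path)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("fibseg binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(Fc)), con, size = 4, endian = "little")
  if (nrow(Fc) > 0) {
    tri <- cbind(V[Fc[, 1], , drop = FALSE], V[Fc[, 2], , drop = FALSE],
                 V[Fc[, 3], , drop = FALSE])
    # facet normal (unnormalized cross product; readers recompute anyway)
    u <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
    w <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
    nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    rec <- t(cbind(nrm, tri))           # 12 floats per triangle
    fbytes <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
    out <- raw(50 * nrow(Fc))           # 48 float bytes + 2 attribute bytes
    pos <- rep((seq_len(nrow(Fc)) - 1) * 50, each = 48) + seq_len(48)
    out[pos] <- fbytes
    writeBin(out, con)
  }
  invisible(path)
}

#' Read a binary STL mesh
#'
#' Rebuilds an indexed [SurfaceMesh-class] by merging bitwise-identical
#' vertices. ASCII or truncated/corrupt STL raises a format error.
#'
#' @param path path to a binary `.stl` file.
#' @return a [SurfaceMesh-class].
#' @export
readMesh <- function(path) {
  if (!file.exists(path))
    .fibsegError("fibseg_io_error", sprintf("file does not exist: %s", path))
  sz <- file.size(path)
  if (sz < 84)
    .fibsegError("fibseg_format_error", "file too small to be a binary STL")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  if (identical(rawToChar(header[1:5]), "solid") && (sz - 84) %% 50 != 0)
    .fibsegError("fibseg_format_error", "ASCII STL is not supported")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (sz != 84 + 50 * n)
    .fibsegError("fibseg_format_error",
                 sprintf("corrupt STL: %d triangles declared but file size is %d bytes", n, sz))
  if (n == 0) {
    return(surfaceMesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  raw <- readBin(con, "raw", 50 * n)
  # 12 float32 + uint16 per record; gather the 9 vertex floats
  recIdx <- rep(seq_len(n) - 1, each = 36)
  off <- rep(12 + seq_len(36) - 1, times = n)   # skip the 12 normal bytes
  vbytes <- raw[recIdx * 50 + off + 1]
  coords <- readBin(vbytes, "numeric", 9 * n, size = 4, endian = "little")
  pts <- matrix(coords, ncol = 3, byrow = TRUE)  # 3n points
  key <- apply(format(pts, digits = 17), 1, paste, collapse = "/")
  uid <- match(key, unique(key))
  V <- pts[!duplicated(uid), , drop = FALSE]
  Fc <- matrix(uid, ncol = 3, byrow = TRUE)
  keep <- Fc[, 1] != Fc[, 2] & Fc[, 1] != Fc[, 3] & Fc[, 2] != Fc[, 3]
  surfaceMesh(V, Fc[keep, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Cohort manifests

.MANIFEST_COLS <- c("case_id", "image", "left_mask", "right_mask", "split")

#' Read / write a cohort manifest
#'
#' The manifest is a CSV (UTF-8, header) with columns `case_id`, `image`,
#' `left_mask`, `right_mask`, `split`; empty mask paths mean that side
#' has no ground truth. An eligibility-filtered, per-fibula manifest
#' additionally carries `side` and `source_case` columns.
#'
#' @param path CSV path.
#' @return a `data.frame` manifest.
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    .fibsegError("fibseg_io_error", sprintf("manifest does not exist: %s", path))
  m <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.MANIFEST_COLS, names(m))
  if (length(missing))
    .fibsegError("fibseg_format_error",
                 sprintf("manifest lacks columns: %s", paste(missing, collapse = ", ")))
  for (cc in c("left_mask", "right_mask")) m[[cc]][m[[cc]] == ""] <- NA_character_
  .checkManifest(m)
  m
}

#' @rdname readManifest
#' @param manifest the manifest `data.frame` to write.
#' @export
writeManifest <- function(manifest, path) {
  .checkManifest(manifest)
  write.csv(manifest, path, row.names = FALSE, na = "")
  invisible(path)
}

.checkManifest <- function(m) {
  if (anyDuplicated(m$case_id))
    .fibsegError("fibseg_format_error", "manifest case_ids must be unique")
  noMask <- is.na(m$left_mask) & is.na(m$right_mask)
  if (any(noMask))
    .fibsegError("fibseg_format_error",
                 sprintf("records without any mask: %s",
                         paste(m$case_id[noMask], collapse = ", ")))
  invisible(TRUE)
}

#' Filter a manifest for approach-specific training eligibility
#'
#' The bilateral first step segments both fibulae jointly and can only be
#' trained on cases where both sides have ground truth
#' (`"bilateral_step1"`). The unilateral first step and the shared second
#' step train on individual fibulae, so every available side becomes its
#' own sample (`"unilateral_step1"`, `"step2"`): the returned manifest
#' has one record per fibula with `side` and `source_case` columns.
#'
#' @param manifest a manifest `data.frame` (see [readManifest()]).
#' @param approachStage `"bilateral_step1"`, `"unilateral_step1"` or `"step2"`.
#' @return the filtered (possibly per-fibula) manifest.
#' @export
filterEligible <- function(manifest,
                           approachStage = c("bilateral_step1",
                                             "unilateral_step1", "step2")) {
  approachStage <- match.arg(approachStage)
  if (approachStage == "bilateral_step1") {
    out <- manifest[!is.na(manifest$left_mask) & !is.na(manifest$right_mask), ,
                    drop = FALSE]
  } else {
    rows <- list()
    for (side in c("left", "right")) {
      col <- paste0(side, "_mask")
      sub <- manifest[!is.na(manifest[[col]]), , drop = FALSE]
      if (nrow(sub)) {
        sub$side <- side
        sub$source_case <- sub$case_id
        sub$case_id <- paste(sub$case_id, side, sep = "_")
        rows[[side]] <- sub
      }
    }
    out <- do.call(rbind, rows)
    if (!is.null(out)) {
      out <- out[order(out$source_case, out$side), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  if (is.null(out) || nrow(out) == 0)
    .fibsegError("fibseg_empty_manifest",
                 sprintf("no record is eligible for %s", approachStage))
  out
}

#' Split a manifest into training and validation sets
#'
#' Deterministic seeded partition at an integer ratio (default 9:1). The
#' validation count is `floor(n * val / (train + val))` with a minimum of
#' one case; the remainder trains. The partition is exhaustive and
#' disjoint.
#'
#' @param manifest manifest `data.frame` with at least 2 records.
#' @param ratio integer(2) `c(train, val)` proportions.
#' @param seed RNG seed making the split reproducible.
#' @return the manifest with the `split` column set to `"train"`/`"val"`.
#' @export
splitManifest <- function(manifest, ratio = c(9, 1), seed = 1) {
  n <- nrow(manifest)
  if (n < 2)
    .fibsegError("fibseg_split_error", "need at least 2 records to split")
  nVal <- max(1L, as.integer(floor(n * ratio[2] / sum(ratio))))
  valIdx <- .withLocalSeed(seed, sample.int(n, nVal))
  manifest$split <- "train"
  manifest$split[valIdx] <- "val"
  manifest
}

# run expr under a seed without disturbing the caller's RNG stream
.withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}
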