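# Seeded synthetic lower-limb CT phantoms with paired fibula ground
# truth, standing in for clinical cohorts that cannot be shared. Each leg
# holds a thick tibia-like cylinder (distractor) and a thin fibula-like
# tube (target) whose centerline bows laterally and whose radius ramps up
# into proximal (head) and distal (malleolus) bulges. The analytic
# geometry gives a closed-form volume oracle for the masks.

#' Construct phantom parameters
#'
#' Defaults are the package's desk-scale study conditions: a
#' 64 x 64 x 160 grid at (2, 2, 2.5) mm spacing (field of view
#' 128 x 128 x 400 mm, proportioned like a lower-extremity CT), legs
#' 31 mm either side of the mid-plane, a 12 mm tibia radius, a 5 mm
#' fibula shaft radius with 8 mm end bulges over the outer 15 percent of
#' the bone length, a 2 mm lateral bow, realistic Hounsfield levels and
#' 10 HU additive Gaussian noise.
#'
#' @param gridDim,spacing grid geometry.
#' @param legOffsetMm,tibiaRadiusMm,fibulaRadiusMm,bulgeRadiusMm,bulgeFrac,bowMm,fibulaOffsetMm,boneLengthFrac
#'   anatomy, see [PhantomParams-class].
#' @param huAir,huSoft,huTrabecular,huCortical,noiseSd intensity model.
#' @param fractureGapsLeft,fractureGapsRight,fractureWidthMm optional
#'   fracture gaps (z positions in mm from the inferior bone end) that
#'   interrupt the fibula, for fragmented-bone fixtures.
#' @param seed RNG seed for the noise field.
#' @return a validated [PhantomParams-class].
#' @export
phantomParams <- function(gridDim = c(64L, 64L, 160L),
                          spacing = c(2, 2, 2.5),
                          legOffsetMm = 31,
                          tibiaRadiusMm = 12,
                          fibulaRadiusMm = 5,
                          bulgeRadiusMm = 8,
                          bulgeFrac = 0.15,
                          bowMm = 2,
                          fibulaOffsetMm = c(20, 12),
                          boneLengthFrac = 0.9,
                          huAir = -1000, huSoft = 40,
                          huTrabecular = 700, huCortical = 1200,
                          noiseSd = 10,
                          fractureGapsLeft = numeric(0),
                          fractureGapsRight = numeric(0),
                          fractureWidthMm = 12,
                          seed = 1L) {
  new("PhantomParams",
      gridDim = as.integer(gridDim), spacing = as.numeric(spacing),
      legOffsetMm = legOffsetMm, fibulaRadiusMm = fibulaRadiusMm,
      bulgeRadiusMm = bulgeRadiusMm, bulgeFrac = bulgeFrac, bowMm = bowMm,
      tibiaRadiusMm = tibiaRadiusMm,
      fibulaOffsetMm = as.numeric(fibulaOffsetMm),
      boneLengthFrac = boneLengthFrac,
      huAir = huAir, huSoft = huSoft, huTrabecular = huTrabecular,
      huCortical = huCortical, noiseSd = noiseSd,
      fractureGapsLeft = as.numeric(fractureGapsLeft),
      fractureGapsRight = as.numeric(fractureGapsRight),
      fractureWidthMm = fractureWidthMm,
      seed = as.integer(seed))
}

# internal: fibula radius profile along the bone, mm
.fibulaRadiusProfile <- function(zRel, L, shaft, bulge, frac) {
  ramp <- function(t) 0.5 * (1 + cos(pi * pmin(t, 1)))   # 1 at the end -> 0
  extent <- frac * L
  r <- shaft + (bulge - shaft) * pmax(ramp(zRel / extent),
                                      ramp((L - zRel) / extent))
  r[zRel < 0 | zRel > L] <- 0
  r
}

# internal: analytic volume of the fibula tube, mm^3
.fibulaAnalyticVolume <- function(params) {
  L <- params@boneLengthFrac * params@gridDim[3] * params@spacing[3]
  s <- params@fibulaRadiusMm; b <- params@bulgeRadiusMm
  e <- params@bulgeFrac * L
  d <- b - s
  # int_0^e r(z)^2 dz with r = s + d*ramp: ramp integrates to e/2, ramp^2 to 3e/8
  endInt <- s^2 * e + 2 * s * d * (e / 2) + d^2 * (3 * e / 8)
  pi * (s^2 * (L - 2 * e) + 2 * endInt)
}

#' Generate one synthetic lower-limb CT phantom
#'
#' Builds the Hounsfield image and the left/right fibula ground-truth
#' masks deterministically from the parameters (the seed only drives the
#' noise field). Each leg contains a tibia (cortical shell, trabecular
#' core) and a fibula (uniform cortical) spanning `boneLengthFrac` of the
#' axial field of view; soft-tissue cylinders surround both bones. The
#' two fibula masks are disjoint and lie strictly on their own side of
#' the mid-plane.
#'
#' @param params a [PhantomParams-class].
#' @return a [PhantomCase-class].
#' @examples
#' p <- phantomParams(gridDim = c(32, 32, 40), spacing = c(4, 4, 10))
#' generatePhantom(p)
#' @export
generatePhantom <- function(params) {
  validObject(params)
  d <- params@gridDim; sp <- params@spacing
  fov <- d * sp
  xs <- (seq_len(d[1]) - 0.5) * sp[1]        # voxel centers, corner-based mm
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  midX <- fov[1] / 2; midY <- fov[2] / 2
  L <- params@boneLengthFrac * fov[3]
  z0 <- (fov[3] - L) / 2
  zRel <- zs - z0
  rProf <- .fibulaRadiusProfile(zRel, L, params@fibulaRadiusMm,
                                params@bulgeRadiusMm, params@bulgeFrac)
  bow <- params@bowMm * sin(pi * pmin(pmax(zRel / L, 0), 1))
  tibiaZ <- zs >= 0.02 * fov[3] & zs <= 0.98 * fov[3]

  hu <- array(params@huAir, d)
  left <- array(0L, d); right <- array(0L, d)

  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  for (sideSign in c(+1, -1)) {              # +1 left (high x), -1 right
    legX <- midX + sideSign * params@legOffsetMm
    fibX0 <- legX + sideSign * params@fibulaOffsetMm[1]
    fibY <- midY + params@fibulaOffsetMm[2]
    dTib2 <- (X - legX)^2 + (Y - midY)^2
    softTib <- dTib2 <= (params@tibiaRadiusMm + 14)^2
    tibCort <- dTib2 <= params@tibiaRadiusMm^2
    tibCore <- dTib2 <= (params@tibiaRadiusMm - 3)^2
    gaps <- if (sideSign > 0) params@fractureGapsLeft else params@fractureGapsRight
    for (k in seq_len(d[3])) {
      fibX <- fibX0 + sideSign * bow[k]
      dFib2 <- (X - fibX)^2 + (Y - fibY)^2
      softFib <- dFib2 <= (params@bulgeRadiusMm + 6)^2
      sl <- hu[, , k]
      sl[softTib | softFib] <- params@huSoft
      if (tibiaZ[k]) {
        sl[tibCort] <- params@huCortical
        sl[tibCore] <- params@huTrabecular
      }
      if (rProf[k] > 0) {
        inGap <- length(gaps) > 0 &&
          any(zRel[k] >= gaps & zRel[k] <= gaps + params@fractureWidthMm)
        if (!inGap) {
          fib <- dFib2 <= rProf[k]^2
          sl[fib] <- params@huCortical
          if (sideSign > 0) left[, , k] <- as.integer(fib)
          else right[, , k] <- as.integer(fib)
        }
      }
      hu[, , k] <- sl
    }
  }
  if (params@noiseSd > 0) {
    noise <- .withLocalSeed(params@seed,
                            array(rnorm(prod(d), 0, params@noiseSd), d))
    hu <- hu + noise
  }
  hu <- pmin(pmax(hu, -1024), 3071)
  og <- sp / 2                                # voxel (1,1,1) center
  new("PhantomCase",
      image = ctVolume(hu, sp, og),
      leftFibula = voxelMask(left, sp, og),
      rightFibula = voxelMask(right, sp, og),
      params = params)
}

#' Analytic fibula volume implied by phantom parameters
#'
#' Closed-form volume (mm^3) of the fibula tube (shaft plus end-bulge
#' ramps), the oracle against which voxelized mask volumes are checked.
#'
#' @param params a [PhantomParams-class].
#' @return volume in cubic millimetres.
#' @export
fibulaAnalyticVolume <- function(params) .fibulaAnalyticVolume(params)

#' Generate a cohort of phantoms with clinical laterality structure
#'
#' Writes `nRightOnly + nLeftOnly + nBoth` phantom cases (NIfTI image and
#' available-side masks) and a CSV manifest to `dir`. Mask availability
#' emulates clinical cohorts in which not every patient has both fibulae
#' segmented: right-only cases omit the left mask and vice versa (the
#' image always shows both legs). Per-case seeds are derived from the
#' master seed, and mild per-case anatomical jitter (radii, bow, leg
#' position) makes cases distinct.
#'
#' @param nRightOnly,nLeftOnly,nBoth case counts per laterality profile.
#' @param params base [PhantomParams-class] for every case.
#' @param seed master seed; case `i` uses `seed * 1000 + i` for anatomy
#'   jitter and noise.
#' @param dir output directory (created if needed).
#' @param prefix case id prefix.
#' @return the manifest `data.frame` (also written to `dir/manifest.csv`),
#'   with a `provenance` attribute recording the seed.
#' @export
generateCohort <- function(nRightOnly, nLeftOnly, nBoth, params = phantomParams(),
                           seed = 1, dir = tempfile("cohort"),
                           prefix = "case") {
  counts <- c(nRightOnly, nLeftOnly, nBoth)
  if (any(counts < 0))
    .fibsegError("fibseg_param_error", "cohort counts must be >= 0")
  if (sum(counts) == 0)
    .fibsegError("fibseg_empty_manifest", "all cohort counts are zero")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profile <- rep(c("right", "left", "both"), counts)
  rows <- vector("list", length(profile))
  for (i in seq_along(profile)) {
    caseSeed <- as.integer((seed * 1000 + i) %% .Machine$integer.max)
    p <- .jitterParams(params, caseSeed)
    case <- generatePhantom(p)
    id <- sprintf("%s%03d", prefix, i)
    imgPath <- file.path(dir, paste0(id, ".nii.gz"))
    writeVolume(case@image, imgPath)
    lp <- NA_character_; rp <- NA_character_
    if (profile[i] %in% c("left", "both")) {
      lp <- file.path(dir, paste0(id, "_left.nii.gz"))
      writeMask(case@leftFibula, lp)
    }
    if (profile[i] %in% c("right", "both")) {
      rp <- file.path(dir, paste0(id, "_right.nii.gz"))
      writeMask(case@rightFibula, rp)
    }
    rows[[i]] <- data.frame(case_id = id, image = imgPath,
                            left_mask = lp, right_mask = rp,
                            split = "unassigned", stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "provenance") <- sprintf("fibseg phantom cohort, seed %d", seed)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

# internal: per-case anatomical jitter (about 8 percent on radii, 2 mm on
# the leg position) plus a fresh noise seed
.jitterParams <- function(params, caseSeed) {
  jit <- .withLocalSeed(caseSeed, runif(5, -1, 1))
  params@fibulaRadiusMm <- params@fibulaRadiusMm * (1 + 0.08 * jit[1])
  params@bulgeRadiusMm <- params@bulgeRadiusMm * (1 + 0.06 * jit[2])
  params@tibiaRadiusMm <- params@tibiaRadiusMm * (1 + 0.05 * jit[3])
  params@bowMm <- params@bowMm * (1 + 0.2 * jit[4])
  params@legOffsetMm <- params@legOffsetMm + 1.5 * jit[5]
  params@seed <- as.integer(caseSeed)
  validObject(params)
  params
}
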