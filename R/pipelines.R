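# End-to-end orchestration of the two segmentation variants and the
# two-stage training protocol.
#
# Bilateral: stage 1 segments both fibulae jointly from the whole
# down-sampled CT; the two largest first-step components are taken to be
# the fibulae, labeled left/right, and each side is cropped (+margin),
# mirrored if right, refined by stage 2 at high resolution, re-mirrored
# and placed back on the original grid.
#
# Unilateral: the CT is split at the field-of-view mid-plane, the right
# half mirrored, and one shared stage-1 network segments each half; the
# rest of the chain is identical. Each side is processed independently,
# which removes the bilateral failure mode in which component filtering
# of a fragmented joint prediction discards a bone.

#' Pipeline configuration
#'
#' Stage resolutions default to the full-scale values (bilateral first
#' step 144 x 144 x 288, unilateral first step 96 x 192 x 320 on the
#' half field of view, second step 80 x 80 x 960); desk-scale phantom
#' experiments pass smaller grids. Every resolution must be divisible by
#' `2^depth` of the network spec in use.
#'
#' @param approach `"bilateral"` or `"unilateral"`.
#' @param stage1Dim first-step input grid (per half for unilateral).
#' @param stage2Dim second-step input grid (around one fibula).
#' @param bboxMarginMm margin added to the stage-1 bounding box before
#'   cropping (guards against slight under-segmentation; default 5 mm).
#' @param stage2MinCropMm numeric(3): minimum physical extent (mm) of the
#'   stage-2 crop per axis, `0` meaning the pure bounding box. Expanding
#'   small crops to a fixed in-plane extent keeps the anisotropic
#'   stretch onto the stage-2 grid consistent between training (ground
#'   truth boxes) and inference (detected boxes); the box is shifted,
#'   not clipped, at the image border so the extent is exact.
#' @param threshold binarization threshold on probabilities.
#' @param minComponentFrac bilateral stage 1: a component smaller than
#'   this fraction of the largest is debris, not a candidate bone.
#' @param bboxUnionMinFrac unilateral stage 1: components at least this
#'   fraction of the largest are pooled into the side's bounding box.
#' @param erodeIterations,sigmaVox,isoLevel mesh post-processing knobs.
#' @param cropMm ROI crop for evaluation (default 70 mm).
#' @param seed seed recorded in provenance.
#' @return a list of class `fibsegPipelineConfig`.
#' @export
pipelineConfig <- function(approach = c("bilateral", "unilateral"),
                           stage1Dim = NULL,
                           stage2Dim = c(80L, 80L, 960L),
                           bboxMarginMm = 5,
                           stage2MinCropMm = c(0, 0, 0),
                           threshold = 0.5,
                           minComponentFrac = 0.25,
                           bboxUnionMinFrac = 0.05,
                           erodeIterations = 1L,
                           sigmaVox = 1,
                           isoLevel = 0.5,
                           cropMm = 70,
                           seed = 1L) {
  approach <- match.arg(approach)
  if (is.null(stage1Dim))
    stage1Dim <- if (approach == "bilateral") c(144L, 144L, 288L)
                 else c(96L, 192L, 320L)
  structure(list(approach = approach,
                 stage1Dim = as.integer(stage1Dim),
                 stage2Dim = as.integer(stage2Dim),
                 bboxMarginMm = bboxMarginMm,
                 stage2MinCropMm = stage2MinCropMm,
                 threshold = threshold,
                 minComponentFrac = minComponentFrac,
                 bboxUnionMinFrac = bboxUnionMinFrac,
                 erodeIterations = as.integer(erodeIterations),
                 sigmaVox = sigmaVox, isoLevel = isoLevel,
                 cropMm = cropMm, seed = as.integer(seed)),
            class = "fibsegPipelineConfig")
}

# internal: the stage-2 crop box. Axes with a configured minimum
# physical extent are anchored on the mask centroid (robust to boundary
# under-segmentation, so training boxes from ground truth and inference
# boxes from detections coincide to within a voxel) and given exactly
# that extent, shifted -- never clipped -- at the grid border; the
# remaining axes use the plain bounding box + margin.
.stage2Box <- function(mask, config) {
  bb <- maskBBox(mask, marginMm = config$bboxMarginMm)
  minMm <- config$stage2MinCropMm
  if (all(minMm <= 0)) return(bb)
  sp <- spacing(mask)
  idx <- which(voxels(mask) != 0, arr.ind = TRUE)
  lo <- bb@lo; hi <- bb@hi
  for (ax in 1:3) {
    if (minMm[ax] <= 0) next
    need <- as.integer(ceiling(minMm[ax] / sp[ax]))
    width <- hi[ax] - lo[ax] + 1L
    if (width >= need) next
    ctr <- as.integer(round(mean(idx[, ax])))
    lo[ax] <- ctr - (need - 1L) %/% 2L
    hi[ax] <- lo[ax] + need - 1L
    if (lo[ax] < 1L) { hi[ax] <- hi[ax] + (1L - lo[ax]); lo[ax] <- 1L }
    if (hi[ax] > bb@refDim[ax]) {
      lo[ax] <- max(1L, lo[ax] - (hi[ax] - bb@refDim[ax]))
      hi[ax] <- bb@refDim[ax]
    }
  }
  new("BBox", lo = lo, hi = hi, refDim = bb@refDim)
}

# internal: refine one side with stage 2. sideMaskFull is the stage-1
# detection resampled to the grid of `norm` (a normalized CTVolume).
# Returns the refined full-grid mask (integer array) or NULL.
.refineSide <- function(norm, sideMaskFull, weights2, config, mirror) {
  bb <- .stage2Box(sideMaskFull, config)
  crop <- cropGrid(norm, bb)
  if (mirror) crop <- mirrorLR(crop)
  x2 <- resampleGrid(crop, config$stage2Dim, "trilinear")
  p2 <- unetForward(weights2, x2)
  m2 <- binarizeProb(p2, config$threshold)
  mCrop <- resampleGrid(m2, gridDim(crop), "nearest")
  if (mirror) mCrop <- mirrorLR(mCrop)
  uncropMask(mCrop, bb, gridDim(norm), spacing(norm), origin(norm))
}

# internal: assemble a SegmentationResult from per-side masks
.assembleResult <- function(ct, masks, status, config, log) {
  mesh <- list(left = NULL, right = NULL)
  for (side in c("left", "right")) {
    if (!is.null(masks[[side]]) && sum(voxels(masks[[side]])) > 0) {
      kept <- keepLargestComponents(masks[[side]], k = 1L)
      masks[[side]] <- kept$components[[1]]
      mesh[[side]] <- postprocessMask(masks[[side]],
                                      erodeIterations = config$erodeIterations,
                                      sigmaVox = config$sigmaVox,
                                      isoLevel = config$isoLevel)
    } else if (identical(status[[side]], "ok")) {
      status[[side]] <- "empty"
      masks[side] <- list(NULL)
    }
  }
  new("SegmentationResult",
      leftMask = masks$left, rightMask = masks$right,
      leftMesh = mesh$left, rightMesh = mesh$right,
      status = c(left = status$left, right = status$right), log = log)
}

#' Bilateral two-step segmentation
#'
#' Runs the full bilateral chain on a CT volume: normalize, down-sample
#' to the stage-1 grid, segment both fibulae jointly, keep the two
#' largest components and label them left/right, then per side crop the
#' original-resolution CT to the detection's bounding box (+margin),
#' mirror the right side, refine with stage 2, re-mirror and restore to
#' the original grid, and post-process to surface meshes.
#'
#' When the first step yields fewer than two candidate bones (a
#' fragmented prediction whose pieces fall below `minComponentFrac`, or
#' a missed bone), the pipeline degrades gracefully: the available side
#' is still produced and the other is flagged `"shortfall"` in the
#' result status rather than crashing.
#'
#' @param ct a [CTVolume-class] in Hounsfield units.
#' @param weights1,weights2 stage-1 / stage-2 [UNetWeights-class].
#' @param config a [pipelineConfig()] with `approach = "bilateral"`.
#' @return a [SegmentationResult-class].
#' @export
segmentBilateral <- function(ct, weights1, weights2, config = pipelineConfig("bilateral")) {
  t0 <- Sys.time()
  norm <- normalizeHU(ct)
  x1 <- resampleGrid(norm, config$stage1Dim, "trilinear")
  p1 <- unetForward(weights1, x1)
  m1 <- binarizeProb(p1, config$threshold)
  cand <- keepLargestComponents(m1, k = 2L, minFrac = config$minComponentFrac)
  log <- list(stage1_components = length(cand$sizes),
              stage1_sizes = cand$sizes)
  masks <- list(left = NULL, right = NULL)
  status <- list(left = "shortfall", right = "shortfall")
  if (length(cand$components) == 0) {
    status <- list(left = "empty", right = "empty")
  } else {
    if (length(cand$components) == 2) {
      lr <- labelLeftRight(cand$components)
    } else {
      # single candidate: assign by which side of the mid-plane it sits on
      midMm <- origin(m1)[1] + (gridDim(m1)[1] / 2 - 0.5) * spacing(m1)[1]
      isLeft <- .centroidLR(cand$components[[1]]) > midMm
      lr <- if (isLeft) list(left = cand$components[[1]], right = NULL)
            else list(left = NULL, right = cand$components[[1]])
    }
    for (side in c("left", "right")) {
      if (is.null(lr[[side]])) next
      sideFull <- resampleGrid(lr[[side]], gridDim(norm), "nearest")
      masks[[side]] <- tryCatch(
        .refineSide(norm, sideFull, weights2, config, mirror = side == "right"),
        fibseg_empty_mask = function(e) NULL)
      status[[side]] <- if (is.null(masks[[side]])) "empty" else "ok"
    }
  }
  log$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  .assembleResult(ct, masks, status, config, log)
}

#' Unilateral two-step segmentation
#'
#' Splits the CT at the field-of-view mid-plane, mirrors the right half,
#' and applies one shared stage-1 network to each half; per half the
#' bounding box pools all substantial stage-1 components
#' (`bboxUnionMinFrac`), so a fragmented bone still yields a full-extent
#' box. Stage-2 refinement then proceeds exactly as in the bilateral
#' chain. The two sides are fully independent: a failure on one cannot
#' affect the other.
#'
#' @inheritParams segmentBilateral
#' @param config a [pipelineConfig()] with `approach = "unilateral"`.
#' @return a [SegmentationResult-class].
#' @export
segmentUnilateral <- function(ct, weights1, weights2, config = pipelineConfig("unilateral")) {
  t0 <- Sys.time()
  norm <- normalizeHU(ct)
  halves <- splitHalves(norm)
  log <- list()
  masks <- list(left = NULL, right = NULL)
  status <- list(left = "empty", right = "empty")
  nRight <- gridDim(halves$right)[1]
  for (side in c("left", "right")) {
    half <- halves[[side]]
    if (side == "right") half <- mirrorLR(half)
    x1 <- resampleGrid(half, config$stage1Dim, "trilinear")
    p1 <- unetForward(weights1, x1)
    m1 <- binarizeProb(p1, config$threshold)
    log[[paste0(side, "_stage1_voxels")]] <- sum(voxels(m1))
    if (sum(voxels(m1)) == 0) next
    # pool all substantial components into one detection for the bbox
    cc <- keepLargestComponents(m1, k = .Machine$integer.max,
                                minFrac = config$bboxUnionMinFrac)
    pooled <- voxels(cc$components[[1]])
    for (cmp in cc$components[-1]) pooled <- pooled | voxels(cmp)
    det <- voxelMask(array(as.integer(pooled), dim(pooled)),
                     spacing(m1), origin(m1))
    detHalf <- resampleGrid(det, gridDim(half), "nearest")
    refined <- tryCatch(
      .refineSide(half, detHalf, weights2, config, mirror = FALSE),
      fibseg_empty_mask = function(e) NULL)
    if (is.null(refined)) next
    if (side == "right") refined <- mirrorLR(refined)
    # embed the half back into the full grid
    full <- array(0L, gridDim(norm))
    if (side == "right") full[seq_len(nRight), , ] <- voxels(refined)
    else full[(nRight + 1):gridDim(norm)[1], , ] <- voxels(refined)
    masks[[side]] <- voxelMask(full, spacing(norm), origin(norm))
    status[[side]] <- "ok"
  }
  log$seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  .assembleResult(ct, masks, status, config, log)
}

#' Run the configured segmentation approach
#'
#' @param ct a [CTVolume-class].
#' @param weights1,weights2 stage weights.
#' @param config a [pipelineConfig()]; dispatches on `config$approach`.
#' @return a [SegmentationResult-class].
#' @export
segmentCT <- function(ct, weights1, weights2, config) {
  if (config$approach == "bilateral") segmentBilateral(ct, weights1, weights2, config)
  else segmentUnilateral(ct, weights1, weights2, config)
}

# ---------------------------------------------------------------------------
# Training-sample preparation

# internal: read a case's image once
.loadCase <- function(row) {
  list(image = readVolume(row$image),
       left = if (!is.na(row$left_mask)) readMask(row$left_mask) else NULL,
       right = if (!is.na(row$right_mask)) readMask(row$right_mask) else NULL)
}

# internal: one stage-2 sample from a single fibula (mirrored to the left
# side when it is a right fibula), cropped to the GT bounding box.
.makeStage2Sample <- function(image, mask, side, config) {
  if (side == "right") { image <- mirrorLR(image); mask <- mirrorLR(mask) }
  bb <- .stage2Box(mask, config)
  x <- resampleGrid(normalizeHU(cropGrid(image, bb)), config$stage2Dim, "trilinear")
  y <- resampleGrid(cropGrid(mask, bb), config$stage2Dim, "nearest")
  list(x = voxels(x), y = voxels(y))
}

# internal: stage-1 samples for one case under an approach
.makeStage1Samples <- function(case, row, config) {
  out <- list()
  if (config$approach == "bilateral") {
    un <- voxels(case$left) + voxels(case$right)
    target <- voxelMask(array(as.integer(un > 0), dim(un)),
                        spacing(case$left), origin(case$left))
    x <- resampleGrid(normalizeHU(case$image), config$stage1Dim, "trilinear")
    y <- resampleGrid(target, config$stage1Dim, "nearest")
    out[[1]] <- list(x = voxels(x), y = voxels(y))
  } else {
    halves <- splitHalves(case$image)
    for (side in c("left", "right")) {
      if (is.null(case[[side]])) next
      img <- halves[[side]]
      msk <- splitHalves(case[[side]])[[side]]
      if (side == "right") { img <- mirrorLR(img); msk <- mirrorLR(msk) }
      x <- resampleGrid(normalizeHU(img), config$stage1Dim, "trilinear")
      y <- resampleGrid(msk, config$stage1Dim, "nearest")
      out[[length(out) + 1]] <- list(x = voxels(x), y = voxels(y))
    }
  }
  out
}

#' Train a full two-step approach on a cohort
#'
#' Implements the two-stage training protocol with Expansion Transfer
#' Learning: the second-step network is trained from scratch on
#' individual fibula crops (right fibulae mirrored to the left, so all
#' available ground truth is used), then its weights initialize the
#' first-step network, which is trained on its stage-specific inputs --
#' the whole down-sampled CT with a both-fibula target for the bilateral
#' approach, mirrored half-volumes with single-fibula targets for the
#' unilateral approach. Eligibility and 9:1 train/validation splitting
#' are handled internally via [filterEligible()] and [splitManifest()].
#'
#' @param manifest cohort manifest (see [readManifest()]).
#' @param approach `"bilateral"` or `"unilateral"`.
#' @param spec [UNetSpec-class] shared by both stages (required for ETL).
#' @param trainConfig1,trainConfig2 [unetTrainConfig()] per stage.
#' @param config a [pipelineConfig()] for resolutions and margins.
#' @param stage2Weights optional pre-trained second-step weights; the
#'   second step is approach-independent, so one training can serve both
#'   approaches.
#' @param verbose print per-epoch losses.
#' @return `list(stage1 = , stage2 = UNetWeights, history = list,
#'   sampleCounts = c(stage2, stage1))`.
#' @export
trainApproach <- function(manifest, approach = c("bilateral", "unilateral"),
                          spec = unetSpec(),
                          trainConfig1 = unetTrainConfig(),
                          trainConfig2 = unetTrainConfig(),
                          config = NULL,
                          stage2Weights = NULL, verbose = FALSE) {
  approach <- match.arg(approach)
  if (is.null(config)) config <- pipelineConfig(approach)
  history <- list()
  # --- stage 2: every available fibula, mirrored to the left ------------
  elig2 <- filterEligible(manifest, "step2")
  n2 <- nrow(elig2)
  if (is.null(stage2Weights)) {
    part2 <- splitManifest(elig2, c(9, 1), trainConfig2$seed)
    mk2 <- function(rows) lapply(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      case <- .loadCase(row)
      .makeStage2Sample(case$image, case[[row$side]], row$side, config)
    })
    s2 <- list(train = mk2(part2[part2$split == "train", ]),
               val = mk2(part2[part2$split == "val", ]))
    r2 <- trainUNet(s2, trainConfig2, spec = spec, stage = "step2",
                    verbose = verbose)
    stage2Weights <- r2$weights
    history$stage2 <- r2$history
  }
  # --- stage 1: ETL init, then approach-specific inputs ------------------
  stage <- if (approach == "bilateral") "bilateral_step1" else "unilateral_step1"
  elig1 <- filterEligible(manifest, stage)
  part1 <- splitManifest(elig1, c(9, 1), trainConfig1$seed)
  mk1 <- function(rows) {
    out <- list()
    for (i in seq_len(nrow(rows))) {
      row <- rows[i, ]
      if (approach == "unilateral") {
        case <- .loadCase(row)
        case[[setdiff(c("left", "right"), row$side)]] <- NULL
      } else case <- .loadCase(row)
      out <- c(out, .makeStage1Samples(case, row, config))
    }
    out
  }
  s1 <- list(train = mk1(part1[part1$split == "train", ]),
             val = mk1(part1[part1$split == "val", ]))
  init1 <- expansionTransfer(stage2Weights, spec)
  r1 <- trainUNet(s1, trainConfig1, initWeights = init1, stage = stage,
                  verbose = verbose)
  history$stage1 <- r1$history
  list(stage1 = r1$weights, stage2 = stage2Weights, history = history,
       sampleCounts = c(stage2 = n2, stage1 = nrow(elig1)))
}

#' Evaluate trained weights on a test cohort
#'
#' Segments every test case with the configured approach and compares
#' each side that has ground truth, producing one row per fibula with
#' Dice score, average surface distance and 95th-percentile Hausdorff
#' distance, whole-bone and ROI-restricted, plus aggregate mean and sd
#' rows. Sides without ground truth are skipped with a logged reason;
#' failed sides appear with their status and NA metrics.
#'
#' @param manifest test manifest.
#' @param weights1,weights2 trained stage weights.
#' @param config a [pipelineConfig()].
#' @return `data.frame` with columns `case_id`, `side`, `approach`,
#'   `DS`, `ASD_mm`, `HD95_mm`, `ROI_DS`, `ROI_ASD_mm`, `ROI_HD95_mm`,
#'   `status`; aggregate rows carry `case_id` `"mean"` / `"sd"`.
#' @export
runExperiment <- function(manifest, weights1, weights2, config) {
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    case <- .loadCase(row)
    res <- segmentCT(case$image, weights1, weights2, config)
    for (side in c("left", "right")) {
      gt <- case[[side]]
      if (is.null(gt)) next
      pred <- if (side == "left") res@leftMask else res@rightMask
      st <- res@status[[side]]
      if (is.null(pred)) {
        met <- data.frame(DS = 0, ASD_mm = NA_real_, HD95_mm = NA_real_,
                          ROI_DS = NA_real_, ROI_ASD_mm = NA_real_,
                          ROI_HD95_mm = NA_real_)
      } else {
        met <- evaluatePair(gt, pred, cropMm = config$cropMm)[, 1:6]
      }
      rows[[length(rows) + 1]] <- cbind(
        data.frame(case_id = row$case_id, side = side,
                   approach = config$approach),
        met, data.frame(status = st))
    }
  }
  tab <- do.call(rbind, rows)
  mcols <- c("DS", "ASD_mm", "HD95_mm", "ROI_DS", "ROI_ASD_mm", "ROI_HD95_mm")
  agg <- function(f, label) {
    out <- data.frame(case_id = label, side = "all", approach = config$approach)
    for (m in mcols) out[[m]] <- f(tab[[m]], na.rm = TRUE)
    out$status <- ""
    out
  }
  rbind(tab, agg(mean, "mean"), agg(sd, "sd"))
}
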