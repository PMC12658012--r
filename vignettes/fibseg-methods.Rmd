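---
title: "Two-stage 3D U-Net fibula segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage 3D U-Net fibula segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In mandibular reconstruction with a free fibula flap, a patient-specific
3D model of the fibula is segmented from a lower-extremity CT and used to
plan the bone transplant. Manual segmentation is slow and
operator-dependent; `fibseg` implements a fully automatic coarse-to-fine
pipeline with two 3D U-Nets:

1. **Step 1 (localization)** finds the fibulae in a heavily down-sampled
   view of the scan.
2. **Step 2 (refinement)** segments each bone precisely from the CT
   cropped to the detected bounding box and resampled to a tall, narrow
   grid that matches fibula geometry.

Both fibulae appear in every scan, which the two supported variants
exploit differently:

* **Bilateral** — step 1 segments both bones jointly from the whole
  field of view. Training this step requires cases with *both* sides
  annotated; in a typical clinical cohort (13 right-only, 26 left-only,
  36 both-sided of 75 patients) that discards 52% of the data.
* **Unilateral** — the scan is split at the field-of-view mid-plane
  (axis 1, the left-right axis, index increasing toward patient left),
  the right half is mirrored, and a single step-1 network serves both
  halves. Every annotated fibula becomes usable (111 samples from the
  cohort above), and the relative resolution is higher because half the
  field of view maps onto a comparable grid.

Mirroring is a pure grid flip about the field-of-view mid-plane — not an
anatomical registration; it relies on patients being positioned roughly
centrally, and on the approximate left-right mirror symmetry of the legs.

# The network

`unetSpec(depth, baseChannels)` describes a fully convolutional encoder
/decoder: the encoder has `2*depth + 2` convolutions (3×3×3 kernels,
same padding, ReLU) with `depth` 2×2×2 max-poolings, doubling feature
maps at each pooling; the mirrored decoder upsamples by element
repetition (factor 2 per axis) and concatenates skip features; a final
1-channel convolution with a sigmoid yields per-voxel probabilities.
The default `unetSpec(4, 16)` is the full-size architecture: ten encoder
convolutions, four pooling steps, 512 feature maps at the deepest layer.
Because the network is fully convolutional, trained weights run at any
resolution divisible by `2^depth` — the property behind **Expansion
Transfer Learning (ETL)**: the second step is trained first (the easier,
cropped task) and all of its parameters initialize the first-step
network at the wider field of view (`expansionTransfer()`).

Training (`trainUNet()`) uses Adam on the soft Dice loss

$$ L = 1 - \frac{2\sum_i p_i t_i + \epsilon}{\sum_i p_i + \sum_i t_i + \epsilon},
\qquad \epsilon = 10^{-6}, $$

batch size 1 (whole volumes at the stage resolution, no patches), no
data augmentation, and keeps the best-validation-loss checkpoint.
Intensities are prepared by `normalizeHU()`: clip to [−1024, 3071] HU and
map linearly to [0, 1]; no per-image standardization.

Choices the underlying method leaves open, fixed here as package
defaults:

* per-convolution nonlinearity ReLU; normalization is config-switchable
  (`norm = "none"` reproduces the plain reference behaviour;
  `norm = "instance"` adds per-channel instance normalization with
  learned scale/shift after every convolution except the output);
* sigmoid output with a downstream binarization threshold of 0.5;
* Adam learning rate 1e-3, epochs per stage in the experiment
  configuration, batch size 1;
* He-normal seeded initialization.

The pure Dice loss is numerically treacherous for small unnormalized
networks: once the sigmoid saturates (probabilities exactly 0/1), its
gradient vanishes and training dies with the loss pinned at 1 — a state
we observed reproducibly from aggressive learning rates, from
over-confident warm starts on a new stage's input distribution, and
from wholesale ReLU death in wider networks. Three complementary
safeguards address this:

* **Instance normalization** (enabled in the desk-scale configuration)
  keeps activations in a sane range at any depth/width and removes the
  failure mode at the root; with it, both stages train stably and the
  warm-started first step converges as reliably as a fresh start.
* **Bounded-logit output**: the output activation is
  `sigmoid(a·tanh(z/a))` with `a = 12` — indistinguishable from the
  plain sigmoid at working logits but never gradient-dead at extreme
  confidence.
* **A warm-start saturation guard**: if transferred weights are both
  saturated (90th percentile of |logit| > 8) and fitting poorly (Dice
  loss > 0.5 on the first sample), the output layer is
  temperature-rescaled so the 90th percentile of |logit| is 4; healthy
  initializations are never touched. Global gradient-norm clipping
  (threshold 1) additionally caps the occasional huge Dice-loss step.

# The pipelines

`segmentBilateral()` / `segmentUnilateral()` orchestrate: normalize →
resample to the stage-1 grid → forward → binarize → component analysis →
per-side bounding box (+ margin) on the original grid → crop → mirror if
right → resample to the stage-2 grid → forward → binarize → re-mirror →
restore to the original grid → post-process to a surface mesh.

Design decisions:

* **Candidate filtering (bilateral).** The two largest 26-connected
  components of the step-1 output are taken to be the fibulae;
  components smaller than `minComponentFrac` (default 0.25) of the
  largest are debris and not candidates. When fewer than two candidates
  remain — the known failure mode in which a fragmented prediction loses
  a bone to exactly this filtering — the pipeline emits the available
  side and a machine-readable `"shortfall"` status instead of failing
  silently. The unilateral variant cannot exhibit this joint-field mode:
  each half is processed independently, and its bounding box pools *all*
  substantial components of that half (`bboxUnionMinFrac`, default
  0.05), so a fragmented bone still receives a full-extent box.
* **Per-side boxes.** Stage-2 crops use one bounding box per fibula
  (computed from the up-sampled stage-1 detection on the original grid,
  nearest-neighbour), not a joint box around both.
* **Box margin.** Default 5 mm isotropic; the margin guards against
  step-1 under-segmentation and should be on the order of two stage-1
  voxels.
* **Minimum crop extent.** `stage2MinCropMm` optionally gives the crop
  a fixed physical extent per axis, anchored on the mask centroid
  (which detections estimate accurately even when their boundaries are
  off) and shifted — never clipped — at the image border. Because the
  crop is stretched anisotropically onto the fixed stage-2 grid,
  keeping extent and anchor consistent makes the scale and framing seen
  by the refinement network identical between training (ground-truth
  masks) and inference (detections). With `0` (the default) the crop is
  the pure bounding box; the desk-scale phantom experiments set 36 mm
  in-plane, where the small networks are otherwise measurably brittle
  to an mm-level box difference.
* **Left/right labeling** reduces "orientation in space" to the centroid
  rule: under the declared axis convention the component with the
  greater left-right coordinate is the left fibula. Exactly equal
  centroids are an error, not a guess.
* **Mesh chain order**: binarize → largest component → binary erosion
  (3×3×3 box, 1 iteration) → Gaussian smoothing (sigma 1 voxel,
  anisotropy-aware) → iso-surface at 0.5. Element, iterations, sigma and
  iso level are configuration knobs; the method source is silent on all
  of them.
* **Iso-surface extraction** marches over the Freudenthal (six
  tetrahedra) decomposition of each grid cell rather than the classic
  cube case table: no ambiguous cases, watertight by construction
  (shared cell faces always triangulate consistently), and vertices are
  keyed by grid edges so the mesh is indexed without post-hoc merging.
  Accuracy is oracle-checked: a smoothed 10 mm cube yields an enclosed
  volume within a few percent of 1000 mm³.
* **Coordinates.** Grid axis 1 is patient left-right (increasing toward
  the left), axis 3 inferior→superior; physical units are mm throughout;
  voxel indices and bounding boxes are 1-based inclusive (the natural R
  convention); the center of voxel (1,1,1) sits at `origin`.

# Evaluation metrics

`evaluatePair()` reports Dice score, symmetric average surface distance
(ASD) and the 95th-percentile Hausdorff distance (HD95), whole-bone and
ROI-restricted:

* Surfaces are foreground voxels with a 6-connected background
  neighbour (the grid border counts as background), taken as voxel
  centers in mm — deterministic and directly checkable against a
  brute-force oracle, which the test suite does on >100 seeded random
  mask pairs to 1e-9 mm.
* ASD pools the directed nearest-neighbour distances of both directions
  and averages; HD95 takes the linearly interpolated 95th percentile of
  the same pooled multiset. Directed variants and the percentile are
  arguments (`probs = 1` gives the classical Hausdorff distance).
* Empty masks: Dice of two empty masks is 1 (perfect agreement);
  surface distances of an empty mask are undefined and reported as `NA`
  with a validity flag, never coerced to a number.
* **ROI restriction** (`roiRestrict()`): in fibula-free-flap surgery the
  proximal and distal 6–7 cm are preserved for knee/ankle stability, so
  accuracy matters most in the central bone. The window
  `[zmin(gt) + 70, zmax(gt) − 70]` mm is computed once from the
  ground-truth extent along the inferior–superior grid axis (a straight
  axial crop, not along the bone's principal axis) and applied to both
  masks. A ground truth shorter than 140 mm has no valid ROI and is
  flagged. The 70 mm default is a parameter (`cropMm`).

# The synthetic phantom

Clinical CT with fibula ground truth is not shareable, so the package
generates seeded lower-limb phantoms (`generatePhantom()`,
`generateCohort()`): a 64×64×160 grid at (2, 2, 2.5) mm — field of view
128×128×400 mm, proportioned like a lower-extremity scan — with two legs
on opposite sides of the mid-plane. Each leg holds a soft-tissue
envelope, a thick tibia-like cylinder (cortical shell at 1200 HU,
trabecular core at 700 HU) as distractor, and the target: a thin
fibula-like tube (5 mm shaft radius, uniform cortical HU) whose
centerline bows laterally (2 mm) and whose radius ramps into 8 mm
proximal/distal bulges over the outer 15% of its 360 mm length —
mimicking the fibular head and malleolus, where segmentation is known to
be weakest, and sized so a 70 mm ROI crop removes them entirely. Air,
soft tissue and bone levels sit at realistic Hounsfield values and
additive Gaussian noise (sd 10 HU) is applied before clipping. Cohorts
reproduce clinical laterality structure (right-only / left-only /
both-sided ground truth) with mild seeded anatomical jitter (radii ±6–8%,
bow ±20%, leg position ±1.5 mm) per case.

The analytic tube geometry supplies a closed-form volume oracle, and on
noiseless phantoms simple thresholding at the soft-tissue/cortical
midpoint recovers exactly the bone voxels — a sanity bound for any
trained model.

What the phantom does *not* emulate: cortical/trabecular texture,
partial-volume blur, scanner artifacts (beam hardening, metal), true
anatomical shape variation, pathology, and neighbouring-structure
complexity. Passing the end-to-end phantom tests therefore demonstrates
that the pipeline machinery — two-stage training with ETL, mirroring
bookkeeping, component filtering, ROI evaluation — functions and
recovers known geometry; it does not certify clinical accuracy on real
scans.

A fragmented-bone variant (`fractureGapsLeft` / `fractureGapsRight`)
interrupts a fibula with soft-tissue gaps, producing the multi-component
first-step predictions that trigger the bilateral shortfall but leave
the unilateral variant intact — the robustness contrast between the two
approaches, reproduced qualitatively at desk scale.

# Desk-scale experiment sizes

The shipped experiment defaults (`defaultExperimentConfig()`,
`inst/extdata/default-config.yaml`) are chosen for a single CPU: network
`depth 3, base 4, instance normalization`; stage-1 grids 32×32×96
(bilateral, whole field of view) and 24×48×96 (per mirrored half,
unilateral — finer relative resolution than the bilateral view, as in
the full-scale setting); stage-2 grid 24×24×96 with a fixed 36 mm
in-plane crop extent; training cohort of 20 phantoms (4 right-only /
4 left-only / 12 both-sided) plus 5 both-sided test cases; Adam 1e-3,
20 epochs per stage (12 for the unilateral first step, whose aligned
warm start converges quickly); stage 2 first, then ETL into each
stage 1. The full-scale resolutions (144×144×288, 96×192×320,
80×80×960) remain the `pipelineConfig()` defaults and all are divisible
by 2⁴ as the full-size network requires.

The acceptance checks ask for per-side Dice ≥ 0.8 against phantom
ground truth — deliberately below what the clean-phantom task allows,
and far from certifying the headline accuracy a full-scale training on
clinical data would report.

# Known limitations

* The training loop is plain single-threaded CPU code; it is adequate
  for the phantom studies the package ships, not for clinical-scale
  training.
* Without normalization (`norm = "none"`), ETL at toy scale can be
  *negative* transfer: features tuned on left-oriented crops bias the
  orientation-agnostic bilateral first step toward a one-sided local
  optimum under the pure Dice loss. Instance normalization resolves
  this in the desk-scale configuration; the per-epoch histories are
  exposed so users can see either behaviour.
* Orientation handling trusts the NIfTI header to already match the
  package axis convention; no automatic reorientation.
* Binary STL stores float32; coordinates round-trip at single precision.
* NIfTI-1 headers store spacing/origin as float32; values like 0.8 mm
  are exact only at single precision (and bit-stable from the first
  write onward).
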