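# fibseg default experiment configuration (desk-scale phantom study).
# Mirrors fibseg::defaultExperimentConfig(); any field may be overridden.

seed: 1

phantom:
  grid_dim: [64, 64, 160]        # voxels; field of view 128 x 128 x 400 mm
  spacing: [2.0, 2.0, 2.5]       # mm
  noise_sd: 10                   # additive Gaussian noise, HU

cohort:
  # laterality profile of the training cohort: not every case has both
  # fibulae annotated, which is exactly what motivates the unilateral
  # approach
  n_right_only: 13
  n_left_only: 26
  n_both: 36
  n_test_both: 10                # independent both-sided test set

network:
  depth: 3                       # pooling steps (full-size network: 4)
  base_channels: 4               # feature maps after the first conv (full-size: 16)
  norm: instance                 # per-conv instance normalization (full-size ref: none)

pipeline:
  bilateral:
    stage1_dim: [32, 32, 96]     # whole field of view (full-scale: 144 x 144 x 288)
  unilateral:
    stage1_dim: [24, 48, 96]     # half field of view (full-scale: 96 x 192 x 320)
  stage2_dim: [24, 24, 96]       # per-fibula crop (full-scale: 80 x 80 x 960)
  stage2_min_crop_mm: [36, 36, 0]  # fixed in-plane crop extent (scale consistency)
  bbox_margin_mm: 5
  threshold: 0.5

training:
  stage1: {lr: 0.001, epochs: 20}
  stage2: {lr: 0.001, epochs: 20}

crop_mm: 70                      # ROI restriction: removed from each bone end
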