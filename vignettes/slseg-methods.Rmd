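---
title: "Super Learner ensemble segmentation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super Learner ensemble segmentation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(slseg)
```

## The problem

Lipomatous tumors — fat-containing soft-tissue tumors spanning benign lipoma
through liposarcoma — are delineated on T1-weighted or proton-density MR
images for radiomic analysis and surgical planning, and manual delineation of
a single tumor can take hours. Automating the segmentation is hard for a
reason that is mostly *not* about the network: multicenter MR data are
heterogeneous. Intensity scales are arbitrary and scanner-dependent, surface
coils impose smooth multiplicative bias fields, and the tumors themselves
vary in size, location and contrast, sometimes nearly isointense with normal
subcutaneous fat.

No single intensity normalization fixes all of this, and each one suppresses
some image feature while preserving others. slseg therefore trains *several*
convolutional base learners on differently preprocessed copies of the data
and stacks them: a Super Learner combines their per-voxel probability maps
with a convex weight vector optimized on held-out data.

## The pipeline

1. **Cohort split** (`split_cohort`). Exams are shuffled with a seeded
   generator and partitioned train/tune/test by largest-remainder rounding of
   `n * fractions`. At the canonical fractions (0.80, 0.09, 0.11) a 185-exam
   cohort splits 148/17/20. Largest-remainder is the only rounding rule that
   reproduces those three published counts simultaneously, which is why it is
   the package's rule.

2. **Preprocessing variants** (`preprocess_spec`, `default_variants`). Six
   combinations: z-score without bias correction; z-score, volume min–max,
   slice min–max and Nyul standardization after bias correction, all with the
   plain U-Net; and z-score after bias correction with the attention U-Net.
   Keeping one variant *without* bias correction hedges against the cases
   where the correction itself removes genuine features.

3. **Base learners** (`train_cv`). Each variant is trained five-fold
   cross-validated on the training split (each fold in turn serving as
   validation), giving 6 × 5 = 30 learners. Training minimizes a
   dice-coefficient loss with Adam, batch 16 slices, with on-the-fly
   augmentation (rotation ±15°, scaling 0.9–1.1, horizontal/vertical flips at
   probability 0.5).

4. **Super Learner** (`fit_weights`, `combine_maps`, `binarize`). The 30
   learners predict the tuning split; the weights `w` minimize the voxelwise
   cross-entropy of the combined probability
   `p_SL = sum_j w_j p_j` under the simplex constraints `w_j in [0, 1]`,
   `sum w_j = 1`. The combined map is thresholded at 0.5 (ties map to tumor).

5. **Evaluation** (`dsc`, `sensitivity`, `specificity`, `hd95`, `roc_auc`,
   `summarize_by_location`). Overlap metrics, the 95th-percentile Hausdorff
   distance in mm, voxelwise ROC/AUC, and per-location summary tables with
   improvement rows (signed difference for overlap metrics, percent reduction
   for HD95).

## Model details and their assumptions

### Network architecture

`build_unet` constructs a 2D U-Net: `levels` encoder blocks of two 3×3
convolutions (each followed by batch-norm and ReLU), 2×2 max-pooling between
levels, features doubling from `root_features`; a mirrored decoder with 2×2
transposed-convolution upsampling and skip concatenation; a final 1×1
convolution with sigmoid output. The attention variant gates each skip with
an additive attention block: 1×1 projections of the gating (coarser-level)
and skip signals, ReLU, a 1×1 projection to one channel, sigmoid, and
bilinear resampling of the gating projection to the skip resolution; the
resulting per-pixel coefficient in [0, 1] multiplies the skip features.

The networks, batch-norm, pooling, transposed convolutions, attention gates,
Adam and the full backpropagation are implemented in the package (R with
compiled C++ kernels for the 3×3 convolutions and a few hot element-wise
operations). Correctness is pinned by finite-difference gradient tests over
every parameter tensor of both architectures.

Two spatial assumptions follow the 2D slice-wise design: input slices must
be divisible by `2^(levels-1)` in both in-plane dimensions, and the slice
axis is never pooled, resampled or convolved across.

### Initialization

Convolutions are He-initialized; batch-norm starts at scale 1 / shift 0. The
final 1×1 convolution's bias is initialized to −2 so the output sigmoid
starts near the foreground prior rather than at 0.5. Tumor voxels are a few
percent of a slice; starting at 0.5 makes the dice denominator (`sum p`)
enormous relative to the overlap term and flattens early gradients. Measured
on the phantom cohort, the negative bias cuts the epochs to a validation
dice of 0.93 roughly in half and removes a spurious early plateau in the
min–max variants. This is an initialization choice of the package; it does
not change the architecture or the parameter count.

### Optimization

Adam with learning rate 1e-3 is the function default for `train_learner`.
The pipeline default (`pipeline_config`) is 1e-2 with up to 8 epochs and
early stopping once the mean validation dice reaches 0.92: at the desk-scale
network size (levels 3, root 4, 64×64 slices) the smaller rate needs several
times more epochs on the phantom cohort for no accuracy gain. At full scale
(levels 5, root 32, 512×512, 120 epochs, batch 16) the conservative default
is the appropriate one. Batch-norm uses batch statistics during training and
running statistics (momentum 0.9) at inference, so prediction is
deterministic and independent of batch composition.

### Dice loss

`dice_loss` is `1 − (2·Σpy + ε)/(Σp + Σy + ε)` over the whole batch with
ε = 1e-6. The ε keeps slices with empty masks finite (they are retained in
training), and the loss ignores the background class entirely, which is what
makes it robust to the extreme tumor/background imbalance.

### Super Learner weight optimization

`fit_weights` parameterizes the weights as a softmax over unconstrained
logits initialized at zero — the starting point is exactly the uniform
weight 1/m, and every iterate is feasible by construction, so no projection
step is needed. Full-batch Adam (default rate 0.05) minimizes the summed
voxelwise cross-entropy with the combined probability clipped to
[1e-7, 1−1e-7] before the logarithms. The epoch budget is 200 with early
stop after 10 consecutive epochs improving less than 1e-8. Whether the loss
is summed or averaged over voxels does not change the minimizer; the package
sums. A degenerate tuning truth (single class everywhere) yields uniform
weights with a warning rather than an error.

### Bias-field correction

`bias_correct` estimates a smooth multiplicative field in the log domain:
each iteration sharpens the current corrected log intensities into a
piecewise-constant tissue estimate (k-means with deterministic quantile
initialization, k = 4) and fits the residual with a tensor-product cubic
B-spline surface (control-point spacing defaulting to a quarter of the
in-plane field of view) by Tukey-bisquare-weighted least squares with a
small ridge. The robust weights suppress voxels whose residual reflects
class misassignment rather than smooth bias. The fitted log field is
centred, clamped to the range observed on the fitted voxels (guarding
against spline extrapolation outside the foreground), exponentiated and
divided out. The estimate is fitted on a regular subsample of ~4000
foreground voxels (intensity above a small positive floor) and evaluated on
the full grid; the procedure is deterministic. A constant volume is returned
unchanged (there is no bias to remove); an all-zero volume is an error.

Because ensemble inference applies the identical correction once per base
learner, results are memoised in a package-local cache keyed by exam id,
voxel checksums and parameters (`options(slseg.bias_cache = FALSE)` opts
out).

### Nyul histogram standardization

`nyul_train` learns landmark intensities at percentiles
{1, 10, 20, …, 90, 99} over foreground voxels — those above the mean of the
volume's nonzero intensities — maps each volume's landmarks linearly so the
anchors hit the standard range (0, 100), and averages across training
volumes. `nyul_apply` pipes a new volume through the piecewise-linear map
from its own landmarks to the standard values, extrapolating linearly with
the end-segment slopes. The foreground threshold is the package's reading of
the method (the citation-level description leaves it open); the map is
monotone by construction and affine-invariant in the training volumes. In
cross-validated training, scales are fitted per fold on that fold's training
exams only.

### HD95

Boundary voxels are mask voxels with at least one face-adjacent background
neighbour (the outside of the grid counts as background), in 3D. Directed
nearest-neighbour Euclidean distances are computed in mm with anisotropic
spacing in *both* directions, pooled, and the 95th percentile taken with
linear interpolation. The pooled definition makes HD95 symmetric in its
arguments; some tools instead take the maximum of two directed percentiles.
A brute-force all-pairs oracle pins the package's choice in the tests. A
slice-wise 2D option (`slicewise = TRUE`) restricts distances to within
slices, since published boundary metrics are sometimes computed that way;
the volumetric 3D form is the default. If either mask is empty HD95 is
undefined (`NA`), never an exception; two empty masks give DSC 1 by
convention.

## The phantom generator

Real multicenter MRI of this kind is not publicly available, so
`generate_cohort` produces a synthetic stand-in that reproduces the
*statistical structure* the method targets, not MR physics:

- piecewise-constant anatomy: dark background (0.10), a soft-tissue body
  ellipse (0.35), a bright subcutaneous fat band (1.00);
- an ellipsoidal tumor, optionally lobulated (union of 1–3 overlapping
  ellipsoids, mimicking insinuating lipomatous shapes), with mean intensity
  = fat × a contrast factor drawn from 1.1–1.6 (toward 1 = nearly isointense
  with fat, the clinically hard case);
- a smooth multiplicative bias field (low-pass filtered seeded noise,
  exponentiated, mean 1, default peak amplitude 0.3, correlation length 16
  voxels);
- a site style (intensity offset, scale, gamma) cycled round-robin over
  three defaults, modeling scanner/protocol intensity conventions;
- additive Gaussian noise (sd 0.05).

Default scale is 60 exams of 8×64×64 voxels at (4, 1, 1) mm spacing; exams
are bit-reproducible functions of `(seed, index)`. What the phantom does
*not* emulate: anatomical texture, partial-volume effects, k-space
artifacts, fat saturation variants, or tumors that infiltrate between
fascial planes. Passing the end-to-end tests therefore demonstrates that
the pipeline machinery — preprocessing, training, stacking, evaluation —
behaves correctly under controlled heterogeneity, not that the trained
desk-scale networks would transfer to clinical images.

## Problem sizes used by the test suite

The suite trains desk-scale networks (levels 3, root 4, 64×64 slices) on the
60-exam phantom cohort: a 1-variant × 2-fold smoke configuration and the full
6-variant × 5-fold configuration (30 base learners), plus many small
property checks on 8–16 voxel grids. These sizes were chosen so the whole
suite runs on a single CPU in well under half an hour while still exercising
every stage at realistic relative proportions. The full-scale configuration
(levels 5, root 32, 512×512) is constructible and tested for shape and
parameter-count correctness but not trained in the suite.

## Numerical choices

- Dice ε 1e-6; SL probability clip 1e-7; batch-norm ε 1e-5.
- Thresholding uses ≥, so a uniform 0.5 map is all-tumor rather than
  silently empty.
- Z-score uses the population standard deviation over the whole 3D volume;
  constant volumes normalize to zeros with a warning (degenerate inputs must
  not kill a batch pipeline).
- `split_cohort` breaks remainder ties by position, making the split a pure
  function of (ids, fractions, seed).
- One pipeline seed expands deterministically into per-stage seeds (split,
  folds, per-learner initialization and augmentation, SL fit) via an LCG
  hash, so any stage can be reproduced in isolation.

## Known limitations

- 2D slice-wise networks: no inter-slice context, so spurious disconnected
  predictions in isolated slices are possible (they inflate HD95).
- At desk scale the tuning split is tiny (9% of 60 exams is 5), so the
  optimized weights can mildly overfit it; the equal-weights ensemble —
  always evaluated alongside — is occasionally on par with the optimized
  one there. The optimized/equal gap is expected to matter most when base
  learners differ strongly in quality, as they do on heterogeneous clinical
  data.
- The bias-correction model assumes approximately piecewise-constant tissue
  classes; heavy texture would leak into the field estimate.
- DICOM series are not read directly; convert to NIfTI or the raw float32
  cache format first.
- The phantom's site styles are global intensity maps; real protocol
  differences also change resolution, contrast mechanisms and noise texture.
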