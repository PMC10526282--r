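---
title: "Brain age from 2D moment projections: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age from 2D moment projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(projage)
```

## The model

Brain age regression maps a structural brain image to an age estimate; the
gap between predicted and chronological age is a candidate disease
biomarker. 3D convolutional networks are the default tool but are costly to
train at biobank scale. `projage` instead compresses each 3D volume into a
handful of 2D *moment projections* and trains 2D networks on those.

For a volume on the common grid, each anatomical plane contributes up to
two channels: the per-pixel arithmetic mean and the per-pixel standard
deviation of the intensities along the plane's normal axis. The intuition
is that the mean captures average tissue density along a ray, while the
standard deviation captures how variable the tissue is across slices —
empirically the more informative of the two for aging. Skew and kurtosis
channels (standardized third and fourth central moments) are implemented as
extensions but excluded from the default channel set.

Three design points fix the numerical meaning of a projection:

* **Population standard deviation** (divide by the number of slices N, not
  N − 1). Either convention differs only by a constant factor per plane,
  which the network would absorb; one must simply be fixed for
  reproducibility, and we use ÷N.
* Projections are computed over the **full padded extent**, including
  all-zero slices introduced by padding. Padding happens before projection,
  so zero slices deliberately contribute to the moments.
* **No intensity normalization** is applied between loading and
  projection; gray-matter likelihood maps are already on a [0, 1] scale.

Zero-padding to the common grid is symmetric; when a margin is odd the
extra voxel goes to the high-index side. This tie-break is arbitrary but
must be fixed, otherwise two runs can produce images shifted by one pixel.

## The network family

Each plane with at least one selected channel gets a stack of `depth`
(13, 19 or 25) 3×3 convolutions. Filters start at `round(4w)` and double at
each 2×2 max-pool down-sampling to `round(256w)`, with `w` ∈ {0.5, 1, 2}
the width multiplier: two convolutions per resolution level for depth 13,
three for 19, four for 25, plus a single top layer. Batch normalization
follows every 2nd/3rd/4th convolution; a convolution immediately followed
by batch norm carries no bias (its shift would be removed by the
normalization). Layers follow the order convolution → batch norm →
activation → dropout. A global mean pool reduces each stack to `round(256w)`
features, making the stack independent of image size — this is what allows
one set of shared weights (*iso*) to serve the differently-shaped axial
(H×H) and coronal/sagittal (H×Z) images. The concatenated features feed a
dense head `3·256w → 64w → 256w → 640w → 10 → 1` with batch normalization
after the first two hidden layers and a linear output node.

### How the architecture was pinned down

The layer arrangement is not free: the family must reproduce a set of
published trainable-parameter counts exactly, and those counts
over-determine most choices. Writing the count of a two-channel stack as a
polynomial in `w` gives `589,680 w² + 1,084 w`, which matches the filter
schedule above with 3×3 kernels, bias-free normalized layers, and
batch-norm scale/shift counted as trainable — with zero residual. The
difference between 6-channel and 3-channel variants (108 = 3 extra input
channels × 4 first-layer filters × 9) independently forces the 3×3 kernel.
The head total is likewise pinned to `229,376 w² + 7,680 w + 21`, but its
internal split is under-determined (several integer layouts realize it
exactly); we chose the layout above, which reuses the stacks'
bias-free-before-normalization convention. One published value for the
deepest non-shared variant is mutually inconsistent with the rest of the
family under any shared-head architecture (a modular-arithmetic argument
shows no integer stack size can satisfy it); the package reproduces every
other count exactly and the test suite records the single discrepancy.

Two details the counts cannot adjudicate were set by convention: the
activation is ReLU, and down-sampling is 2×2 max pooling with ceiling
division (so 208 → 104 → 52 → 26 → 13 → 7 → 4). Pooling versus strided
convolution does not change parameter counts.

## Training protocol

Training minimizes MSE (years²) with Adam at learning rate 0.003 (default),
runs a fixed number of epochs with per-epoch reshuffling, and overwrites a
checkpoint whenever validation MSE reaches a new minimum; the saved model
is the early-stopping readout while training continues to the budget. Batch
size (default 32) and weight initialization (Glorot-uniform, seeded) are
exposed in the configuration since neither is externally constrained. The
whole packed training set is held resident in memory and reused across
epochs — the central efficiency claim of the projection approach — and the
test suite verifies that no volume files are touched once a dataset is
packed. Determinism is per-device: identical seeds give bit-identical loss
curves on one machine; cross-device floating-point drift is expected.

Running batch norm statistics use momentum 0.1 and epsilon 1e-5; training
batches use biased (÷N) variance. In the dropout-between-conv configuration
(rate 0.2) dropout follows every normalized convolution; in the
between-dense configuration (rate 0.3 or 0.5) it sits between the dense
layers of the head. Parameter counts are identical between the two
placements because dropout has no parameters and batch norm stays in place.
At desk scale the between-conv placement shows a markedly larger
train/validation gap (the known variance-shift disharmony between dropout
and batch normalization is not buffered by small cohorts), so the phantom
age-recovery experiment in the acceptance suite uses the between-dense
variant.

## The phantom generator

The generator exists so every downstream stage is testable without
restricted clinical data. A phantom is an ellipsoidal "head": an outer
shell of high gray-matter likelihood (0.85) around a low interior (0.25)
with a near-zero central ventricle, soft ~1-voxel edges, additive Gaussian
noise clipped to [0, 1], and per-subject morphology jitter. Aging is purely
geometric and linear:

* shell thickness starts at 10% of the smallest grid dimension at the
  youngest age and **halves** across the 44–82-year range (cortical
  thinning, deliberately exaggerated so a few hundred subjects suffice);
* ventricle radius starts at 8% and **doubles** (ventricular expansion).

Per-subject jitter multiplies the head semi-axes by 1 + N(0, 0.03) and
shifts the centre; noise is N(0, 0.05) on the intensity scale. These are
one-time choices of "plausible but learnable" and are not tuned. Ages are
sampled uniformly over integer years; the split assigns floor(0.7n) to
train and floor(0.15n) to validation with the remainder (absorbing
rounding) to test.

What the phantom does *not* emulate: cortical folding, tissue-class
mixtures, scanner artifacts, non-uniform age distributions, sex effects,
or any realistic anatomy. Passing tests therefore demonstrate that the
*pipeline mechanics* — projection, training, checkpointing, ablation —
work and that the architecture can extract a geometric aging signal; they
say nothing about accuracy on real MRI.

## Augmentation

Offline augmentation appends perturbed copies of the training projections:
a composed affine (scale ∈ [0.95, 1.05], shear and rotation within ±5°)
about the image centre followed by an elastic deformation (uniform random
displacement field, Gaussian-smoothed with σ = 8 px, amplitude 2 px),
sampled bilinearly with zero fill. The magnitudes are "small" by
construction and exposed in the configuration. All channels of one plane of
one pseudo-subject share a single transform — mean and std images of a
plane are views of the same anatomy and must deform together. Augmentation
is train-only and refuses other splits; labels are copied unchanged.

## The ablation study

`run_ablation()` trains one model per non-empty subset of the available
channels per learning rate (63 subsets for six channels; the empty set is
untrainable and excluded), records each run's best validation loss, and
computes per-channel marginal contributions: the mean, over all ordered
subset pairs (S, S ∪ {c}) with S non-empty and over learning rates jointly,
of loss(S) − loss(S ∪ {c}). The second learning rate defaults to 0.001.
Best-validation (not final-epoch) loss is used as each run's summary. The
aggregator is validated against brute-force averaging on hand-built loss
tables, independently of any training.

## Numerical choices and degenerate inputs

* Moment images with zero variance report skew and kurtosis 0 (threshold
  std > 1e-12) rather than NaN.
* `pad_to_grid` is an exact identity at the target shape and errors on
  oversize volumes; padding preserves total intensity and maximum.
* The augmentation identity configuration (unit scale, zero angles, zero
  elastic amplitude) reproduces the input bit-exactly: bilinear sampling at
  exact integer coordinates takes the fast path with weight 1.
* Checkpoints embed the full model specification; loading into a different
  architecture fails naming the mismatched field.
* The compiled engine stores feature maps planar (channels-last) and picks,
  per layer, either an im2col+GEMM convolution (wide layers) or a direct
  stencil (narrow layers); the two paths are algebraically identical and
  gradients for both are checked against central finite differences.

## Problem sizes used by the test suite

The acceptance experiments run at deliberate desk scale: 500 phantoms on a
64 × 64 × 52 grid (quarter linear scale of a 256 × 256 × 208 acquisition
grid) for age recovery with a depth-13, width-×0.5, six-channel model
trained 100 epochs; and 48 phantoms on a 32 × 32 × 28 grid, 8 epochs per
subset, for the 126-training ablation. Parameter counting, projection
oracles, augmentation bookkeeping and determinism checks are effectively
instantaneous. The mean-predictor baseline (predict the training-set mean
age for everyone) is the reference the phantom experiment must beat by a
factor of two in MAE.

## Known limitations

* The phantom's age signal is simple and strong; real-world accuracy
  claims cannot be derived from it.
* Determinism is per-device; a different BLAS or CPU can change results at
  floating-point precision.
* On-the-fly (per-epoch) augmentation is not implemented; the augmented
  set is materialized once, which multiplies memory use by 1 + n_copies.
* The dense-head internal layout is one of several exactly count-matching
  realizations; predictions (though not counts) would differ slightly
  under another realization.
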