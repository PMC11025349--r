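---
title: "Methods: calcification segmentation and quantitative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcification segmentation and quantitative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

calcseg implements a three-stage pipeline for breast-calcification analysis
in mammograms: (1) pixel-level segmentation of calcification lesions with a
compact encoder–decoder network, (2) morphological quantification of the
segmented lesions, and (3) benign/malignant classification of the resulting
feature table. Because clinical mammogram collections are not
redistributable, the package ships a phantom generator that produces
images with exact ground truth; every claim the test suite makes is a claim
about these phantoms, not about clinical data.

## The phantom generator

A phantom consists of a smooth tissue-like background plus bright elliptical
lesions:

* **Background.** The sum of a base intensity (0.35) and Gaussian-blurred
  white-noise fields at two correlation lengths (4 px and 32 px, amplitudes
  0.04 and 0.08 after normalisation), plus i.i.d. Gaussian detector noise
  (sd 0.01). Two correlation lengths give the surround-density features
  (`density_32`, `density_8`) something non-trivial to measure.
* **Lesions.** Anti-aliased ellipses with random orientation, eccentricity
  and a low-order harmonic perturbation of the boundary ("irregularity").
  Lesion intensity is added on top of the local background (contrast drawn
  from [0.15, 0.45]), so a mask-positive pixel is always at least as bright
  as the background beneath it — the defining property of calcification on
  a mammogram. Optic blur (Gaussian, sigma 0.7 px) is applied to the lesion
  field only; the stored ground-truth mask is the crisp pre-blur support.
* **Scale.** At the modelled detector pitch of 0.068 mm/pixel, lesions
  under 0.5 mm — the conventional micro-calcification cut-off — are at most
  about 7 px across. The generator enforces this bound on the
  micro-diameter range.
* **Placement.** Rejection sampling with a budget of 100 retries per
  lesion; lesion supports must stay at least 1.5 px apart so the number of
  mask components equals the number of placed lesions (two integer pixel
  centres at distance ≥ 1.5 cannot be 8-adjacent). Clusters are seeded at a
  random centre and their members are placed within the cluster radius.
* **Profiles.** The benign default is few, large, round, scattered lesions
  (4 micro + 6 macro, eccentricity ≤ 1.3, no seeded clusters); the
  malignant default is many, small, irregular, clustered lesions (22 micro
  + 1 macro + 3 clusters of 6–9 members within 22 px). These encode the
  radiological convention the quantified features target. No quantitative
  distribution of benign vs malignant calcification morphology was
  available to calibrate against, so the profiles are reasonable stand-ins,
  chosen once, not fitted to any downstream result.

What the phantoms do **not** emulate: anatomy (pectoral muscle, skin line,
vessels), scanner-specific noise spectra, compression artefacts, or
non-calcific bright structures that cause false positives in practice.
Passing tests therefore demonstrate that the implementation is correct and
that the pipeline can learn and discriminate under controlled conditions —
not that it reaches clinical performance.

## Tiling and stitching

Mammograms are large while calcifications are tiny, so images are processed
as 512×512 crops with 20% overlap (stride `floor(512 × 0.8) = 409`). The
final tile along each axis is clamped flush with the image edge, so no
margin is ever left unsegmented; images smaller than a tile are zero-padded
into a single tile. At inference the per-tile probability maps are stitched
by arithmetic averaging over every tile covering a pixel — an unweighted
combination rule chosen for its idempotence (stitching the tiles of a map
reproduces the map exactly, a property the tests exercise). Binarization
uses a strict `p > 0.5` rule, so ties fall to background.

## Augmentation

Geometric ops (scaling then cropping back to tile shape, affine
rotation/shear/translation) are applied identically to image and mask, with
nearest-neighbour interpolation for the mask so it stays binary;
photometric ops (Gaussian blur, unsharp sharpening, gamma correction,
CLAHE) touch only the image. The grayscale transform is implemented as
gamma correction and the histogram transform as CLAHE; both are
conventional choices for these op names. During training a fresh augmented
view of each tile is drawn every epoch.

Copy-paste augmentation operates on connected components: with a donor
mask of `C` components, `round(ratio × C)` components are chosen uniformly
and each is pasted — image patch alpha-blended by the component mask — at a
uniform random location where its bounding box fits and does not touch an
existing lesion (checked against the recipient mask grown by one pixel, so
pasted lesions never merge with existing ones and component counts add
exactly). A fixed-count selection was preferred over per-component
Bernoulli sampling because it makes augmentation strength reproducible;
placement failures after 100 retries skip the component with a warning.

## The segmentation network

The network is an encoder–decoder in the UNet family with three block
types:

* **Input conv block** (3×3, stride 1, batch norm, ReLU) with *no*
  downsampling, so micro-calcifications of a few pixels are never lost
  before the first feature map;
* **Fused-MBConv blocks** (3×3 expansion conv at expansion factor 4, SiLU,
  squeeze-and-excitation with reduction 4, 1×1 projection, residual where
  shapes allow), each preceded by 2×2 max pooling in the encoder;
* **Tokenized-MLP blocks**: a 3×3 stride-2 patch embedding followed by a
  mixer — spatial channel-group shift (5 groups, offsets −2…2) across
  width, 1×1 token projection, 3×3 depthwise conv, GELU, shift across
  height, 1×1 re-projection, residual add and layer normalisation.

The encoder stacks 1 conv + 4 fused-MBConv + 2 tokenized-MLP blocks with
channel widths 64, 64, 128, 256, 512, 1024, 2048; the decoder mirrors it
(2 tokenized-MLP + 4 conv blocks, widths 1024…64) with learnable 2×2
transposed-convolution upsampling and skip connections at every resolution,
merged by concatenation followed by a convolution (the UNet convention; a
plain additive merge is rejected at build time rather than silently
approximated). A 1×1 convolution and sigmoid produce the per-pixel lesion
probability. For a 512-px input the encoder resolutions are 512, 256, 128,
64, 32, 16, 8 and the decoder mirrors them back up.

`width_divisor` divides every channel width so the identical architecture
runs at desk scale; the default of 1 reproduces the full schedule
(~57 M parameters), while the desk-scale divisor of 8 gives ~0.9 M. All
forward and backward passes are implemented in the package (im2col
convolutions over BLAS in compiled code, hand-written backprop verified
against numerical differentiation in the test suite); inference uses
batch-norm running statistics and is deterministic.

## Losses and the two-phase schedule

Calcification masks are extremely imbalanced (well under 1% positive
pixels), so phase 1 trains with an equally weighted sum of

* **focal loss**, mean of `−α_t (1−p_t)^γ log p_t` with α = 0.25, γ = 2
  (the reference defaults), probabilities clamped to `[1e−7, 1−1e−7]`; and
* **soft Dice loss**, `1 − (2Σpt + s)/(Σp + Σt + s)` with `s = 1e−6`.

Phase 2 fine-tunes the phase-1 best checkpoint with a Hausdorff-distance
surrogate: `mean((p − t)² (D_t^α + D_p^α))` with α = 2, where `D_t` and
`D_p` are unsigned Euclidean distance transforms of the target and the
binarized prediction. Exact Hausdorff distance is not differentiable, so
the distance weights are treated as constants in the gradient; the exact
point-set Hausdorff distance is retained in the test suite as an ordering
oracle. Symmetric weighting (both transforms) is used. The distance
transform of an empty point set is defined as the image diagonal, and the
degenerate all-empty case is fixed to zero. Fine-tuning uses the HD loss
alone (not added to the phase-1 loss) at a tenth of the learning rate —
the reading of "fine-tune with the HD loss" that keeps the two phases
cleanly separated.

## Training protocol

The reference protocol is a 4:1 image-level train/test split, fivefold
cross-validation on the training side, 200 phase-1 epochs, Adam with
cosine-decayed learning rates (1e−3 phase 1, 1e−4 phase 2), per-fold model
selection by validation Dice, and test-time ensembling of the five fold
models by probability averaging before thresholding. Splits and folds are
always at the image level, never the tile level, so tiles of one image
cannot leak between a training fold and its validation fold.

The desk-scale study conditions, fixed once in `desk_train_config()` and
used by the tests and the acceptance script, are: 60 phantoms of 256 px
(48 train / 12 test), disjoint 128-px tiles (~200 training tiles), width
divisor 8, batch size 2, 20 phase-1 epochs and 5 HD fine-tuning epochs —
sizes at which the full pipeline trains in minutes on one CPU core while
still exercising every architectural and loss component. The small batch
doubles the optimisation steps available inside the fixed epoch budget,
which matters far more than gradient smoothness at this scale, and the
desk protocol raises the phase-1 learning rate to 2e−3: with a cosine
schedule compressed to a tenth of the reference epoch count, a larger
initial step recovers part of the optimisation distance the shorter
schedule gives up. Checkpoint
selection uses six training images held out as a validation set. The desk
protocol disables stochastic augmentation: the generator already supplies
arbitrarily many independent phantoms, which removes augmentation's main
benefit (augmentation remains available through `train_config(aug = ...)`
and is exercised by the test suite).

## Evaluation

Dice, specificity, recall and IoU are computed from per-image confusion
counts and averaged across images (the averaged-vs-pooled choice is
recorded in the output). Any 0/0 ratio — an empty ground truth with an
empty prediction — scores 1 and is flagged. The 95% CI on Dice is a
percentile bootstrap over images (2000 resamples by default); classifier
AUC CIs use a stratified bootstrap over test rows. ROC curves are computed
by an explicit threshold sweep with tied scores collapsed, and AUC by the
trapezoid rule, which the tests pin to the Mann–Whitney pairwise statistic.

## Quantification

Components are labelled with 8-connectivity (two diagonal-touching pixels
are one lesion). Geometric conventions, chosen once and used consistently:

* **Perimeter** is the crack-edge boundary length of the pixel region
  (every exposed pixel edge counts 1), so a 10×10 square has perimeter 40
  and roundness `4π·100/40² ≈ 0.785`. This convention makes the closed
  forms exact for rectangles; for digitised disks it overestimates the
  smooth perimeter by up to 4/π, which is immaterial because the features
  are used as relative categories.
* The **minimum-area rectangle** is fitted by rotating calipers over the
  convex hull of the pixel *corner* points, so a single pixel is a 1×1
  rectangle and rectangularity of axis-aligned rectangles is exactly 1.
* **Size** bins are component areas in pixels (< 10, 10–30, > 30).
* **Surround densities** (`density_32`, `density_8`) are mean image
  intensities over the set of pixels within Euclidean distance 32 (resp. 8)
  of the component, excluding the component itself.
* **Clusters**: the mask is dilated with a 16×16 all-ones structuring
  element anchored at `floor(k/2) = (8, 8)` (recorded because even kernels
  are anchor-ambiguous), dilated domains are labelled, and a domain
  containing strictly more than 5 original components is a cluster. The
  cluster area is the dilated-domain pixel count.
* The `_l/_m/_s` category triples use fixed cut points
  (`threshold_config()`), not per-image quantiles, so counts are comparable
  across images. Defaults were chosen once from the phantom intensity and
  size ranges: density (0.50, 0.65), aspect ratio (1.3, 1.8), perimeter
  (14, 32) px, roundness (0.45, 0.62), long side (5, 9) px, rectangularity
  (0.55, 0.70), perimeter ratio (1.02, 1.18).

An empty mask yields zero counts, zero densities and an `empty_flag`.

## Classification

Seven classifiers with common-default hyperparameters and fixed seeds:
decision tree (rpart), logistic regression (glm), RBF SVM (e1071), kNN
(k = 5, class), random forest (200 trees), XGBoost (50 rounds, depth 3)
and AdaBoost. No AdaBoost implementation is available in the dependency
set, so the package implements discrete AdaBoost.M1 with depth-1 rpart
stumps (50 rounds): weighted stump fitting, `α = log((1−err)/err)`,
multiplicative weight updates, and a score equal to the normalised weighted
vote margin mapped to [0, 1] with 0.5 on the decision boundary. Its feature
importances are the α-weighted, normalised stump importances. Features are
standardized (statistics fitted on the training split only) for the
scale-sensitive models (LR, SVM, kNN); tree ensembles consume raw features.
Zero-variance features are dropped with a warning. Accuracy is reported at
the fixed 0.5 threshold rather than an ROC-optimal one.

## Numerical and degenerate-input choices

* Min-max normalisation of a constant input image is defined as all zeros.
* Probabilities are clamped before any logarithm; Dice uses a 1e−6 smooth.
* `binarize` is strict (`>`), so exact-threshold pixels are background.
* Component ordering is deterministic (raster order of first pixel), as is
  every seeded operation; training is deterministic given a seed under
  single-threaded BLAS.
* Shape-ratio features that exceed 1 through digitisation are clipped to 1
  and flagged.

## Known limitations

The phantom realism limits stated above are the main one. Others: the
full-width network is far too slow to *train* on CPU (only its forward
pass is exercised); DICOM input is not supported (no reader in the
dependency set — convert to PNG/TIFF first); the HD loss weights are
recomputed from the binarized prediction each step, which makes phase-2
loss values comparable only within an epoch; and the classifier stage
assumes the feature table fits in memory, which is trivially true at the
scales involved.
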