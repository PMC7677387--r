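---
title: "Automated iliopsoas muscle volumetry: models, parameters and design notes"
author: "psoasvol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated iliopsoas muscle volumetry: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The iliopsoas (psoas major plus iliacus) is the chief hip flexor, and its
size is widely used as an imaging surrogate for sarcopenia and frailty.
Manual cross-sectional-area measurements are slow and inconsistent across
studies, so population imaging calls for fully automated *volumetry*:
segment both muscles in 3-D from the water image of a Dixon MRI
acquisition and report volumes, asymmetry, and a height-normalized index
per subject. `psoasvol` implements such a pipeline end to end — landmark
cropping, normalization, augmentation, a 3-D residual encoder–decoder
trained with a soft Dice loss, cross-validated agreement analysis, and
cohort statistics — together with a phantom simulator that stands in for
cohort data, so every stage is testable on a laptop-class CPU.

## Image model and preprocessing

Inputs are water-signal volumes on a 2.232 × 2.232 × 3.0 mm grid (axis 1
left–right, axis 2 anterior–posterior, axis 3 inferior–superior), one
hip landmark per side, and optional binary annotation masks.

* **Cropping.** Each muscle is processed in a fixed crop (default
  96 × 96 × 192 voxels) anchored on its hip landmark. The anchoring is a
  design choice the source description leaves open: in-plane the box is
  centred on the landmark; along the body axis the landmark sits at 25 %
  of the crop extent from the inferior face, because the muscle extends
  mostly superiorly from the hip. Both fractions are arguments of
  `crop_to_roi()`. Voxels outside the parent volume are zero-filled
  (air), and the crop origin (`source_offset`) is recorded so a predicted
  mask can be re-embedded losslessly.
* **Normalization.** Intensities are divided by the crop's 99th
  percentile and clipped at one, so isolated signal spikes cannot
  compress the dynamic range. The percentile is the linear-interpolation
  (type 7) empirical quantile *per crop*: cropping precedes normalization
  in the stated processing order, so the statistic is local to the region
  the network sees. An all-zero crop is a degenerate-input error.
* **Reflection.** Left crops are mirrored about the first in-plane axis
  so the network always sees right-like anatomy; masks follow the
  identical geometry. Reflection is an involution and swaps the side
  label.

## Augmentation

Per subject and muscle, the original and its mirror image are each
combined with `n_random_transforms` (default 7) random affine
resamplings plus the untouched version: 2 muscles × 2 reflection states
× (1 + 7) = 32 samples per subject, hence 2880 from 90 annotated
subjects. This factorization of the stated "two sets of 16 samples" is
the one that reproduces the printed totals. Translations are uniform
integers up to 6 voxels in-plane and 24 out-of-plane; scaling is uniform
in ±25 % in-plane (one factor shared by both in-plane axes) and ±50 %
out-of-plane, reflecting the larger population variation in muscle
length than width. Scaling is about the crop centre (the source is
silent on the fixation point; the centre is the convention that keeps
augmented anatomy inside the crop). Intensities are resampled
trilinearly, masks with nearest-neighbour under the same map, so labels
stay binary.

## Network

A V-Net-style residual encoder–decoder with SELU activations:

```
I -> D(2,32) -> D(3,64) -> D(3,128) -> L -> U(3,128) -> U(3,64) -> U(3,32) -> F
```

The initial block I applies a 5×5×5 convolution (8 filters) and a
stride-2 2×2×2 convolution (16 filters). Down blocks D(i,m) run i
5×5×5 convolutions with m filters then a stride-2 convolution; up blocks
mirror them with transpose convolutions; the bottleneck L runs three
128-filter convolutions at 1/16 resolution (6 × 6 × 12 for the default
crop); F applies a 16-filter 5×5×5 convolution, a 1×1×1 convolution and
a sigmoid. Every block is residual; long skips join contraction and
expansion at equal resolution.

Design points the source leaves open, resolved here:

* **Skip fusion** is element-wise addition (the residual V-Net lineage);
  a 1×1×1 projection reconciles channel counts where they differ —
  including block I's 1-to-8-channel residual.
* **Initialization** is LeCun fan-in variance scaling, the scheme SELU's
  self-normalizing property assumes.
* **Activation placement**: each convolution is followed by SELU and the
  residual addition comes after the stack, with no activation after the
  add (V-Net convention).
* **width_multiplier** scales every channel count so CPU tests can train
  the identical topology at 1/8 width; it is an addition of this package,
  not part of the reference recipe. Parameter counts scale ≈
  quadratically (the tests assert a ratio of ~4 between widths 1 and ½).

The implementation is a flat tape of six primitive ops (conv, stride-2
down, stride-2 transpose up, SELU, add, sigmoid) over numbered tensor
slots, with im2col + BLAS GEMM convolutions in C++. Forward and backward
are exercised by finite-difference gradient checks in the test suite
(relative errors ~1e-7).

## Training and validation

Soft Dice loss `1 − (2Σpm + ε)/(Σp + Σm + ε)` with ε = 1
voxel-equivalent (avoids 0/0 on empty masks), computed per sample and
averaged over the batch — at batch size 3 per-batch pooling and
per-sample averaging genuinely differ, and per-sample is the standard
V-Net practice. A note on a tempting invariant: the *probability-space*
gradient of the smooth Dice loss does not vanish at a perfect binary
prediction (the unconstrained optimum lies outside [0,1]); the gradient
that reaches the weights passes through the sigmoid and does vanish as
the prediction saturates. The tests check the logit-level statement.

Optimization is Adam (standard moment decays) at learning rate 1e-4,
batch size 3, and a fixed 100-epoch budget with best-loss checkpointing
("until convergence" is operationalized as the fixed budget plus
checkpointing). The learning-rate sweep runs truncated (10-epoch)
probes over 1e-1 … 1e-6 and selects the argmin of final training loss.
Validation is unstratified seeded six-fold cross-validation (90 subjects
→ 75 train / 15 test per fold), per-muscle Dice averaged per subject
(pooled confusion counts available as an option), and Bland–Altman
agreement of predicted vs. manual volumes using percent differences with
the pairwise-mean denominator and 1.96·SD limits.

## Quantification and QC

Volumes are voxel count × voxel volume; the left−right difference is
signed `left − right` (negative ⇒ right larger, matching the reported
convention); the iliopsoas muscle index is IMI = total volume / height²
in ml/m² (heights in cm are auto-converted; the reference table's
"ml/cm²" header is treated as a typo — its values are consistent with
ml/m²). QC screening flags, without dropping records: per-muscle volumes
outside [100, 800] ml (outside the observed population ranges with
margin), relative asymmetry above 0.25, and within-gender total-volume
|z| above 4.

## Population statistics

Shapiro–Wilk gates normality (it rejects for all variables at
population scale, as expected); analyses are therefore rank-based:
Spearman correlations (mid-ranks, t-approximation p), Wilcoxon rank-sum
for gender comparisons, signed-rank for left vs. right. Both Wilcoxon
tests use exact enumeration (all C(n, n_a) rank assignments / all 2^n
sign patterns, mid-ranks for ties) up to total n = 12 and the tie- and
continuity-corrected normal approximation beyond; p-values are
two-sided throughout with 0.05 significance and no multiplicity
correction, mirroring the exploratory stance of the source analysis.
The age trend of IMI is a penalized cubic-regression-spline GAM
(`mgcv`, basis dimension 10, GCV smoothness), reported per gender on an
age grid with a numerical first derivative. The handedness analysis is
a rank-sum test of the left−right difference between right- and
left-handed subjects — the source names no test, so this choice is the
package's own.

## The phantom world

The simulator is a *stated world*, not a tuning dial; its defaults are
fixed once and the tests live with them.

* **Geometry.** Each muscle is a curved centerline (quadratic lateral
  bow, peak 12 mm, in the coronal plane) swept with circular
  cross-sections whose radius follows `r(u) = r_max · sin(πu)^0.5` — a
  fusiform bulge peaking mid-length. Default muscle length 330 mm on a
  96 × 96 × 160 grid at the working voxel size. The peak radius is
  solved in closed form from the target volume, then a global radius
  scale is calibrated by bisection against the voxelized count, so
  achieved mask volumes sit well within the 3 % contract (typically
  0.1 %). Landmarks sit at the inferior end of each centerline.
* **Intensity.** Muscle 0.7, fat rind 1.0, spine-like cylinder 0.45,
  body background 0.1, air 0, then 2 mm Gaussian blur and additive
  Gaussian noise (SD 0.05), clipped at zero. This gives water-image-like
  contrast without modelling MR physics — deliberately: the phantoms
  test the pipeline's mechanics, not MR realism. No bias fields, motion,
  breath-hold stitching or multi-organ anatomy; a green segmentation
  test therefore establishes correctness of the machinery, not clinical
  performance.
* **Demographics.** All covariates are truncated normals at the
  published per-gender moments and printed ranges. The volume model
  works on the IMI scale: IMI = piecewise-linear-in-age + linear-in-BMI
  + Gaussian noise, and total volume = IMI × height². The published
  tables are internally consistent with this factorization — it
  reproduces the printed IMI means and SDs to ~2 % and makes the
  volume–height rank correlation (~0.5) an *emergent* property rather
  than a fitted one. Slopes are solved analytically from the target
  Spearman correlations through the Gaussian identity
  ρ_Pearson = 2 sin(π ρ_Spearman / 6) using numeric moments of the
  truncated age density; the male age trend has a changepoint at 62
  years with a pre/post slope ratio of 0.2 (decline accelerating in the
  early 60s), the female trend a single shallow slope. The left−right
  difference is an independent truncated normal (mean −6.5/−7.3 ml),
  and handedness (89 % right) is simulated independently of asymmetry,
  matching the null association reported.

## Numerical and scale choices

* Coordinates are 0-based voxel indices with half-open extents; the
  reflection axis is the first in-plane axis; out-of-bounds fill is 0.
* NIfTI-1 I/O is implemented directly (no R NIfTI package is available
  in the supported stack): single-file `.nii`/`.nii.gz`, sform-encoded
  voxel size, float64 intensities, uint8 masks; round-trips are
  bit-exact and cross-checked against nibabel in the tests.
* Desk scale: the reference training scale (96×96×192 crops, full
  width, 100 epochs, GPU) is far outside a 1-CPU budget. The test suite
  runs the identical topology at width 1/8 on 32×32×16 crops; the
  six-fold cross-validation acceptance check keeps the full protocol
  (18 phantoms, train 15 / test 3) with 8 epochs at learning rate 1e-3
  and meets DSC ≥ 0.8 with volume bias within ±10 % (measured: pooled
  DSC 0.913 ± 0.069, bias −0.24 %) in about seven CPU minutes. The headline full-scale figures (DSC 0.9046 ± 0.0058, bias
  −0.2 %) are not reproducible without the original cohort; nothing in
  this package claims otherwise.
* Translation covariance of the trained network holds *because of* the
  shift augmentation: trained without it, the model memorizes the
  phantoms' fixed position and the property degrades. The covariance
  test trains with augmentation for exactly this reason.
* Seeds: every stochastic stage derives a stage seed from one global
  seed (string-hashed, kept below 2³¹), so stages are independently
  reproducible and two runs with the same config hash produce
  byte-identical tables.

## Known limitations

Phantoms are geometric idealizations; no claim of MR realism. The
percentile normalization and crop anchoring follow this package's
documented conventions where the source is silent, so absolute numbers
from other implementations may differ at the margin. The statistics
module implements the tests the source analysis used; it is not a
general-purpose statistics library. Separating psoas major from iliacus
(or psoas minor) is out of scope — it is not achievable on standard
Dixon images, which is the reason the composite iliopsoas is measured.
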