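# psoasvol

Fully automated iliopsoas muscle volumetry from water-signal Dixon MRI,
in R.

The iliopsoas (psoas major + iliacus) is the main hip flexor and a
common imaging surrogate for sarcopenia. Manual annotation of both
muscles takes hours per subject, which rules it out for population
imaging. `psoasvol` implements the automated alternative end to end:

* **Preprocessing** — fixed-shape crops (default 96 × 96 × 192 voxels at
  2.232 × 2.232 × 3.0 mm) anchored on per-side hip landmarks,
  99th-percentile intensity normalization (`min(x/p99, 1)`), and
  mid-sagittal reflection so both muscles share one chirality.
* **Augmentation** — per subject: 2 muscles × 2 reflection states ×
  (1 original + 7 random translation/scaling transforms) = 32 training
  samples (2880 from 90 annotated subjects).
* **Segmentation network** — a 3-D residual encoder–decoder
  (U-Net/V-Net hybrid) with SELU activations,
  `I → D(2,32) → D(3,64) → D(3,128) → L → U(3,128) → U(3,64) → U(3,32) → F`,
  5×5×5 convolutions, stride-2 2×2×2 resolution transitions, additive
  long skips and a final sigmoid — implemented from scratch (forward and
  backward) on Rcpp/BLAS, with a `width_multiplier` for CPU-scale runs.
* **Training/validation** — soft Dice loss
  `1 − (2Σpm + ε)/(Σp + Σm + ε)`, Adam (lr 1e-4, batch 3, 100 epochs,
  rate selected by a 1e-1…1e-6 sweep), six-fold cross-validation
  (75 train / 15 test), Dice score `DSC = 2TP/(FP + 2TP + FN)` and
  Bland–Altman agreement (bias ± 1.96 SD of percent differences).
* **Quantification** — per-subject left/right/total volumes (ml),
  signed left−right difference, iliopsoas muscle index
  `IMI = total volume / height²` (ml/m²), and QC flags (bounds,
  asymmetry, outliers).
* **Population statistics** — Shapiro–Wilk normality gate, Spearman
  correlations, Wilcoxon rank-sum and signed-rank tests (exact
  enumeration for n ≤ 12), penalized cubic-spline (GAM) age trends.
* **Phantom simulator** — Dixon-like volumes with ground-truth bilateral
  fusiform muscles, hip landmarks, and demographic cohorts matching the
  published population distributions, so the whole pipeline runs and is
  tested without any cohort data.

## Worked example

Simulate a cohort parameterized from the published population tables,
quantify it, and run the standard analyses:

```r
library(psoasvol)

cohort  <- generate_cohort(cohort_params(), n_female = 2496, n_male = 2504,
                           seed = 17)
records <- records_from_cohort(cohort)
analyze_cohort(records)
```

```
<cohort_analysis> 5000 subjects
  male vs female total volume: p = 0
  L-R mean difference d (ml): female -5.996, male -6.056
  Spearman rho(volume, height): female 0.539, male 0.500
  Spearman rho(IMI, BMI): female 0.484, male 0.467
  Spearman rho(IMI, age): female -0.164, male -0.288
  handedness vs asymmetry: p = 0.668
```

Male volumes exceed female, the right muscle is systematically larger
(d < 0 with the left-minus-right sign convention), volume tracks height,
IMI tracks BMI, and IMI declines with age about three times faster in
men — with the decline accelerating after the early 60s (see the spline
trend in `fit_age_trend()`).

A desk-scale imaging run — phantoms → crops → training → segmentation →
quantification → stats — fits in a couple of minutes:

```r
cfg <- pipeline_config(out_dir = "out", seed = 3, n_subjects = 12)
run_pipeline(cfg)                      # writes NIfTI, CSV and JSON artifacts
```

and the same is scriptable per stage from the shell:

```sh
Rscript inst/cli/psoasvol run-all --out-dir out --seed 3 --n 12
```

Seeded six-fold cross-validation of the desk-scale network on 18
phantoms (the package's stand-in for the full-scale validation, which
needs the original cohort and GPU training) reaches a pooled
out-of-sample DSC of 0.913 ± 0.069 with a Bland–Altman volume bias of
−0.24 % in ≈7 CPU-minutes; the test suite asserts DSC ≥ 0.8 and
|bias| ≤ 10 %.

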