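---
title: "Methods: synthetic cine phantoms, segmentation transfer learning, and agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cine phantoms, segmentation transfer learning, and agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cinefunc)
```

`cinefunc` implements a complete left-ventricular (LV) analysis chain for
short-axis cine image stacks: synthetic phantom generation with analytic
ground truth, a compact segmentation network trained with a two-step
frozen/unfrozen transfer schedule, mask/contour conversion with a
plain-text contour dialect, ED/ES volumetrics, and observer/model
agreement statistics. This vignette documents the models, the default
parameters and their rationale, and the numerical conventions that
downstream results depend on.

## The synthetic cine phantom

A short-axis cine scan is a stack of `n_slices` parallel slices, each
imaged at `n_phases` time points across the cardiac cycle. The phantom
emulates the LV as a bright circular blood pool (label 1) surrounded by
an annular myocardium (label 2) on a dark background (label 0):

* **Geometry.** Per labeled slice the end-diastolic endocardial radius is
  either given explicitly or tapered linearly from base to apex. The
  outermost `empty_slice_margin` slices at each end of the stack carry
  images but *empty masks*, emulating basal/apical slices with no
  labelable LV. Defaults mirror a high-resolution small-animal
  acquisition: 0.4 × 0.4 mm in-plane spacing, 6 mm slice thickness, 13
  slices, 30 phases.
* **Contraction.** The cavity radius scales by
  `1 - contraction_fraction * w(p)` where `w` is a smooth cosine weight,
  0 at end-diastole (phase 1) and 1 at end-systole (phase
  `floor(0.4 * n_phases) + 1`). Since slice area scales with the radius
  squared, the analytic ejection fraction is
  `100 * (1 - (1 - contraction_fraction)^2)`; the default 0.37 yields
  about 60 %, a healthy baseline.
* **Infarct.** An `infarct_spec()` thins the wall by a fixed fraction
  inside an angular sector on selected slices, and the study pipeline
  additionally reduces the contraction fraction of infarct animals —
  jointly lowering EF and LV mass as expected after coronary occlusion.
* **Papillary muscles.** Rendered as darker disks *inside* the cavity but
  labeled as blood pool, following the convention of not excluding
  papillary muscles from the blood-pool volume. They matter for the
  segmentation task (intensity is not a label proxy) and for contour
  tracing (holes are filled).
* **Rasterization.** A pixel belongs to a region iff its center lies
  inside the continuous boundary (pixel-center rule). The analytic
  volumes are computed from the continuous geometry
  (`sum(pi * r^2 * dz)`), so the voxel-counted volumes converge to the
  analytic ones as the pixel spacing shrinks — a property the test suite
  asserts.

```{r phantom}
cfg <- phantom_config(n_slices = 5, n_phases = 8, image_size = 48,
                      endo_radius_px = c(11, 9, 7), wall_thickness_px = 5,
                      empty_slice_margin = 1, seed = 1)
ph <- generate_phantom_stack(cfg)
ph$ground_truth$analytic_ef_percent
```

### Image quality and degradation

Image quality uses a 3-category ordinal score (artefacts, noise, general
image quality), each rated 1 (best) to 4 (worst), summed to a total in
3–12. `inject_degradation()` maps the ratings onto three independent
channels: additive Gaussian noise (sd `0.04 * (noise - 1)`),
multiplicative low-frequency shading bands emulating B0/B1 field
inhomogeneity (amplitude `0.12 * (artefacts - 1)`), and Gaussian blur
(sigma `0.6 * (general - 1)` px). A score of (1, 1, 1) is the identity;
label masks are never degraded. The channel gains were chosen so that the
worst rating visibly degrades but does not destroy the LV; they are study
conditions of the synthetic generator, not fitted quantities.

### Realism limits

The phantom is deliberately minimal: circular cross-sections, no
through-plane motion, no trabeculation, no flow artefacts, and
multiplicative observer jitter rather than a full delineation model.
It is sufficient to exercise every algorithmic path (empty slices,
infarct asymmetry, papillary holes, quality degradation) and to provide
exact analytic ground truth, but Dice/HD levels obtained on it do not
transfer to real cine data.

## Segmentation model and transfer schedule

The segmentation network is a compact 2-level U-Net implemented in plain
R: two 3×3 convolution blocks, a 2×2 mean-pool, two bottleneck
convolutions, nearest upsampling with a skip concatenation, a fusion
convolution, and a 1×1 three-class head. The head is the designated
*final parameter group*. Training minimizes a soft (generalized) Dice
loss with Adam under a one-cycle learning-rate policy (linear warmup from
`max_lr/10` over the first 30 % of iterations, cosine annealing to
`max_lr/100`).

Transfer learning is emulated end to end: `pretrain_model()` fits the
network on a *source* phantom distribution (different geometry scale, no
papillary features), then `train_transfer()` adapts it to the target
distribution in two phases:

1. **Frozen:** only the head trains (`frozen_epochs`, default 100, at
   `frozen_max_lr`, default 1e-4).
2. **Unfrozen:** all parameters train (`unfrozen_epochs`, default 100, at
   `unfrozen_max_lr`, default 1e-5).

A checkpoint with its validation Dice is stored every
`checkpoint_every` epochs (default 10) and the checkpoint with the
highest validation Dice over both phases is selected. The contract —
frozen phase leaves non-head parameters bit-identical, checkpoint counts
equal `epochs / checkpoint_every`, selection maximizes validation Dice —
is asserted by the acceptance tests. Optional augmentation mirrors a
standard cine recipe: left–right flips, rotations up to 90°, lighting
changes of 0.4, zoom up to 1.2 (geometric transforms applied jointly to
image and mask, photometric to the image only).

The default *desk-scale* problem sizes in `run_config()` (48 px
phantoms, 32 px model input, 8 base filters, 6 + 4 epochs) are this
package's own choice: they keep a full study run under a minute on one
CPU while still reaching high validation Dice on clean phantoms. They
are not claims about any particular acquisition.

## Contours and the CON-TXT dialect

Boundaries are traced as the 0.5 iso-contour of the binary region
indicator on a zero-padded grid, so vertices sit on half-pixel positions
between foreground and background pixel centers. The endocardial contour
bounds the cavity (label 1, holes filled); the epicardial contour bounds
the union of cavity and myocardium. Rasterization back to masks uses
strict point-in-polygon tests of pixel centers, which makes
`mask -> contours -> mask` pixel-exact on simply connected regions.

Numerical conventions, fixed for all round trips:

* Coordinates are **1-based** pixel indices with `x = column`,
  `y = row` (the native R matrix convention; a 0-based dialect would
  invite off-by-one errors at every boundary with R code).
* Files use the plain-text CON-TXT v1 dialect (UTF-8, LF): a header
  (`#CONTXT 1`, `scan <id>`, `spacing <dx> <dy> <dz>`) followed by
  `contour <slice> <phase> <endo|epi> <n>` blocks. Coordinates are
  printed with 17 significant digits, so write → read → write is
  byte-identical.

## Volumetrics

Per phase, the blood-pool volume is the label-1 voxel count times the
voxel volume. ED is the phase with the largest and ES with the smallest
blood-pool volume (ties: earliest phase; the study pipeline pins ED/ES
to the ground-truth phases for all raters so that parameter differences
reflect delineation, not phase choice). Derived parameters:
`SV = EDV - ESV`, `EF = 100 * SV / EDV` (flagged `NA`, never 0, when
`EDV = 0`), and LV mass as (epicardial − endocardial volume at ED) times
the conventional myocardial density 1.05 g/ml. Slices with empty masks
at ED or ES contribute zero volume and are counted in
`n_missing_slices`, since missing labels artificially reduce volumes.

```{r function}
vcfg <- volumetry_config(c(0.4, 0.4), 6)
compute_function(ph$ground_truth$masks, vcfg)
```

## Agreement metrics

* **Dice** `2|A∩B| / (|A|+|B|)` on filled regions (cavity for LV, the
  myocardial ring for MY). One empty region scores 0; both empty is
  undefined (`NA`) and excluded from aggregation.
* **Hausdorff distance** between boundary point sets (endocardial
  contours for LV, epicardial for MY): the symmetric maximum of directed
  minimum distances. One absent contour gives `+Inf`; both absent,
  `NA`. Distances default to **pixels** (`hd_units = "px"`), because the
  synthetic grid is the natural unit; millimetre output is a
  multiplication by the pixel spacing away.
* **Aggregation**: mean for Dice, median for HD. Infinite HDs
  participate in the median — `cap_hd()` (cap 100) exists for plotting
  only and never enters aggregation.
* **Prediction status**: against a manual reference, images without
  reference labels are *excluded*; empty predictions with nonempty
  references are *missing*; otherwise the myocardium Dice decides
  *correct* (≥ `tau`) vs *incorrect*. `tau = 0.5` is an operational proxy
  for a visual correctness check and should be reported with results.

## Reproducibility statistics

For paired per-scan series of one parameter (EF, SV, LV mass, EDV, ESV)
from two raters:

* **Bland–Altman**: bias (mean difference) and limits of agreement
  `bias ± 1.96 SD`.
* **ICC**: two-way mixed-effects, absolute agreement, *single measure* —
  ICC(A,1) from the ANOVA mean squares. Single-rater agreement is the
  quantity of interest when asking whether one observer could replace
  another. Identical duplicated series give ICC = 1 exactly; zero total
  variance leaves it undefined (`NA`).
* **CoV**: `100 * SD(a - b) / grand mean`, the grand mean taken over all
  values of both series. This denominator reproduces CoV = 0 % exactly
  for identical series; a per-pair-mean denominator is available
  explicitly since the convention is stated ambiguously in the field.
* **Paired t-tests** (two-sided) with Bonferroni threshold
  `overall_alpha / m` (default 0.05 / 4 = 0.0125). Each vector is
  checked with a Shapiro–Wilk test; a rejection warns but does not block
  the t-test, mirroring common practice of reporting the parametric test
  alongside the normality caveat.
* **Relative deviation**: `100 * |bias| / reference mean`, e.g. a
  2.35 ml bias at a 43.4 ml mean is 5.4 %.

```{r stats}
ef_a <- c(61.2, 48.7, 55.3, 63.9, 44.1, 58.8)
ef_b <- ef_a + rnorm(6, 0.5, 1)
agreement_stats(paired_series("EF", ef_a, ef_b))
```

## The study pipeline

`run_study()` chains all stages deterministically from one master seed:
cohort generation with per-animal geometry jitter and quality-graded
degradation, three simulated observers (first observer, a repeat by the
same observer, and a second observer with larger jitter plus a
systematic bias), an animal-wise group-stratified split (no animal's
scans straddle subsets), pretraining and transfer training, test-set
prediction with contour export, cardiac function with pinned ED/ES,
pairwise agreement (intra-observer, inter-observer, model vs first
observer) and the per-parameter statistics. All intermediates are
persisted as CSV/JSON when `out_dir` is set; identical config and seed
reproduce every table bit for bit.
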