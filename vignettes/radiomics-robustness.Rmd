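---
title: "Robustness of carotid CTA texture radiomics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness of carotid CTA texture radiomics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radicc)
```

## The problem

Texture radiomics promise to read plaque biology out of routine carotid CT
angiography (CTA): culprit arteries — those on the side consistent with a
patient's stroke or TIA — may carry wall-texture signatures that calcium
scoring alone misses. But radiomic features are notoriously sensitive to
choices nobody standardises: who drew the region of interest (ROI), whether
intensities were normalised or resegmented, how grey levels were discretised,
and how anisotropic voxels were resampled. A feature that changes class when
the ROI grows by one voxel is clinically useless however discriminative it
looks in one dataset.

`radicc` implements the full robustness-then-classification workflow for
this setting: perturb the segmentation systematically, extract 93 unfiltered
texture features under a grid of 19 pre-processing/quantisation settings,
categorise each feature's stability by intraclass correlation, prune
redundancy, and compare cross-validated culprit/non-culprit classifiers.
Because clinical carotid CTA datasets are not freely redistributable, the
package ships a synthetic phantom generator that reproduces the *statistical
structure* the analysis relies on, so every stage is testable end to end.

## The phantom cohort

`generateCohort(phantomConfig())` builds paired arteries for `nPatients`
patients (default 41, i.e. 82 arteries), each a concentric structure per
axial slice:

* a contrast-filled lumen (`lumenHu`, default 400 HU, with a per-artery
  bolus factor of 0.75–1.25),
* an annular wall carrying a correlated Gaussian random field
  (`wallHuMean` 65 HU, within-artery SD `wallHuSd` 25 HU), produced by
  spatially smoothing white noise — chosen because co-occurrence and
  run-length features respond directly to correlation length,
* 0–3 calcific blobs (> 300 HU) of random size, spanning nearly
  plaque-free to heavily calcified arteries,
* a perivascular compartment of fatty tissue (`fatHu` −80 HU) mixed with
  per-artery patches of muscle-like tissue (~45 HU).

The binary mask encompasses the whole vessel (lumen, wall, calcium) plus a
one-voxel margin into the perivascular ring, so ROI dilation and erosion
genuinely change fat, muscle and contrast content — the stressor the
robustness analysis is about. Single-slice mode is a depth-1 grid at
0.4 × 0.4 × 0.625 mm; multi-slice mode is 14 slices at 3 mm thickness,
with wall and perivascular textures evolving along the artery as an AR(1)
process (mixing 0.8 per slice) because real vessel texture is continuous
in z.

Two design points deserve emphasis:

* **Between-artery heterogeneity is essential, not decoration.** The ICC
  that defines robustness compares perturbation-induced variation against
  between-subject variation. Real cohorts vary enormously (vessel calibre,
  wall attenuation, calcification burden from zero to extreme, contrast
  density); a phantom of near-identical arteries would make every feature
  "poor" by construction. The generator therefore draws per-artery anatomy
  and attenuation from wide distributions.
* **The class effect is a texture effect.** `textureEffect` (default 0.4)
  multiplies the culprit wall's smoothing-kernel width and texture SD.
  With `textureEffect = 0` the two classes are identical in law, which the
  test suite exploits for calibration checks. The emulated study gives no
  quantitative plaque-texture statistics, so the default is the package's
  own choice of a moderate, recoverable effect; it is deliberately not a
  published fact.

The calcium covariate is *sampled*, not measured from the image: per class
from lognormal laws calibrated once to the summary medians and IQRs of the
emulated cohort (culprit meanlog log 263, sdlog 1.5; non-culprit meanlog
log 387, sdlog 1.6). The distributions overlap heavily, making calcium a
deliberately weak predictor. Note that a fitted calcium-only classifier can
learn the sign of the weak association, so its cross-validated AUC tends to
sit slightly above 0.5 even though the raw feature's AUC is below 0.5.

## Pre-processing and quantisation

`enumerateSettings()` builds the 19-cell grid per analysis mode:

| scheme       | quantisation            | values            |
|--------------|-------------------------|-------------------|
| original     | fixed bin width (HU)    | 10, 15, 20, 25, 30, 35 |
| original     | fixed bin number        | 8, 16, 32, 64, 128, 256 |
| normalised   | fixed bin number        | 8, 16, 32, 64, 128, 256 |
| resegmented  | fixed bin width         | 25 only           |

Normalisation z-scores the whole image (mean 0, SD 1, no rescaling
constant); on z-scored intensities a 10–35 "HU" bin width leaves almost no
grey levels, which is why the normalised scheme only pairs with fixed bin
numbers. Resegmentation restricts the mask to voxels in [0, 200] HU
*inclusive*, excluding perivascular fat and dense calcium/contrast, and is
analysed at bin width 25 only (the default of the reference extraction
software).

Quantisation conventions, since edge rules change texture matrices:

* Fixed bin width anchors bins at the ROI minimum:
  `level = floor((v - min)/bw) + 1`. The anchor is an ROI statistic — never
  a whole-image statistic — and a constant ROI occupies a single level.
* Fixed bin number uses equal-width bins spanning the ROI range with a
  closed upper edge (the maximum maps to level `nb`).
* Both are monotone, and fixed-bin-number levels are invariant to affine
  intensity maps — hence normalise-then-quantise equals quantise for that
  method, a property the tests assert.

Multi-slice volumes are resampled to 1 mm isotropic before feature
extraction, with the image interpolated either by prefiltered cubic
B-spline (recursive prefilter, mirror boundaries; the interpolant passes
through the input samples) or trilinearly. The mask always uses nearest
neighbour so it stays binary; the image interpolator alone defines the
B-spline/linear comparison.

## The 93 features

`featureRegistry()` pins 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14
GLDM and 5 NGTDM feature names; `extractAll()` always returns exactly these
93, in this order. Conventions, all at chessboard distance 1:

* GLCM/GLRLM are direction-resolved — 4 in-plane directions in single-slice
  (2D) mode, 13 directions in multi-slice (3D) mode — with features
  computed per direction and averaged. Matrices are symmetrised.
* GLSZM zones use 8-connectivity (2D) / 26-connectivity (3D).
* GLDM dependence uses tolerance α = 0; the dependence size `j` counts the
  centre voxel plus its dependent neighbours, so an isolated voxel has
  `j = 1` and the centre of a constant 3×3 slice has `j = 9`.
* NGTDM excludes voxels with no in-mask neighbour from the voxel total.
* First-order statistics use the raw (pre-quantisation) intensities except
  entropy and uniformity, which use the discretised histogram. Variance,
  skewness and kurtosis are population moments; kurtosis is not
  excess-corrected.
* Degenerate guards: a single-voxel ROI has undefined GLCM features
  (returned as `NA` with a warning); a flat NGTDM returns the standard
  large-value Coarseness guard (1e6); a zero-variance correlation returns 1.

Every feature is verified against an independent brute-force oracle
(exhaustive neighbour enumeration, naive loops) on random masked ROIs to
1e-8, and the direction-averaged classes are checked to be invariant under
90° rotation and under global HU shifts.

## Perturbation and robustness

`generateVariants()` emulates inter-observer variability with binary
morphology using the discrete radius-1 ball (5-voxel cross in 2D, 7-voxel
octahedron in 3D):

* single-slice: erode ×2, erode ×1, original, dilate ×1, dilate ×2 (k = 5);
* multi-slice: one erosion only, so enough voxels survive (k = 4);
* resegmented scheme: dilations only (k = 3).

Eroded variants must keep at least `minVoxels` (default 10 — the guard the
emulated workflow describes qualitatively without a number) or the sample
is excluded with a log entry. Variants nest by construction, and Dice
agreement with the original decreases monotonically with perturbation
strength. A simulated second observer (independent boundary-voxel flips)
provides an inter-observer Dice distribution alongside.

Robustness treats arteries as subjects and mask variants as raters in a
two-way mixed-effects, single-rater ICC:

* consistency: ICC(3,1) = (MS~R~ − MS~E~) / (MS~R~ + (k−1) MS~E~)
* absolute agreement: ICC(2,1) = (MS~R~ − MS~E~) /
  (MS~R~ + (k−1) MS~E~ + k/n (MS~C~ − MS~E~))

Categories: poor (< 0.5), moderate (0.5–0.9), excellent (≥ 0.9).
Categorisation uses the absolute-agreement form; the consistency form is
reported alongside and drives the interpolation-method comparison.
Negative small-sample estimates are kept as computed (categorised poor) —
truncating at zero would bias the poor/moderate boundary. All-equal cells
yield an undefined ICC, counted with poor in summaries. Both forms are
verified against a `stats::aov` two-way ANOVA oracle to 1e-10.

## Classification

Only excellently robust features enter classification. Redundancy pruning
removes, within every pair with Spearman |ρ| ≥ 0.95 (processed in
descending |ρ|), the feature with the lower univariate rank AUC; AUC ties
break to the lexicographically first name so the result is deterministic.
The univariate AUC is the Mann–Whitney statistic with midranks — identical
to the AUC of a univariate logistic score, and never flipped below 0.5.

Six classifiers are compared, each pinned explicitly and seeded with random
state 42: decision tree (impurity splitting, unlimited depth), random
forest (100 trees), LASSO and elastic-net logistic regression (mixing 0.5,
fixed penalty 1/n — the unit inverse-regularisation convention, no tuning),
a one-hidden-layer perceptron (8 units), and gradient-boosted trees
(100 rounds). Evaluation is five-fold stratified cross-validation after a
single seeded shuffle, with features standardised to mean 0/variance 1.
Standardisation statistics come from the training folds only by default
(`scaleMode = "infold"`); the emulated workflow standardises before CV
without stating fold handling, so a `"global"` toggle preserves that
behaviour for comparison. Feature selection (robustness + redundancy) runs
on the full table before CV, exactly as the emulated workflow orders its
steps — a documented leakage caveat that the null-calibration tests bound:
with the class effect off, mean CV AUCs stay near chance because the
selection steps use labels only to break ties among near-duplicate
features.

Model comparisons follow the workflow's trio — calcium-only,
radiomics-only, and the integrated model — under identical fold
assignments, with:

* DeLong's placement-value test on the pooled out-of-fold scores (verified
  against both an established implementation and a stratified bootstrap),
* the Wilcoxon signed-rank test on the five paired fold AUCs, using the
  normal approximation *without* continuity correction and dropping zero
  differences: five one-signed differences give W = 0, μ = 7.5,
  σ = √13.75, z = −2.0226, two-sided p = 0.0431 — the convention that
  reproduces the printed p = 0.043 of the emulated analysis. An exact-
  distribution mode exists for untied differences.
* The accuracy interval is the percentile interval of fold accuracies (the
  emulated report does not state its CI method).

## Numerical and scale choices

Problem sizes in the tests and acceptance script are the package's own
choices for a single-CPU desk run: phantoms use a 40-voxel in-plane grid
(vessel ≈ 10 mm across at 0.4 mm pixels, masks of ~400–600 voxels), the
recovery experiments use the study-sized 41-pair cohort over 20 seeds at
the resegmented bin-width-25 setting (the workflow's final-model setting),
and the scheme-contrast experiment uses 20-pair cohorts. Monte-Carlo
calibration tests use per-artery summary statistics, which are iid across
arteries, so their KS tests are exactly calibrated.

## What passing tests do and do not show

The phantom reproduces the structure the method needs — paired classes, a
texture-borne class effect, confounders (fat, muscle, calcium, contrast)
inside the dilated masks, heavy between-artery heterogeneity — so green
tests demonstrate that the pipeline measures robustness correctly, that
resegmentation removes confounder-driven instability (the poor-feature
count drops relative to the original scheme), and that an injected wall
texture effect is recovered through the full selection-plus-classification
chain while vanishing under the null.

They do not certify clinical numbers. The phantom's wall signal is cleaner
and its perivascular confounders sharper than real plaque, so robustness
*proportions* differ from those of any real cohort even when directions
match. Its voxel-scale intensity grain also makes features more sensitive
to the interpolator than smooth-kernel clinical CTA, where the two
interpolations agree almost universally; on the phantom, absolute agreement
between B-spline and linear resampling is markedly lower, with systematic
per-method offsets (B-spline overshoot at sharp lumen/fat edges). Realistic
anatomy (bifurcations), scanner reconstruction effects, DICOM handling and
Agatston scoring are out of scope.
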