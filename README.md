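# radicc

Robustness analysis of carotid CT angiography (CTA) texture radiomics under
segmentation perturbation, and culprit-artery classification with the
features that survive.

## The problem

After a stroke or TIA, carotid CTA shows which artery is stenosed — but
texture radiomics of the vessel wall may also carry plaque-biology
information that calcium scoring misses. Radiomic features, however, are
fragile: they shift with the observer's ROI outline, with intensity
pre-processing (normalisation, HU-range resegmentation), with the grey-level
quantisation rule, and with the interpolator used for isotropic resampling.
`radicc` quantifies that fragility and carries only the stable features
forward into classification.

The workflow:

1. **Perturb** each artery's binary mask by morphological dilation/erosion
   (radius-1 disc/sphere, 1–2 iterations) to emulate inter-observer
   variability.
2. **Extract** 93 unfiltered radiomic features — 18 first-order, 24 GLCM,
   16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM — under a 19-setting grid of
   pre-processing schemes (original / normalised / resegmented to
   [0, 200] HU) × quantisation (fixed bin widths 10–35 HU, fixed bin
   numbers 8–256), in single-slice (2D) or multi-slice (3D, resampled to
   1 mm isotropic by cubic B-spline or trilinear interpolation) modes.
3. **Categorise robustness** per feature with the two-way mixed-effects,
   single-rater intraclass correlation across mask variants (subjects =
   arteries, raters = variants):
   ICC(2,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + k/n (MS_C − MS_E)),
   with poor (< 0.5), moderate (0.5–0.9) and excellent (≥ 0.9) classes;
   segmentation agreement itself is measured by the Dice coefficient
   DC = 2|X∩Y| / (|X|+|Y|).
4. **Prune redundancy** among excellent features: within every pair with
   Spearman |ρ| ≥ 0.95, keep the feature with the higher univariate
   rank AUC.
5. **Classify** culprit vs non-culprit arteries (five-fold stratified CV,
   six pinned classifiers incl. elastic-net logistic regression with
   mixing 0.5) and compare calcium-only, radiomics-only and integrated
   models with DeLong's test on pooled out-of-fold scores and the Wilcoxon
   signed-rank test on fold AUCs.

Clinical carotid CTA cohorts are not redistributable, so the package ships
a synthetic phantom generator (`generateCohort()`): paired culprit /
non-culprit arteries with contrast-filled lumen, textured wall
(Gaussian random field; the culprit class differs by a controllable
correlation-length/variance effect), calcific blobs, heterogeneous
perivascular fat/muscle, and a weakly informative lognormal calcium
covariate. Every downstream stage is testable without any download.

## Worked example

```r
library(radicc)

cfg     <- phantomConfig(nPatients = 41, seed = 7)   # 82 arteries
cohort  <- generateCohort(cfg)
setting <- settingSpec("resegmented", "fixed_bin_width", 25)

se <- extractFeatures(cohort, setting)     # 93 features x (82 x 3 variants)
rt <- robustnessTable(se, settingId(setting))
robustnessSummary(rt)
#>        class  n excellent excellent_pct moderate moderate_pct poor poor_pct
#> 1 firstorder 18        18         100.0        0         0.00    0        0
#> 2       glcm 24        24         100.0        0         0.00    0        0
#> ...
#> 7      Total 93        91          97.8        2         2.15    0        0

excellent <- rt$feature[rt$category == "excellent"]
tab       <- featureTable(se, settingId(setting))
selected  <- redundancyFilter(tab[, excellent], tab$label)
length(selected)        # 46 non-redundant robust features

cmp <- compareModels(tab, selected)        # elastic net, seed 42
cmp$calcium
#> Cross-validated elastic_net: mean AUC 0.565 (SD 0.141), accuracy 54.4%
cmp$integrated
#> Cross-validated elastic_net: mean AUC 0.908 (SD 0.069), accuracy 83.9%
cmp$wilcoxon_integrated_vs_calcium
#> [1] 0.04310447
```

Reading: under HU-range resegmentation nearly all features are robust to
ROI perturbation on this phantom (the confounding fat/calcium voxels are
excluded), the injected wall-texture effect makes the radiomic model far
outperform the deliberately weak calcium covariate, and with all five fold
AUCs favouring the integrated model the signed-rank comparison lands at its
five-fold one-signed value p ≈ 0.043. Under the original (unresegmented)
scheme the same phantom yields many poorly robust features — the
perturbation-absorbed perivascular fat drives low-grey-value features
unstable. `runPipeline()` wires all stages together and writes
CSV/JSON artefacts plus a run log.

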