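---
title: "Robustness-screened radiomics benchmarking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness-screened radiomics benchmarking: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`radstab` studies a question that matters whenever quantitative image
features feed predictive models: *which features survive realistic
perturbations of the imaging pipeline, and which selector-classifier
combinations build stable models from the survivors?* The package
implements the full chain — synthetic CT tumour phantoms, image
standardization, handcrafted radiomics extraction, perturbation-based
robustness screening by the intraclass correlation coefficient, a
four-stage feature-selection cascade, a selector-by-classifier
cross-validated benchmark, and survival follow-through — as tested,
reusable R functions.

## The phantom cohort

Real contrast-CT liver-tumour cohorts with outcome labels are rarely
shareable, so the package ships a generator whose output has the
statistical structure the downstream analysis assumes:

* **Geometry.** Each tumour is an ellipsoid whose radius is modulated by
  low-order spherical-harmonic jitter (three harmonic orders, RMS
  amplitude 10% of the radius), so shape features vary across subjects.
  Diameters are drawn from a truncated log-normal anchored at a 59.68 mm
  median within 10.40–153.33 mm, the range typical of intermediate-stage
  hepatocellular carcinoma; reduced ranges are used in examples and tests
  purely for compute scale, and every such reduction is stated where it
  happens.
* **Intensity.** Background attenuation is 60 HU (arterial-phase liver
  parenchyma); the tumour interior adds a class-dependent mean shift plus
  a Gaussian random field obtained by Gaussian-smoothing white noise at a
  class-dependent correlation length, and white Gaussian quantum noise
  (default SD 10 HU) is added everywhere. The texture field makes
  second-order features class-informative in a controllable way.
* **Classes.** Label 1 ("disease control") and label 0 ("progression")
  differ in mean shift and correlation length by the `effect` parameter
  (default 20 HU and 1.5 voxels, centred on 35 HU and 2.25 voxels). With
  `effect = 0` the label is independent of image content, which is the
  null configuration used for calibration tests. The 70/30 class split of
  the emulated cohort is reproduced exactly by construction.
* **Survival.** Event times are exponential, median 18 months for
  controls, hazard multiplied by `hr` (default 2.49) for progressors; a
  single administrative censoring horizon is solved numerically to hit
  the requested censoring fraction (default 0.35). These defaults are free
  parameters of the generator, not estimates: no intensity or texture
  statistics of the real tumours are available to fit them.

Per-subject seeds are derived from the global seed by stable label
hashing, so regeneration is bit-identical and independent of evaluation
order. What the phantoms deliberately do **not** model: anatomy
surrounding the tumour, contrast-phase dynamics, scanner/kernel
variation, and segmentation disagreement between observers. Passing tests
on phantoms therefore demonstrates correctness of the machinery and
calibration of the statistics, not clinical performance.

## Image standardization

The chain is `resegment` (keep voxels in (−1000, 400) HU) →
`adaptive_window` → `denoise` (Gaussian, σ = 0.5 voxel) →
`normalize_and_equalize` (0–255, 256-bin histogram equalization) →
`select_informative_slices` (the 3 consecutive axial slices with maximal
tumour area, ties toward the smaller index) → `crop_to_bbox` (224 × 224,
1 px = 1 mm at base spacing, zero-padded). Design choices that were
genuinely open:

* The source material lists the standardization steps without a binding
  order; intensity operations run before slice selection so all three
  slices share one transform.
* The adaptive window has no published formula; it is defined as centre =
  in-mask mean, width = twice the inner 1st–99th percentile spread,
  floored at 1 HU, which makes windowing idempotent and robust to
  outlier voxels.
* Equalization uses 256 bins on the already-rescaled image; on an image
  whose gray levels are equally populated it is the identity, which is
  the property the tests pin down.
* A mask thinner than three slices is padded by duplicating the nearest
  mask-bearing slice (with a warning), keeping every stack balanced.

## Feature extraction

The handcrafted extractor emits **851 named features**: 14 shape + 18
first-order + 75 texture features (GLCM 24, GLRLM 16, GLSZM 16, GLDM 14,
NGTDM 5) on the original image, and the 93 non-shape features recomputed
on each of the 8 sub-bands of a single-level stationary 3-D wavelet
transform. Numerical choices:

* **Texture in 2-D per slice.** A 3-slice stack is too thin for
  13-direction 3-D statistics; GLCM/GLRLM run over the 4 in-plane
  directions at distance 1 (direction-averaged, then slice-averaged),
  GLSZM/GLDM/NGTDM use 8-connected in-plane neighbourhoods. Shape is
  3-D, so the 14-feature shape family and the 851 total are preserved.
* **Discretization.** 32 equal-width bins over the pooled in-mask range
  of the image at hand; each wavelet sub-band is binned independently.
  This makes texture features exactly invariant to additive intensity
  shifts, a property the tests assert.
* **Wavelet.** The stationary (undecimated) transform keeps the array
  shape so the original mask applies to every sub-band. Basis Coiflet-1;
  any axis shorter than the filter support (always the 3-slice z axis)
  falls back to Haar. Convolutions are periodic and centred on the
  kernel's energy centroid so sub-bands stay spatially aligned with the
  mask.
* **Shape meshes.** Surface area and mesh volume come from marching
  tetrahedra on a lightly smoothed (σ = 0.8 voxel) copy of the mask with
  interpolated iso-crossings; meshing the raw binary mask overestimates
  a sphere's area by ~12–30% (staircase bias), while the smoothed mesh
  lands within ~1%. The price is that mesh volume under-reports sharply
  cornered or very thin objects relative to voxel counting; voxel volume
  is reported alongside, and consistency across subjects is what the
  downstream analysis uses. Degenerate single-voxel masks return
  documented conventions (axis lengths 0, sphericity 1) with a warning.
* **Degenerate ROIs.** A constant ROI yields zero entropy/contrast and
  correlation-type features equal to 1 by convention; a slice whose ROI
  has no voxel pairs falls back to the same single-level conventions.

The deep-feature branch is a *pluggable numeric feature-bank contract*:
`feature_bank()` provides a deterministic stand-in (D seeded random 5×5
filters, valid convolution, ReLU, global max pooling, mean over slices)
with the widths of the popular pre-trained networks (512/1536/2048), and
`read_external_features()` accepts any precomputed per-subject CSV.
True pre-trained CNN activations are out of scope by design.

## Perturbations and robustness

Three perturbation kinds, each compared against the original as one ICC
panel per feature: slice thickness (slab averaging to 1/2/3/5 mm;
majority vote for the mask), in-plane rotation (−30°, −15°, +15°, +30°;
bilinear for the image, nearest-neighbour for the mask, applied to the
selected 2-D slices), and segmentation (morphological dilation/erosion
with a unit ball to a target volume ratio 0.8/1.2, stopping at the
nearest achieved ratio). Thickness and segmentation act on the raw
volume/mask *before* preprocessing so the whole chain re-runs on the
perturbed input; rotation is inherently in-plane and acts after slice
selection.

Robustness is ICC(2,1) — two-way random, absolute agreement, single
rater — computed per feature per kind on the balanced subjects × raters
panel (original included as a rater; all levels of a kind pooled into one
panel). A feature passes if every kind's ICC is ≥ 0.85; "more than 0.85"
versus "cutoff 0.85" is resolved as ≥, and the cutoff is an argument.
Feature standardization (zero mean, unit variance) happens *after*
filtering, fitted on training folds only.

## Selection cascade and benchmark

The cascade is: (1) drop zero-MAD features; (2) keep the top 20% by
absolute Welch *t*; (3) rank with one of 13 filter selectors; (4)
optionally refine by recursive feature addition (RFA), keeping a feature
only if mean stratified 10-fold CV AUC improves by > 1e-4. The eight
mutual-information selectors use the standard conditional-likelihood
criterion forms (MIM, MIFS, MRMR, JMI, CIFE, CMIM, ICAP, DISR) with
plug-in MI on 10 equal-frequency bins; the five score selectors are
Fisher score, |Welch t|, chi-square on binned contingencies, best
threshold-split Gini decrease, and ReliefF (k = 10, range-normalized).
Ranking budgets default to K = 30 candidates. Ties always break toward
the earlier catalogue column, making every ranking order-invariant.

`cv_evaluate()` guards against leakage: standardization, SMOTE class
balancing and the entire cascade are fitted on the training split of each
fold only. AUC uses the rank (Mann–Whitney) formulation with midranks;
model stability is RSD = 100·sd/mean of the 10 fold AUCs; confusion
metrics are pooled over out-of-fold predictions at threshold 0.5.
`run_grid()` builds one record per extractor × selector × classifier and
shares per-fold selections across classifiers (identical results, shared
work) whenever RFA is off; with RFA on, the selection depends on the
classifier and is recomputed. The optimum is the maximum mean AUC with
lower RSD as tie-break. Classifiers are delegated to established R
toolkits with fixed defaults and pinned seeds; the nearest-neighbour
vote and AdaBoost stumps are implemented in-package so class-1
probabilities are exact.

## Survival follow-through

Subjects are stratified by the chosen model's *out-of-fold* predicted
label — the leakage-free reading of "dichotomize by model prediction" —
then compared by Kaplan–Meier curves, the two-group log-rank test, and a
univariate Cox model with Breslow tie handling (the tie convention is a
declared choice; the data are continuous so ties are rare). The Cox
hazard ratio is reported for predicted-progression versus
predicted-control, so HR > 1 means the model's high-risk group dies
faster.

## Problem sizes and what the tests show

The test-suite and the acceptance script run the full machinery at
reduced sizes chosen once for compute scale: full-size (224 px crop,
59.68 mm tumour) extraction is exercised on a single subject; the
1,092-model grid runs on an n = 30 cohort at 32 px crops with small
classifier budgets and RFA off (the grid's combinatorics and leakage
guarantees do not depend on these sizes); signal-recovery and robustness
studies use n = 100 and n = 20 cohorts at 32–48 px crops with 12–30 mm
tumours. One consequence of the standardization chain worth knowing when
interpreting phantom results: per-subject adaptive windowing plus
histogram equalization removes most of a class-wise additive intensity
shift by construction, so the recoverable class signal on phantoms lives
mainly in the texture correlation length — which is exactly the kind of
signal the texture families are meant to capture. Calibration suites use 200–1,000 Monte-Carlo replicates. The
statistical calibration results (log-rank size, Cox coverage, null AUC)
are properties of the implementation and carry over to real data; the
absolute robustness percentages and AUCs measured on phantoms are
properties of the phantom distribution and do not predict clinical
values.

## Known limitations

* Phantom realism is deliberately minimal (see above); effect-size
  defaults are free parameters.
* Texture matrices are 2-D per slice; a thick-volume 3-D texture mode is
  out of scope.
* Classifier hyperparameters are library defaults with pinned seeds, not
  tuned reproductions.
* The deep-feature stand-in shares only the interface (and none of the
  semantics) of pre-trained CNN features.
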