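---
title: "A masked 3D radiomics pipeline for paired-sequence MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A masked 3D radiomics pipeline for paired-sequence MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Skull base chordoma and chondrosarcoma look alike on MRI but behave very
differently: chordoma recurs aggressively, chondrosarcoma responds well to
radiotherapy. Because image-guided biopsy of central skull base lesions is
unsafe, a classifier built from quantitative image features ("radiomics")
is an attractive preoperative aid. `radvox` implements such a pipeline end
to end for paired post-gadolinium T1 ("GD") and T2 volumes with a manually
delineated volume of interest (VOI): high-throughput 3D feature extraction,
recursive-feature-elimination (RFE) selection, and nested cross-validated
classification with a strict hold-out test — plus a seeded phantom
generator that lets every stage be validated without patient data.

```{r, eval = FALSE}
library(radvox)
cases <- generate_cohort(cohort_config(n_cases_per_class = 10, seed = 1))
tab <- extract_cohort(cases)
dim(tab)  # 20 cases x (case_id, label, 4876 features)
```

## Feature extraction

Each sequence volume is decomposed once with a single-level 3D Coiflet-1
wavelet transform applied separably along x, y and z, producing 8 subband
images (`LLL` ... `HHH`; the first letter is the x-axis filter) next to the
original — 9 images in all. The transform is *undecimated* (stationary):
decimation would halve the grid and break voxel correspondence with the
VOI mask, so keeping the native grid is the only choice that needs no mask
resampling. Boundaries are handled by half-sample mirror padding, the
standard choice for image wavelets because it avoids introducing edge
ramps. The analysis filters are the orthonormal Coiflet-1 bank; no further
rescaling is applied to the subbands.

From the 9 images the pipeline computes, per sequence:

* **8 morphology features** from the mask alone (mesh volume, approximate
  volume, surface area, surface-to-volume ratio, sphericity,
  compactness 1 and 2, maximum 3D diameter);
* **18 intensity features** per image (moments, percentiles, energy,
  dispersion measures);
* **20 histogram features** per image on a fixed 64-level quantization;
* **58 texture features** per image and per quantization at 16, 32, 64 and
  128 gray levels: 11 GLCM, 13 GLRLM, 13 GLSZM, 16 NGLDM and 5 NGTDM.

That yields `8 + 9*(18+20) + 9*4*58 = 2438` features per sequence and
`2438 * 2 = 4876` per case. The exact identity and order of every feature
is fixed by a versioned registry (`inst/extdata/feature_registry.yaml`);
extraction refuses to run if the registry counts deviate from
8/18/20/11/13/13/16/5. Feature names follow the convention
`{bins}_{sequence}_{subband}_{family}_{name}`, e.g.
`6bit_GD_HHL_GLCM_inverse_difference_moment` ("6bit" = 64 gray levels);
intensity features render the bins token as `-` because they need no
quantization, and morphology features are named `MORPH_{sequence}_{name}`.
The same mask serves both sequences, so the two morphology blocks carry
identical values under sequence-tagged names; the sequence tag keeps the
4876 column names unique.

### Conventions that the source material leaves open

Several numerical conventions are not derivable from the study design and
are fixed here once:

* **Quantization** uses the fixed-bin-number scheme on the within-VOI range
  of each image separately (`level = floor(n_bins*(x-min)/(max-min)) + 1`,
  maximum clamped to `n_bins`, constant regions mapping to level 1). Each
  wavelet subband is quantized independently because subbands have
  unrelated dynamic ranges. This makes every histogram and texture feature
  exactly invariant under affine rescaling of the acquired intensities —
  a desirable property for uncalibrated MRI.
* **Texture geometry**: Chebyshev distance 1 everywhere (26-neighborhood),
  counts merged over the 13 unique 3D directions *before* normalization
  (one matrix per family rather than per-direction feature averaging),
  zones 26-connected, NGLDM dependence threshold 0. Merged aggregation is
  deterministic and the cheapest of the standard options.
* **Degenerate guards**: features with a variance denominator (GLCM
  correlation, skewness, kurtosis, coefficient of variation) return 0 on a
  constant VOI; the NGTDM coarseness denominator is guarded at 1e-6; mode
  and argmax ties resolve to the smallest level. Entropies are base 2;
  percentiles interpolate linearly.
* **Moments** use the population convention (divide by N); z-scores use the
  sample (N-1) standard deviation. Both are stated so results are exactly
  reproducible.

### Morphology meshing

Volume and surface area come from an iso-surface triangulation of the mask
at level 0.5 (marching tetrahedra over the voxel-center lattice). Meshing
the raw 0/1 indicator puts every vertex at an edge midpoint, and the
resulting staircase faceting overestimates the surface area of a digitized
sphere by roughly 10-30% — enough to push sphericity far from 1 for a
genuinely spherical object. The mask indicator is therefore zero-padded and
lightly smoothed (Gaussian, sigma 0.8 voxel per axis) before triangulation,
after which a radius-15 digitized ball measures sphericity within about 1%
of the analytic value. Masks so thin that smoothing drops the entire field
below 0.5 (e.g. a single voxel) fall back to the raw indicator. The maximum
3D diameter is the largest pairwise distance between surface voxel centers,
floored at the largest voxel spacing so it stays physically meaningful for
degenerate masks.

## Feature selection

Selection operates on the z-scored training table (normalization statistics
come from the training rows only and are reused, frozen, for any validation
data — anything else would leak hold-out information). Unless configured
otherwise it runs independently per sequence, mirroring a design in which
GD and T2 features are reported separately.

1. **Feature number.** For each candidate count k in 1..10 and each of 5
   repeats, the training cases are split into 4 stratified subgroups; per
   subgroup an RFE runs on the other 3, a logistic regression is fit on the
   surviving k features, and accuracy is measured on the held-out subgroup.
   The k with the best mean accuracy wins; ties go to the smaller k.
2. **RFE.** "Importance" is the absolute coefficient of an L2-regularized
   logistic regression (inverse penalty C = 1) on the standardized
   features; the least important feature is removed and the model refit,
   one feature at a time. Survivor sets are nested by construction, so one
   elimination pass serves every k. Ties remove the feature later in
   registry order.
3. **Frequency voting.** One RFE per repeat runs on a re-randomized 3/4
   subsample (the first subgroup of that repeat's split held out); each
   feature's frequency counts in how many of the 5 survivor sets it
   appears, and the k most frequent are selected (ties: longer mean
   survival, then lexicographic name).
4. **Redundancy pruning.** While any within-sequence pair of selected
   features has |Pearson r| > 0.7 on the training rows, the member with the
   lower frequency is dropped (absolute value deliberately: anticorrelated
   features are equally redundant).

The elimination loop refits the ridge-logistic model a few thousand times
per run, so the solver works in the n-dimensional observation space: the
penalized stationarity condition `beta = C * X'(y - p)` turns the fit into
an n-dimensional fixed-point system whose Newton step costs O(n^3)
regardless of the number of columns, and removing a feature is a rank-1
downdate of the Gram matrix with a warm-started refit. While more than 50
columns remain, one quadratic Newton step per elimination keeps the
stationarity residual near 1e-6; the final 50 columns get fully converged
refits. A unit test pins the solver against glmnet (`alpha = 0`,
`lambda = 1/(n*C)`) to 1e-4.

## Model selection and testing

Two learners are tuned by exhaustive grid search, each point scored by
stratified 2-fold CV AUC on a stratified 80% subset of the training cases:
logistic regression over C in {0.01, 0.1, 1, 10, 100}, and an SVM over
linear and RBF kernels with the same cost grid and RBF width in
{1/d, 0.01, 0.1, 1}. Ties resolve to the first grid point. The learner with
the higher inner-CV AUC is carried forward (ties prefer the logistic
model). Evaluation is stratified 5-fold CV on the training cases — each
fold refits the z-score normalization and the model on the other four and
draws a trapezoidal ROC on the held-out fold — reported as mean ± sample SD
of the 5 AUCs. The final model is refit on all training cases and applied
once to the disjoint hold-out cases; accuracy is reported as an exact
fraction. SVM scores are signed decision margins (AUC is rank-based, so no
probability calibration is needed).

`compare_readers()` implements the accompanying statistics: a two-sided
one-sample t-test of a panel of reader accuracies against the model's
accuracy as reference, a Shapiro-Wilk normality check, the reader median
and the 95% CI of the reader mean, with p < 0.05 flagged significant.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not MRI physics. Each case gets an axis-aligned ellipsoidal VOI
(analytic volume available for morphology checks) with per-axis radii drawn
from 8-14 mm — ellipsoid volumes of roughly 2-11 cm^3, matching the scale
of skull base tumors — placed at a random interior position of a
32x32x32-voxel grid with 1x1x3 mm spacing (slice thickness larger than
in-plane resolution is the MRI norm, and anisotropic spacing forces all
physical quantities through the header geometry). Voxel values are a
Gaussian-smoothed standardized noise field (class-specific correlation
length: 4 mm vs 7 mm at unit effect size) plus a class mean shift (-0.5 vs
+0.5) plus unit-variance voxel noise; the two sequences of a case share the
label and mask but draw independent noise. A single `effect_size` knob
interpolates both class differences towards their common midpoint, so 0
makes the classes exactly exchangeable and larger values extrapolate;
"large effect" conditions in the validation suite use `effect_size = 2`
(a two-noise-SD mean separation plus clearly distinct texture scales).

What the phantoms deliberately do not model: bias fields, coil profiles,
k-space artifacts, partial-volume effects, inter-observer mask variability
or scanner-to-scanner feature instability. Passing tests therefore
demonstrate that the *machinery* is correct and well calibrated — counts,
formulas, selection behavior, null behavior, leak-freedom — not that any
particular clinical accuracy would be attained on real patients.

## Validation strategy and problem sizes

The test suite checks every texture family against brute-force oracles
(explicit pair enumeration, run scanning, BFS flood fill, direct
neighborhood evaluation) on random 4-6 voxel VOIs, and the wavelet against
a triple-loop convolution oracle; mass-conservation and affine-invariance
properties run across seeded random inputs. Calibration checks use 100
permuted-label replicates (grand mean 5-fold AUC must stay in
[0.45, 0.55]) and effect-size-0 cohorts (hold-out accuracy near chance).
The end-to-end check runs 100 seeded replicates of the full pipeline —
generate, extract, select, tune, evaluate, hold out — on 47-train /
10-validation cohorts at 32^3 voxels, the split sizes of the motivating
study, and requires hold-out accuracy of at least 0.8 in at least 80% of
replicates. These sizes keep the whole suite within a coffee break on one
CPU while still exercising every code path at realistic dimensions.

## Known limitations

* No resampling stage: volumes and masks must share a grid; nothing
  protects against sequences acquired on different grids beyond the
  explicit mismatch error.
* The exact feature rosters beyond the counts are a declared convention
  (the registry), as is merged direction aggregation; other radiomics
  software may use per-direction averaging or different formula variants
  and will produce different values for individually named features.
* Mesh-based surface area depends on the smoothing antialiasing choice
  documented above; voxel-face area would be ~1.5x larger for a sphere.
* The RFE reading — one elimination pass per repeat on a re-randomized 3/4
  subsample — is one of several defensible interpretations of a
  "repeated 5 times" protocol; it is configurable via `selection_config()`.
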