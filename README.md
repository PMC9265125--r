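# radvox

Masked 3D radiomics and small-cohort classification for paired-sequence
MRI, built around the problem of telling skull base **chordoma** from
**chondrosarcoma** before surgery. The two tumors are radiographic twins
with opposite clinical behavior, and biopsy of central skull base lesions
is unsafe — so the question becomes: can a classifier trained on
quantitative features of the routine post-gadolinium T1 ("GD") and T2
volumes, within a delineated volume of interest (VOI), separate them?

`radvox` implements the full analysis pipeline as a tested, reusable R
package:

* **Feature extraction** — a single-level undecimated 3D **Coiflet-1
  wavelet** decomposition into 8 subbands (`LLL`…`HHH`) plus the original
  image; per image, 18 intensity and 20 histogram features (64 gray
  levels); per image and per quantization at 16/32/64/128 gray levels, the
  five 3D texture-matrix families — 11 GLCM, 13 GLRLM, 13 GLSZM, 16 NGLDM,
  5 NGTDM — built on the 26-neighborhood and merged over the 13 unique
  directions; and 8 mask morphology features from an iso-surface mesh.
  Per sequence that is

  `8 + 9·(18 + 20) + 9·4·(11 + 13 + 13 + 16 + 5) = 2438` features,
  i.e. `4876` per case, named
  `{bins}_{sequence}_{subband}_{family}_{name}` (e.g.
  `6bit_GD_HHL_GLCM_inverse_difference_moment`).

* **Feature selection** — logistic-regression recursive feature
  elimination (L2, C = 1, one feature removed per refit), with the feature
  number chosen in 1…10 by a 4-subgroup × 5-repeat cross-validation
  simulation, frequency voting over 5 RFE repeats, and pruning of feature
  pairs with |Pearson r| > 0.7 within each sequence.

* **Modeling** — grid-searched logistic regression and SVM with nested
  2-fold CV on a stratified 80% tuning subset, stratified 5-fold ROC/AUC
  evaluation (mean ± SD, per-fold renormalization), hold-out testing on a
  disjoint validation set, and a one-sample t-test (plus Shapiro–Wilk
  check) comparing a panel of human-reader accuracies against the model.

* **Synthetic cohorts** — a seeded generator of two-class 3D phantoms
  (smoothed Gaussian fields with class-specific correlation length and
  mean shift inside ellipsoidal VOIs, anisotropic 1×1×3 mm voxels, NIfTI
  round-trip) so the whole pipeline can be validated end to end without
  patient data.

## Worked example

```r
library(radvox)

# a small two-class phantom cohort: 12 + 12 training, 3 + 3 validation
tr <- generate_cohort(cohort_config(n_cases_per_class = 12, effect_size = 2, seed = 7))
va <- generate_cohort(cohort_config(n_cases_per_class = 3,  effect_size = 2, seed = 50007))
va <- lapply(va, function(cs) { cs$case_id <- paste0("val_", cs$case_id); cs })

tab_tr <- extract_cohort(tr)   # 24 x 4878 (case_id, label, 4876 features)
tab_va <- extract_cohort(va)

res <- run_pipeline(tab_tr, tab_va, selection_config(seed = 7), model_config(seed = 7))
res$selection
#> <selection_result> 3 features after pruning
#>   block GD: k = 2, kept 1
#>   block T2: k = 2, kept 2
res$evaluation
#> <eval_report> lr: AUC 1.000 +/- 0.000 over 5 folds
res$holdout$fraction
#> [1] "6/6"

compare_readers(c(0.5, 0.6, 0.7), res$holdout$accuracy)
#> <reader_comparison> readers mean 0.600 (median 0.600, 95% CI 0.352-0.848)
#>   vs model 1.000: t = -6.928, p = 0.0202 (significant at 0.05)
```

Reading the output: selection settled on 2 features per sequence and
pruned one correlated pair member, leaving 3; the tuned logistic model
separates the phantom classes perfectly in 5-fold CV (the phantom's
`effect_size = 2` is a strong, deliberately easy signal); all 6 held-out
cases are classified correctly; and the simulated reader panel (mean
accuracy 0.60) is significantly below the model at the 0.05 level.

Individual stages are exported too — `wavelet_decompose()`, `quantize()`,
`glcm_features()` … `ngtdm_features()`, `morphology_features()`,
`rfe_rank()`, `evaluate_cv()`, `test_holdout()`, `compare_readers()` — see
the package help and the vignette (`vignettes/radiomics-pipeline.Rmd`) for
the model, its conventions and their rationale.

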