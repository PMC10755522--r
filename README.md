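# bagpipe

Brain-age-gap (BAG) estimation and downstream association analysis from
regional neuroimaging features, in R.

## What this package does

Machine-learning brain-age models regress chronological age on regional
imaging features of cognitively normal adults — per-region gray-matter
volume from T1 MRI, or standardized uptake value ratios (SUVR) from
FDG-PET. Applied to a new subject, the model yields a *brain age*; the
difference

> BAG = predicted brain age − chronological age   (years)

is a compact marker of advanced (positive BAG) or delayed brain aging, and
is studied as a risk marker in subjective cognitive decline (SCD), mild
cognitive impairment (MCI), and progression to dementia.

`bagpipe` implements the full analysis chain as tested, reusable
components:

* **Parcellation & I/O** — reduce a NIfTI volume over an integer atlas
  labelling (90-region default, editable TSV) to a per-region feature
  table; SUVR normalization against an explicit reference-region set.
* **Brain-age estimator** (`fit_nested`, `predict_cohort`) — nested 5×5
  cross-validation; per-feature Tukey-fence outlier exclusion (IQR
  multiplier 6) on training folds only; candidate learners ε-SVR
  (`e1071`) and relevance vector regression (`kernlab`) selected by inner
  validation MAE; per-fold age-bias correction
  `BAG_corrected = BAG_raw − (α·age + β)` with `(α, β)` fit by OLS on
  held-out validation predictions; ensemble averaging of the five
  corrected fold predictions for external cohorts.
* **Permutation importance** (`ensemble_importance`) — per-region increase
  in MAE when the region's column is permuted on the fold's validation
  subjects; medians by lobe/hemisphere.
* **Association battery** (`partial_correlation`,
  `ancova_group_effect`, …) — covariate-adjusted (age, sex, education,
  APOE-ε4) partial correlations of BAG with cognition and pathology
  markers, Pearson/Spearman chosen by a Shapiro–Wilk screen, with
  trend/significant/Bonferroni tiers; Welch and paired t comparisons;
  ANCOVA for stable-vs-decliner contrasts.
* **Progression prediction** (`cv_single_feature_auc`,
  `validate_external`) — stratified 10-fold single-feature logistic
  classification of 2-year MCI decline with covariate residualization
  anchored on the stable subjects of each training fold, AUC by
  Mann–Whitney, a-priori-prevalence probability cutoffs, and external
  validation carrying only the fitted model and the mean cutoff.
* **Synthetic cohort generator** (`generate_cohort`) — cohorts with a
  *known* latent BAG per subject: features decline linearly in
  `age + BAG`, cognition/pathology couple to the latent BAG, and 2-year
  progression follows a logistic model in it. Every downstream stage is
  therefore testable against ground truth without access-restricted
  clinical data.

## Worked example

Train on a synthetic cognitively normal cohort whose feature noise is
calibrated to an analytic error floor of 1.5 y, then infer BAG in an MCI
group carrying a +2.5 y latent shift:

```r
library(bagpipe)

spec <- cohort_spec(n_subjects = 200, seed = 42,
                    noise_sd = calibrate_noise_sd(cohort_spec(n_subjects = 200), 1.5))
cn <- generate_cohort(spec)

config <- bae_config(
  svr_grid = expand.grid(kernel = "linear", cost = c(0.01, 0.1, 1),
                         epsilon = 0.1, stringsAsFactors = FALSE),
  rvr_grid = data.frame(kernel = "linear"), seed = 1)
ensemble <- fit_nested(cn, config)
ensemble
#> <bae_ensemble> 5 folds (svr,svr,svr,svr,svr), modality MRI
#>   held-out MAE (non-outliers): 1.555 y

mci <- generate_cohort(cohort_spec(n_subjects = 250, group = "MCI",
                                   noise_sd = spec$noise_sd,
                                   bag_shift_mean = 2.5, bag_shift_sd = 2,
                                   cognition_coupling = 0.3, seed = 43))
pr <- predict_cohort(ensemble, mci, mode = "ensemble_average")
round(pr$metrics$mean_bag, 2)
#> [1] 2.05
```

The held-out MAE of 1.56 y (R² = 0.95) says the estimator recovers age to
within ~1.6 years on unseen normative subjects. The MCI group's mean
ensemble BAG of 2.05 y recovers the simulated +2.5 y shift up to the
expected shrinkage attenuation of a regularized learner (see the methods
vignette). The covariate-adjusted association of BAG with the memory
composite then reads:

```r
res <- partial_correlation(
  pr$predictions$bag, mci$phenotype$memory_composite,
  data.frame(age = mci$phenotype$chronological_age,
             sex = as.integer(mci$phenotype$sex == "female"),
             education = mci$phenotype$education,
             apoe4 = mci$phenotype$apoe4_carrier),
  method = "auto", x_name = "bag_mci", y_name = "memory")
apply_significance_tiers(res, family = "cognition", m = 2)
#> bag_mci ~ memory | age+sex+education+apoe4: r = -0.341, p = 4.125e-08,
#>   95% CI [-0.447, -0.225], n = 250 [bonferroni_significant]
```

i.e. higher BAG goes with worse memory after adjustment, surviving the
family's Bonferroni threshold (α = 0.05/2).

`make_demo()` + `run_pipeline()` (or
`Rscript inst/cli/bagpipe.R demo --out DIR`) run the same chain end to end
from CSV inputs and write predictions, importance maps, association
tables, progression reports and a checksummed run manifest.

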