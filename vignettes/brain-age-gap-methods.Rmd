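---
title: "Brain age gap estimation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age gap estimation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bagpipe)
```

## The estimation model

Brain age estimation regresses chronological age on a vector of regional
imaging features in cognitively normal (CN) subjects. `bagpipe` consumes
one feature table per modality — per-region gray-matter volume (MRI) or
SUVR (FDG-PET) over a 90-region cortical/subcortical atlas — and fits a
nested cross-validated ensemble:

1. **Outer loop** (5 folds): each fold in turn is held out as a validation
   set.
2. **Outlier exclusion** on the outer-training portion only: a subject is
   excluded from *training* if any feature falls outside the Tukey fences
   `[Q1 − 6·IQR, Q3 + 6·IQR]`, quartiles taken per feature over the
   training subjects. Validation subjects are never excluded, but
   subjects flagged in any fold are marked so accuracy metrics can be
   restricted to non-outliers.
3. **Inner loop** (5 folds) tunes the candidate learners on the cleaned
   outer-training set: ε-SVR over kernel ∈ {linear, radial},
   cost ∈ 10^{−3..3}, ε ∈ {0.01, 0.1, 1}, and relevance vector regression
   over kernel ∈ {linear, radial}. The pair with the lowest mean
   inner-validation MAE wins; ties break toward SVR before RVR and then
   the lexicographically smallest grid row, so selection is fully
   deterministic.
4. The winner is refit on the cleaned outer-training set and predicts the
   outer validation fold; those held-out predictions provide both the
   fold's accuracy estimate and its bias-correction parameters.

Features are z-scaled inside every learner with the statistics of the set
the learner is fit on, so no validation information leaks; kernlab's RVM
carries no intercept, so the response is centered around the training mean
and the mean restored at prediction.

## Age-bias correction

Regularized regression pulls predictions toward the training mean, so the
raw gap `BAG_raw = prediction − age` correlates negatively with age
(regression to the mean). Per outer fold we fit, on the fold's held-out
validation predictions,

    BAG_raw = α·age + β + ε,

and correct every subsequent prediction by
`corrected = raw − (α·age + β)`. Parameterizing the *gap* (rather than
the prediction) on age gives the identity `(α, β) = (0, 0)` for a perfect
predictor; the prediction-on-age parameterization is algebraically
convertible (slope `1 + α`, same intercept). A pooled variant — one line
fit on the pooled validation predictions of all folds — is available via
`bae_config(pooled_bias = TRUE)` for sensitivity analysis; the default
estimates and applies the correction per fold, *before* ensemble
averaging, matching the order of the training pipeline.

Two caveats are worth stating. First, the correction consumes the
subject's true age, so corrected values are calibrated gaps, not pure
predictions; held-out MAE computed after correction is mildly optimistic
(the two correction parameters are fit on the same validation folds).
Second, for a cohort whose brains genuinely look `Δ` years older, a
learner with effective shrinkage slope `k < 1` recovers `k·Δ`, not `Δ`:
bias correction restores the *age* slope but cannot undo the attenuation
of the *latent offset*. Under the generator's affine model,
`k ≈ 1 − v_post/v_age`, where `v_post` is the posterior age variance
given the features (below) and `v_age` the age variance. This is why
offset-recovery analyses here run in a moderate-noise regime (error floor
1.5 y, `k ≈ 0.95`) rather than at the 2.5-y accuracy calibration
(`k ≈ 0.87`), a choice made on this analytic ground, not tuned.

## What the synthetic generator emulates

`generate_cohort()` draws, per subject `i`:

* age `a_i ~ U(60, 90)` (the analysis is restricted to 60+);
* covariates: sex (53% female), education (rounded `N(16, 2.5²)`,
  clamped to 8–22 y), APOE-ε4 carriership (29%) — drawn independently of
  age by default, with optional per-region confounding slopes so
  covariate-adjustment tests can distinguish confounded from clean
  regimes;
* a latent brain age gap `g_i ~ N(μ_g, σ_g²)` — the group's
  accelerated-aging offset;
* features `x_ij = b_j + s_j·(a_i + g_i) + c_j'z_i + ε_ij`,
  `ε_ij ~ N(0, σ²)`: the brain simply "looks" `g_i` years older, which
  makes the latent BAG a well-defined recovery target;
* memory/executive composites `−κ·g_i + noise` (executive uses `0.8κ`);
  pathology markers affine in `g_i` on canonical scales (amyloid PET SUVR
  +0.02/y around 1.10, CSF Aβ₁₋₄₂ −15 pg/mL/y around 950, p-tau/Aβ ratio
  +0.015/y around 0.08 — signs follow the expected pathology directions);
* a 2-year progression label with
  `logit P(decline) = logit(p₀) + λ·g_i`;
* missing-completely-at-random gaps in the cognition/pathology measures
  only, never in demographics (the analysis functions use listwise
  deletion, and only an MCAR mechanism is claimed).

Default MRI baselines/slopes span 50–150 units and −1.2…−0.2 units/y; the
FDG profile spans SUVR-like 0.9–1.5 at −0.006…−0.001/y. The coupling
magnitudes (κ, λ, pathology slopes) have no published generative-scale
counterparts; the defaults are arbitrary but chosen so that recovery tests
have realistic signal-to-noise, and every test states the values it uses.

What the generator does **not** emulate: site/scanner effects,
longitudinal trajectories, non-linear aging, spatially correlated noise,
realistic lesion anatomy. Passing tests therefore demonstrate that the
*machinery* is correct and well-calibrated under the stated model, not
that any accuracy figure transfers to real cohorts.

### Analytic accuracy floor

For the affine generative model the best possible age estimate from one
subject's features has posterior variance
`v_post = 1 / (1/v_age + S/σ²)` with `S = Σ_j s_j²`, and a Gaussian error
of SD `√v_post` has expected absolute error `√(2/π)·√v_post`
(`predicted_mae_floor()`). `calibrate_noise_sd()` inverts this to place a
cohort at a chosen floor. A fitted linear read-out estimated from `n`
training rows inflates the error variance by roughly `(1 + p/n)`
(`predicted_mae()`); this approximation was validated against simulation
before being frozen as the test oracle, and it degrades when `p ≈ n`, so
accuracy checks run at `n ≥ 200` with `p = 90`.

## Downstream statistics

* **Method selection**: Shapiro–Wilk on each focal variable (α = 0.05,
  n ≥ 8); Pearson iff both pass, else Spearman. The screen is applied to
  the variables themselves, the simplest reading of a normality-dependent
  choice; residual-based screening can be layered on by callers.
* **Partial correlation**: residualize both variables on the covariates
  (with intercept) and correlate residuals; the Spearman variant is
  exactly partial Pearson on average ranks. `p` from `t` with
  `n − k − 2` dof; CI by Fisher z (`1/√(n − k − 3)`).
* **Group comparisons**: Welch t (unequal variances are the norm between
  diagnostic groups of different sizes); paired t for within-subject MAE
  comparisons across modalities, with exact degenerate handling (identical
  vectors → t = 0, p = 1; a constant shift → a point interval at the
  shift).
* **ANCOVA**: `outcome ~ group + covariates`; the group F is the squared
  t of the single binary factor, equivalent to the type-III test.
  Covariate coefficients are reported. Age enters the covariate set only
  when the cohort's corrected BAG still correlates with age at p < 0.05 —
  an executed rule, not a per-cohort constant.
* **Tiers**: trend p < 0.1, significant p < 0.05, Bonferroni-significant
  p < 0.05/m with m = 2 for the cognition family and m = 3 for the
  pathology family.

## Progression prediction

Single-feature logistic classifiers under stratified 10-fold CV. In each
fold the predictor is residualized on age/sex/education/APOE with the
linear model fit on the *stable subjects of the training fold* and scaled
by the stable-group residual SD (the reference group defines "normal", so
its SD — not the whole-fold SD — is the unit). The classifier is
unpenalized except for a 1e-8 ridge that stabilizes separable folds
without distorting predicted probabilities, which matters because the
classification cutoff is the training fold's decliner *prevalence* (a
probability, meaningful only for calibrated scores). Ties at the cutoff
classify as decliner (`≥`). Internal sensitivity/specificity use the
pooled validation-fold predictions at the mean cutoff, avoiding a refit's
optimism. External validation refits only the covariate residualization on
the external stable group and carries over the fitted classifier and the
mean cutoff. AUC is computed as the Mann–Whitney probability with ties
counted ½. A predictor is flagged for external validation when its mean
CV AUC exceeds a configurable gate (default 0.7).

## Numerical choices and degenerate inputs

* Zero-IQR features in outlier detection flag only deviations beyond
  1e-12 absolute.
* Degeneracy guards (constant variables, residuals numerically zero
  relative to the input scale, single-class folds, rank-deficient
  designs) raise errors naming the offending quantity rather than
  returning noise-driven statistics; thresholds are relative (1e-10 of
  the input SD) so that exactly-explained variables are caught while
  ordinary data never are.
* All fold assignments, permutations and simulations derive their streams
  from a single seed via a deterministic label hash, so every stage is
  individually reproducible and full runs are byte-identical.
* SUVR normalization is idempotent after one application (the reference
  mean becomes 1), and no default reference set exists — the caller must
  name one.

## Problem sizes used by the test suite

Unit tests run cohorts of 50–150 subjects with reduced, deterministic
learner grids (linear kernels, cost ∈ {0.01, 0.1, 1}); the end-to-end
property checks use the study-scale conditions they verify: n = 200–400
cohorts for accuracy and bias-removal, 20 replicate clinical cohorts of
n = 400 for offset recovery, 2000 simulations for the type-I error of the
partial correlation, 100 seeded fixtures per statistical oracle, and 100
permutation seeds for the importance ranking. The demo profile
(`make_demo()`) uses n = 200/150/250/150 cohorts and a four-candidate
grid so the full pipeline stays interactive.

## Known limitations

* RVR radial-kernel fits can fail on ill-conditioned folds; failed
  candidates receive infinite validation error and selection falls back
  to the next-best candidate, so ensembles always complete, possibly
  without RVR.
* The estimator reports attenuation-uncorrected group offsets
  (`k·Δ`); users comparing groups against the generator's ground truth
  should consult the shrinkage analysis above.
* The normality screen at n in the thousands flags practically negligible
  departures (a known property of Shapiro–Wilk), pushing large-cohort
  associations toward Spearman; this is faithful to the stated rule
  rather than a statistical recommendation.
* Volumes are parcellated in voxel space only; registration, smoothing
  and segmentation are out of scope and must precede the package.
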