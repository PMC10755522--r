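# Type-7 quantile by the explicit interpolation formula, independent of
# stats::quantile: the oracle for the Tukey-fence fixtures.
oracle_q7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

test_that("outlier fences match hand-computed type-7 quartiles", {
  set.seed(21)
  x <- matrix(rnorm(10 * 3), 10, 3)
  x[4, 2] <- oracle_q7(x[-4, 2], 0.75) + 50   # plant one extreme value
  mask <- detect_outliers(x, multiplier = 6)
  oracle <- logical(10)
  for (j in 1:3) {
    q1 <- oracle_q7(x[, j], 0.25); q3 <- oracle_q7(x[, j], 0.75)
    iqr <- q3 - q1
    oracle <- oracle | x[, j] < q1 - 6 * iqr | x[, j] > q3 + 6 * iqr
  }
  expect_identical(mask, oracle)
  expect_true(mask[4])
  expect_equal(sum(mask), 1)
})

test_that("outlier detection handles degenerate spreads and wide fences", {
  x <- matrix(5, 8, 4)                       # zero spread everywhere
  expect_equal(detect_outliers(x), rep(FALSE, 8))
  x[3, 2] <- 5 + 1e-6                        # zero-IQR feature, real deviation
  expect_true(detect_outliers(x)[3])
  set.seed(1)
  g <- matrix(rnorm(200), 20, 10)
  expect_equal(detect_outliers(g, multiplier = 1e6), rep(FALSE, 20))
  expect_error(detect_outliers(matrix(1, 4, 2)), "at least 5")
  expect_error(detect_outliers(matrix(1, 8, 2), multiplier = 0), "> 0")
})

test_that("bias parameters are exact on constructed linear predictions", {
  age <- c(60, 65, 70, 75, 80, 85, 90)
  expect_equal(estimate_bias_params(age, age), c(alpha = 0, beta = 0),
               tolerance = 1e-12)
  expect_equal(estimate_bias_params(age, age + 3), c(alpha = 0, beta = 3),
               tolerance = 1e-12)
  # predictions = 0.5 * age + 40 -> BAG = -0.5 * age + 40
  expect_equal(estimate_bias_params(age, 0.5 * age + 40),
               c(alpha = -0.5, beta = 40), tolerance = 1e-12)
  expect_error(estimate_bias_params(rep(70, 5), rnorm(5)), "variance")
  expect_error(estimate_bias_params(c(60, 70), c(60, 70)), "at least 3")
})

test_that("bias correction is the stated arithmetic and zeroes the age slope", {
  expect_equal(apply_bias_correction(80, 70, 0, 0), 80)
  expect_equal(apply_bias_correction(80, 70, -0.5, 40), 75)
  set.seed(31)
  age <- runif(60, 60, 90)
  pred <- 0.7 * age + 20 + rnorm(60, 0, 2)
  b <- estimate_bias_params(age, pred)
  corrected <- apply_bias_correction(pred, age, b["alpha"], b["beta"])
  refit <- estimate_bias_params(age, corrected)
  expect_equal(unname(refit["alpha"]), 0, tolerance = 1e-10)
  expect_equal(unname(refit["beta"]), 0, tolerance = 1e-8)
})

test_that("nested CV recovers age almost perfectly from noiseless features", {
  co <- noiseless_cohort(n = 100, seed = 13)
  ens <- fit_nested(co, exact_bae_config(seed = 3))
  ho <- predict_cohort(ens, co, mode = "held_out")
  expect_lt(ho$metrics$mae, 0.5)
  expect_gt(ho$metrics$r_squared, 0.99)
})

test_that("fitting is deterministic and refuses undersized cohorts", {
  co <- noisy_cohort(n = 60, target_mae = 2.5, seed = 14)
  cfg <- fast_bae_config(seed = 8)
  a <- fit_nested(co, cfg)
  b <- fit_nested(co, cfg)
  expect_identical(a$heldout, b$heldout)
  expect_identical(
    lapply(a$fold_models, `[`, c("chosen_algorithm", "chosen_hyperparameters",
                                 "bias_alpha", "bias_beta")),
    lapply(b$fold_models, `[`, c("chosen_algorithm", "chosen_hyperparameters",
                                 "bias_alpha", "bias_beta")))
  tiny <- generate_cohort(cohort_spec(n_subjects = 12, seed = 1))
  expect_error(fit_nested(tiny, cfg), "at least 25")
})

test_that("held-out coverage: one prediction per subject from a foreign fold", {
  co <- noisy_cohort(n = 75, target_mae = 2.5, seed = 15)
  ens <- fit_nested(co, fast_bae_config(seed = 2))
  ho <- predict_cohort(ens, co, "held_out")$predictions
  expect_identical(ho$subject_id, co$phenotype$subject_id)
  expect_false(anyNA(ho$corrected_predicted_age))
  # the model of fold k never saw validation subjects of fold k
  for (fm in ens$fold_models) {
    val_ids <- ho$subject_id[ho$fold == fm$fold_index]
    expect_length(intersect(val_ids, names(fm$outlier_mask)), 0)
  }
  expect_equal(ho$bag, ho$corrected_predicted_age - ho$chronological_age,
               tolerance = 1e-12)
})

test_that("ensemble averaging is the arithmetic mean of corrected folds", {
  co <- noisy_cohort(n = 75, target_mae = 2.5, seed = 16)
  ens <- fit_nested(co, fast_bae_config(seed = 2))
  cl <- noisy_cohort(n = 30, target_mae = 2.5, seed = 17)
  pr <- predict_cohort(ens, cl, "ensemble_average")$predictions
  folds <- as.matrix(pr[, sprintf("fold_%d", 1:5)])
  expect_equal(pr$corrected_predicted_age, rowMeans(folds), tolerance = 1e-12)
  expect_equal(pr$bag, pr$corrected_predicted_age - pr$chronological_age,
               tolerance = 1e-12)
  # mode and modality guards
  expect_error(predict_cohort(ens, cl, "held_out"), "training cohort")
  fdg <- generate_cohort(cohort_spec(n_subjects = 30, modality_tag = "FDG",
                                     seed = 1))
  expect_error(predict_cohort(ens, fdg), "modality")
})

test_that("metrics follow their definitions on constructed predictions", {
  pred <- data.frame(chronological_age = c(70, 70),
                     corrected_predicted_age = c(71, 69))
  pred$bag <- pred$corrected_predicted_age - pred$chronological_age
  m <- bagpipe:::bae_metrics(pred)
  expect_equal(m$mae, 1.0)
  expect_equal(m$mean_bag, 0.0)
  expect_equal(m$bag_range, c(-1, 1))
  # five corrected fold estimates average to the final brain age
  expect_equal(mean(c(70, 71, 72, 73, 74)), 72.0)
})

test_that("column-shifted features leave linear-kernel predictions unchanged", {
  co <- noisy_cohort(n = 75, target_mae = 2.5, seed = 18)
  cfg <- bae_config(svr_grid = data.frame(kernel = "linear", cost = 1,
                                          epsilon = 0.1),
                    algorithms = "svr", seed = 5)
  ens <- fit_nested(co, cfg)
  cl <- noisy_cohort(n = 20, target_mae = 2.5, seed = 19)
  base <- predict_cohort(ens, cl, "ensemble_average")$predictions
  # shift one feature column everywhere: the training center absorbs it
  co2 <- co; cl2 <- cl
  co2$features[, 7] <- co2$features[, 7] + 100
  cl2$features[, 7] <- cl2$features[, 7] + 100
  ens2 <- fit_nested(co2, cfg)
  shifted <- predict_cohort(ens2, cl2, "ensemble_average")$predictions
  expect_equal(shifted$corrected_predicted_age, base$corrected_predicted_age,
               tolerance = 1e-6)
})

test_that("ensembles survive serialization round trips", {
  co <- noisy_cohort(n = 60, target_mae = 2.5, seed = 20)
  ens <- fit_nested(co, fast_bae_config(seed = 1))
  tf <- tempfile(fileext = ".rds")
  save_ensemble(ens, tf)
  back <- load_ensemble(tf)
  cl <- noisy_cohort(n = 20, target_mae = 2.5, seed = 21)
  expect_identical(predict_cohort(back, cl)$predictions,
                   predict_cohort(ens, cl)$predictions)
})
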