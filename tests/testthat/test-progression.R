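test_that("reference-anchored residualization matches its oracle", {
  set.seed(1)
  n <- 50
  covs <- matrix(rnorm(n * 2), n, 2)
  ref <- rep(c(TRUE, FALSE), c(30, 20))
  v <- covs %*% c(1, -2) + rnorm(n)
  got <- residualize(as.numeric(v), covs, ref)
  # two-step oracle: normal equations on reference rows, then scaling
  Z <- cbind(1, covs)
  beta <- solve(t(Z[ref, ]) %*% Z[ref, ], t(Z[ref, ]) %*% v[ref])
  res <- as.numeric(v - Z %*% beta)
  expect_equal(got, res / sd(res[ref]), tolerance = 1e-10)
  expect_equal(mean(got[ref]), 0, tolerance = 1e-12)
  # decorrelation from every covariate within the reference group
  for (j in 1:2)
    expect_lt(abs(cor(got[ref], covs[ref, j])), 1e-10)
})

test_that("residualization degenerates to a reference z-score sans covariates", {
  set.seed(2)
  v <- rnorm(40, 10, 3)
  ref <- rep(c(TRUE, FALSE), 20)
  got <- residualize(v, NULL, ref)
  expect_equal(got, (v - mean(v[ref])) / sd(v[ref] - mean(v[ref])),
               tolerance = 1e-12)
  # values exactly linear in covariates within reference: zero residuals there
  covs <- matrix(rnorm(80), 40, 2)
  v2 <- as.numeric(covs %*% c(2, 1)) + 5
  v2[!ref] <- v2[!ref] + 3
  expect_error(residualize(v2, covs, ref), "zero residual variance")
  expect_error(residualize(v, covs, rep(c(TRUE, FALSE), c(3, 37))),
               "reference subset too small")
})

test_that("AUC equals the brute-force pairwise Mann-Whitney probability", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(3)
  for (s in 1:10) {
    scores <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # with ties
    labels <- rbinom(30, 1, 0.4)
    if (sum(labels) %in% c(0, 30)) next
    pos <- which(labels == 1); neg <- which(labels == 0)
    acc <- 0
    for (i in pos) for (j in neg)
      acc <- acc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    expect_equal(roc_auc(scores, labels), acc / (length(pos) * length(neg)),
                 tolerance = 1e-15)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the cutoff is exactly the training decliner prevalence", {
  expect_equal(derive_cutoff(rep(c("decliner", "stable"), c(25, 75))), 0.25)
  expect_equal(derive_cutoff(c(1, 1, 0, 0)), 0.5)
  expect_error(derive_cutoff(rep("stable", 10)), "single class")
})

test_that("near-separable predictors reach high cross-validated AUC", {
  set.seed(4)
  n <- 400
  labels <- rep(c("decliner", "stable"), c(120, 280))
  feature <- (labels == "decliner") + rnorm(n, 0, 0.1)
  cv <- cv_single_feature_auc(feature, labels, n_folds = 10, seed = 5)
  expect_gt(cv$mean_auc, 0.95)
  expect_equal(cv$cutoff_per_fold, rep(0.3, 10), tolerance = 0.01)
  expect_gt(cv$sensitivity, 0.8)
  expect_gt(cv$specificity, 0.8)
})

test_that("an uninformative predictor sits at chance", {
  set.seed(5)
  n <- 2000
  labels <- rep(c("decliner", "stable"), c(500, 1500))
  feature <- rnorm(n)
  cv <- cv_single_feature_auc(feature, labels, n_folds = 10, seed = 6)
  expect_lt(abs(cv$mean_auc - 0.5), 0.03)
})

test_that("cross-validation is seed-deterministic and guards class counts", {
  set.seed(6)
  labels <- rep(c("decliner", "stable"), c(40, 80))
  feature <- rnorm(120) + (labels == "decliner")
  covs <- data.frame(age = rnorm(120))
  a <- cv_single_feature_auc(feature, labels, covs, seed = 7)
  b <- cv_single_feature_auc(feature, labels, covs, seed = 7)
  expect_identical(a$fold_aucs, b$fold_aucs)
  expect_identical(a$cutoff_per_fold, b$cutoff_per_fold)
  expect_error(cv_single_feature_auc(feature[1:20], labels[1:20],
                                     n_folds = 10),
               "n_folds")
})

test_that("external validation carries the cutoff and refits residualization", {
  set.seed(7)
  n <- 300
  labels <- rep(c("decliner", "stable"), c(90, 210))
  feature <- (labels == "decliner") * 1.2 + rnorm(n)
  cv <- cv_single_feature_auc(feature, labels, n_folds = 10, seed = 8)
  ext_labels <- rep(c("decliner", "stable"), c(60, 140))
  ext_feature <- (ext_labels == "decliner") * 1.2 + rnorm(200)
  ext <- validate_external(cv, ext_feature, ext_labels)
  expect_lt(abs(ext$sensitivity - cv$sensitivity), 0.15)
  expect_lt(abs(ext$specificity - cv$specificity), 0.15)
  # boundary cutoffs: everyone called decliner at 0
  cv0 <- cv; cv0$mean_cutoff <- 0
  all_dec <- validate_external(cv0, ext_feature, ext_labels)
  expect_equal(all_dec$sensitivity, 1.0)
  expect_equal(all_dec$specificity, 0.0)
  # a separable predictor separates externally too: sens = spec = 1
  sep_feature <- (labels == "decliner") * 10 + rnorm(n)
  cv_sep <- cv_single_feature_auc(sep_feature, labels, n_folds = 10,
                                  seed = 12)
  ext_sep <- (ext_labels == "decliner") * 10 + rnorm(200)
  sep <- validate_external(cv_sep, ext_sep, ext_labels)
  expect_equal(sep$sensitivity, 1.0)
  expect_equal(sep$specificity, 1.0)
  expect_equal(sep$auc, 1.0)
})

test_that("sensitivity falls and specificity rises as the cutoff grows", {
  set.seed(8)
  n <- 300
  labels <- rep(c("decliner", "stable"), c(100, 200))
  feature <- (labels == "decliner") * 0.8 + rnorm(n)
  cv <- cv_single_feature_auc(feature, labels, n_folds = 10, seed = 9)
  ext_labels <- rep(c("decliner", "stable"), c(70, 130))
  ext_feature <- (ext_labels == "decliner") * 0.8 + rnorm(200)
  sens <- spec <- numeric(0)
  for (cut in c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95)) {
    cvc <- cv; cvc$mean_cutoff <- cut
    v <- validate_external(cvc, ext_feature, ext_labels)
    sens <- c(sens, v$sensitivity); spec <- c(spec, v$specificity)
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("the battery runs identical machinery over a predictor list", {
  set.seed(9)
  n <- 260
  dat <- data.frame(
    progression_status = rep(c("decliner", "stable"), c(80, 180)),
    age = rnorm(n, 73, 6))
  dat$bag <- (dat$progression_status == "decliner") * 1.5 + rnorm(n)
  dat$memory <- -(dat$progression_status == "decliner") * 0.8 + rnorm(n)
  out <- progression_battery(dat, c("bag", "memory", "age"),
                             covariate_cols = "age", n_folds = 10, seed = 10)
  expect_equal(nrow(out$summary), 3)
  expect_gt(out$summary$mean_auc[out$summary$predictor == "bag"], 0.7)
  expect_lt(abs(out$summary$mean_auc[out$summary$predictor == "age"] - 0.5),
            0.1)
  expect_identical(out$summary$passes_gate,
                   out$summary$mean_auc > 0.7)
})
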