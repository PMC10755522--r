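#' Configure the nested cross-validated brain age estimator
#'
#' The estimator runs an outer K-fold loop; within each outer training set
#' it excludes multivariate outliers (Tukey fences per feature, multiplier
#' `outlier_iqr_multiplier`), tunes candidate learners in an inner K-fold
#' loop, refits the winner on the cleaned outer-train set, predicts the
#' outer validation fold, and estimates linear age-bias-correction
#' parameters from those held-out predictions.
#'
#' Candidate learners are epsilon-SVR ([e1071::svm()]) and relevance vector
#' regression ([kernlab::rvm()]). Default grids: SVR over kernel
#' (linear, radial) x cost 10^(-3..3) x epsilon (0.01, 0.1, 1); RVR over
#' kernel (linear, radial). Selection minimizes mean inner-validation MAE;
#' ties break toward SVR before RVR, then the earlier (lexicographically
#' smaller) grid row. Features are z-scaled with the fitting set's own
#' statistics inside every learner, so no validation information leaks.
#'
#' @param n_outer_folds,n_inner_folds fold counts (default 5/5).
#' @param algorithms subset of `c("svr", "rvr")`.
#' @param svr_grid data.frame with columns `kernel`, `cost`, `epsilon`.
#' @param rvr_grid data.frame with column `kernel`.
#' @param outlier_iqr_multiplier Tukey fence multiplier (default 6).
#' @param pooled_bias if `TRUE`, one bias-correction line is fit on the
#'   pooled held-out predictions of all folds instead of per fold
#'   (sensitivity-analysis variant; the default is per fold, estimated and
#'   applied before ensemble averaging).
#' @param seed integer seed controlling fold assignment.
#' @return object of class `bae_config`.
#' @export
bae_config <- function(n_outer_folds = 5,
                       n_inner_folds = 5,
                       algorithms = c("svr", "rvr"),
                       svr_grid = NULL,
                       rvr_grid = NULL,
                       outlier_iqr_multiplier = 6,
                       pooled_bias = FALSE,
                       seed = 1L) {
  algorithms <- match.arg(algorithms, c("svr", "rvr"), several.ok = TRUE)
  if (n_outer_folds < 2 || n_inner_folds < 2)
    stop("fold counts must be >= 2", call. = FALSE)
  if (outlier_iqr_multiplier <= 0)
    stop("`outlier_iqr_multiplier` must be > 0", call. = FALSE)
  if (is.null(svr_grid))
    svr_grid <- expand.grid(kernel = c("linear", "radial"),
                            cost = 10^(-3:3), epsilon = c(0.01, 0.1, 1),
                            stringsAsFactors = FALSE)
  if (is.null(rvr_grid))
    rvr_grid <- data.frame(kernel = c("linear", "radial"),
                           stringsAsFactors = FALSE)
  if ("svr" %in% algorithms && !nrow(svr_grid))
    stop("empty SVR grid", call. = FALSE)
  if ("rvr" %in% algorithms && !nrow(rvr_grid))
    stop("empty RVR grid", call. = FALSE)
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 n_inner_folds = as.integer(n_inner_folds),
                 algorithms = algorithms,
                 svr_grid = order_grid(svr_grid),
                 rvr_grid = order_grid(rvr_grid),
                 outlier_iqr_multiplier = outlier_iqr_multiplier,
                 pooled_bias = isTRUE(pooled_bias),
                 seed = as.integer(seed)),
            class = "bae_config")
}

# Deterministic candidate ordering for tie-breaking: sort grid rows
# lexicographically over their (character-coerced) columns.
order_grid <- function(grid) {
  ord <- do.call(order, lapply(grid, as.character))
  grid[ord, , drop = FALSE]
}

candidate_list <- function(config) {
  cands <- list()
  if ("svr" %in% config$algorithms)
    for (i in seq_len(nrow(config$svr_grid)))
      cands[[length(cands) + 1]] <- c(list(algorithm = "svr"),
                                      as.list(config$svr_grid[i, , drop = FALSE]))
  if ("rvr" %in% config$algorithms)
    for (i in seq_len(nrow(config$rvr_grid)))
      cands[[length(cands) + 1]] <- c(list(algorithm = "rvr"),
                                      as.list(config$rvr_grid[i, , drop = FALSE]))
  cands
}

#' Flag subjects with extreme regional values
#'
#' A subject is flagged iff any feature lies outside the Tukey fences
#' `[Q1 - m*IQR, Q3 + m*IQR]`, with quartiles computed per feature over the
#' given (training) subjects only. Features with zero IQR flag only values
#' differing from the common value by more than 1e-12.
#'
#' @param train_features numeric matrix, subjects x regions (>= 5 rows).
#' @param multiplier fence multiplier `m` (> 0), default 6.
#' @return logical vector, `TRUE` = outlier.
#' @export
detect_outliers <- function(train_features, multiplier = 6) {
  train_features <- as.matrix(train_features)
  if (nrow(train_features) < 5)
    stop("outlier detection needs at least 5 subjects", call. = FALSE)
  if (multiplier <= 0) stop("`multiplier` must be > 0", call. = FALSE)
  q1 <- apply(train_features, 2, stats::quantile, probs = 0.25, names = FALSE)
  q3 <- apply(train_features, 2, stats::quantile, probs = 0.75, names = FALSE)
  iqr <- q3 - q1
  lo <- q1 - multiplier * iqr
  hi <- q3 + multiplier * iqr
  zero <- iqr == 0
  if (any(zero)) {
    med <- apply(train_features[, zero, drop = FALSE], 2, stats::median)
    lo[zero] <- med - 1e-12
    hi[zero] <- med + 1e-12
  }
  out <- sweep(train_features, 2, lo, `<`) | sweep(train_features, 2, hi, `>`)
  unname(rowSums(out) > 0)
}

#' Estimate age-bias-correction parameters
#'
#' Brain-age predictions regress to the training mean: young subjects are
#' over- and old subjects under-estimated, inducing a negative correlation
#' of the raw brain age gap (BAG) with age. The correction fits ordinary
#' least squares of uncorrected BAG (prediction - age) on age over held-out
#' validation predictions: `BAG = alpha * age + beta`.
#'
#' @param validation_ages,validation_predictions numeric vectors (>= 3
#'   pairs, age variance > 0).
#' @return named vector `c(alpha, beta)`; for a perfect predictor both are 0.
#' @seealso [apply_bias_correction()]
#' @export
estimate_bias_params <- function(validation_ages, validation_predictions) {
  stopifnot(length(validation_ages) == length(validation_predictions))
  if (length(validation_ages) < 3)
    stop("need at least 3 validation pairs", call. = FALSE)
  if (stats::var(validation_ages) == 0)
    stop("validation ages have zero variance", call. = FALSE)
  bag <- validation_predictions - validation_ages
  fit <- stats::lm.fit(cbind(1, validation_ages), bag)
  c(alpha = unname(fit$coefficients[2]), beta = unname(fit$coefficients[1]))
}

#' @rdname estimate_bias_params
#' @param raw_prediction raw predicted brain age, years.
#' @param age chronological age, years.
#' @param alpha,beta parameters from [estimate_bias_params()].
#' @return `apply_bias_correction()`: corrected brain age,
#'   `raw - (alpha * age + beta)`.
#' @export
apply_bias_correction <- function(raw_prediction, age, alpha, beta) {
  stopifnot(all(is.finite(raw_prediction)), all(is.finite(age)),
            is.finite(alpha), is.finite(beta))
  raw_prediction - (alpha * age + beta)
}

# ---- learners ---------------------------------------------------------------

# Fit one candidate on (x, y); standardization statistics come from x itself.
fit_learner <- function(x, y, cand) {
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center, scale_)
  y_center <- 0
  model <- if (cand$algorithm == "svr") {
    suppressWarnings(e1071::svm(
      xs, y, type = "eps-regression", kernel = cand$kernel,
      cost = cand$cost, epsilon = cand$epsilon,
      gamma = 1 / ncol(xs), scale = FALSE))
  } else {
    # kernlab's RVM has no intercept term: center the response and add the
    # mean back at prediction time
    y_center <- mean(y)
    kern <- if (cand$kernel == "linear") "vanilladot" else "rbfdot"
    kpar <- if (cand$kernel == "linear") list() else list(sigma = 1 / ncol(xs))
    suppressWarnings(kernlab::rvm(xs, as.numeric(y) - y_center, kernel = kern,
                                  kpar = kpar))
  }
  list(model = model, center = center, scale = scale_, y_center = y_center,
       candidate = cand)
}

predict_learner <- function(fit, x) {
  xs <- scale(x, fit$center, fit$scale)
  as.numeric(stats::predict(fit$model, xs)) + fit$y_center
}

# Deterministic k-fold assignment of n items (shuffled, unstratified).
fold_assignment <- function(n, k, seed) {
  ord <- local_seed(seed, sample.int(n))
  folds <- rep(seq_len(k), length.out = n)
  out <- integer(n)
  out[ord] <- folds
  out
}

# Mean inner-validation MAE of one candidate.
inner_cv_mae <- function(x, y, cand, inner_folds) {
  k <- max(inner_folds)
  maes <- vapply(seq_len(k), function(j) {
    tr <- inner_folds != j
    fit <- tryCatch(fit_learner(x[tr, , drop = FALSE], y[tr], cand),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pred <- tryCatch(predict_learner(fit, x[!tr, , drop = FALSE]),
                     error = function(e) rep(NA_real_, sum(!tr)))
    if (anyNA(pred)) return(Inf)
    mean(abs(pred - y[!tr]))
  }, numeric(1))
  mean(maes)
}

#' Fit the nested cross-validated brain age ensemble
#'
#' Runs the full outer loop described in [bae_config()] on a single-modality
#' training cohort (normally cognitively normal subjects) and returns the
#' ensemble of per-fold final models with their bias-correction parameters,
#' plus one held-out prediction per training subject.
#'
#' Outlier exclusion is applied to each outer-train set only; validation
#' subjects are never excluded, but subjects flagged in any fold are marked
#' so that evaluation metrics can be restricted to non-outliers.
#'
#' @param train_cohort a `cohort`.
#' @param config a `bae_config`.
#' @return object of class `bae_ensemble` with elements `fold_models`,
#'   `heldout` (per-subject held-out prediction table), `config`,
#'   `modality_tag`, `atlas_fingerprint`, `train_fingerprint`.
#' @export
fit_nested <- function(train_cohort, config = bae_config()) {
  stopifnot(inherits(train_cohort, "cohort"), inherits(config, "bae_config"))
  x <- train_cohort$features
  age <- train_cohort$phenotype$chronological_age
  n <- nrow(x)
  if (n < 5 * config$n_outer_folds)
    stop(sprintf("need at least %d subjects for %d outer folds (got %d)",
                 5 * config$n_outer_folds, config$n_outer_folds, n),
         call. = FALSE)
  cands <- candidate_list(config)
  outer_folds <- fold_assignment(n, config$n_outer_folds,
                                 derive_seed(config$seed, "outer_folds"))
  fold_models <- vector("list", config$n_outer_folds)
  heldout <- data.frame(subject_id = train_cohort$phenotype$subject_id,
                        chronological_age = age,
                        fold = outer_folds,
                        raw_predicted_age = NA_real_,
                        corrected_predicted_age = NA_real_,
                        outlier = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(config$n_outer_folds)) {
    tr_idx <- which(outer_folds != k)
    va_idx <- which(outer_folds == k)
    if (stats::var(age[tr_idx]) == 0 || stats::var(age[va_idx]) == 0)
      stop("degenerate fold: constant ages", call. = FALSE)
    mask <- detect_outliers(x[tr_idx, , drop = FALSE],
                            config$outlier_iqr_multiplier)
    clean <- tr_idx[!mask]
    heldout$outlier[tr_idx[mask]] <- TRUE
    inner <- fold_assignment(length(clean), config$n_inner_folds,
                             derive_seed(config$seed,
                                         paste0("inner_folds_", k)))
    inner_mae <- vapply(cands, function(cand) {
      inner_cv_mae(x[clean, , drop = FALSE], age[clean], cand, inner)
    }, numeric(1))
    # first minimum = deterministic tie-break; if the winner fails to refit
    # on the full cleaned outer-train set, fall back to the next-best
    fit <- NULL
    for (best in order(inner_mae)) {
      if (!is.finite(inner_mae[best])) break
      fit <- tryCatch(fit_learner(x[clean, , drop = FALSE], age[clean],
                                  cands[[best]]),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("no candidate learner could be fit on outer fold ", k,
           call. = FALSE)
    raw_va <- predict_learner(fit, x[va_idx, , drop = FALSE])
    bias <- estimate_bias_params(age[va_idx], raw_va)
    corr_va <- apply_bias_correction(raw_va, age[va_idx],
                                     bias["alpha"], bias["beta"])
    heldout$raw_predicted_age[va_idx] <- raw_va
    heldout$corrected_predicted_age[va_idx] <- corr_va
    fold_models[[k]] <- structure(list(
      fold_index = k, chosen_algorithm = cands[[best]]$algorithm,
      chosen_hyperparameters = cands[[best]][-1],
      fit = fit, bias_alpha = unname(bias["alpha"]),
      bias_beta = unname(bias["beta"]),
      inner_validation_mae = inner_mae[best],
      outer_validation_mae = mean(abs(corr_va - age[va_idx])),
      outlier_mask = stats::setNames(mask,
        train_cohort$phenotype$subject_id[tr_idx])), class = "fold_model")
  }
  if (config$pooled_bias) {
    ok <- !is.na(heldout$raw_predicted_age)
    pooled <- estimate_bias_params(heldout$chronological_age[ok],
                                   heldout$raw_predicted_age[ok])
    for (k in seq_along(fold_models)) {
      fold_models[[k]]$bias_alpha <- unname(pooled["alpha"])
      fold_models[[k]]$bias_beta <- unname(pooled["beta"])
    }
    heldout$corrected_predicted_age <- apply_bias_correction(
      heldout$raw_predicted_age, heldout$chronological_age,
      pooled["alpha"], pooled["beta"])
  }
  heldout$bag <- heldout$corrected_predicted_age - heldout$chronological_age
  structure(list(fold_models = fold_models, heldout = heldout,
                 config = config, modality_tag = train_cohort$modality_tag,
                 atlas_fingerprint = object_fingerprint(colnames(x)),
                 train_fingerprint = object_fingerprint(
                   train_cohort$phenotype$subject_id)),
            class = "bae_ensemble")
}

#' @export
print.bae_ensemble <- function(x, ...) {
  algos <- vapply(x$fold_models, `[[`, "", "chosen_algorithm")
  cat(sprintf("<bae_ensemble> %d folds (%s), modality %s\n",
              length(x$fold_models), paste(algos, collapse = ","),
              x$modality_tag))
  cat(sprintf("  held-out MAE (non-outliers): %.3f y\n",
              bae_metrics(x$heldout[!x$heldout$outlier, ])$mae))
  invisible(x)
}

# Metrics over a prediction table with chronological_age /
# corrected_predicted_age / bag columns.
bae_metrics <- function(pred) {
  ok <- stats::complete.cases(pred[, c("chronological_age",
                                       "corrected_predicted_age")])
  pred <- pred[ok, , drop = FALSE]
  if (!nrow(pred)) stop("no complete predictions to evaluate", call. = FALSE)
  err <- pred$corrected_predicted_age - pred$chronological_age
  list(mae = mean(abs(err)),
       r_squared = 1 - sum(err^2) /
         sum((pred$chronological_age - mean(pred$chronological_age))^2),
       bag_range = range(pred$bag),
       mean_bag = mean(pred$bag),
       n = nrow(pred))
}

#' Predict brain age for a cohort
#'
#' Two modes mirror how the training and external cohorts are handled:
#' `held_out` returns the one prediction per training subject produced by
#' the fold in which the subject was in the validation set (only valid for
#' the cohort the ensemble was trained on). `ensemble_average` has every
#' fold model predict every subject, corrects each prediction with that
#' fold's bias parameters, and averages the corrected values; the BAG is
#' computed from the averaged value.
#'
#' @param ensemble a `bae_ensemble`.
#' @param cohort a `cohort` of the same modality.
#' @param mode `"held_out"` or `"ensemble_average"`.
#' @return list with `predictions` (data.frame: subject_id,
#'   chronological_age, raw_predicted_age, corrected_predicted_age, bag,
#'   fold_1..fold_K corrected estimates in ensemble mode, source, outlier
#'   flag in held-out mode) and `metrics` (mae, r_squared, bag_range,
#'   mean_bag, n; held-out metrics cover non-outlier subjects only).
#' @export
predict_cohort <- function(ensemble, cohort,
                           mode = c("ensemble_average", "held_out")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "bae_ensemble"), inherits(cohort, "cohort"))
  if (!identical(ensemble$modality_tag, cohort$modality_tag))
    stop(sprintf("modality mismatch: ensemble %s vs cohort %s",
                 ensemble$modality_tag, cohort$modality_tag), call. = FALSE)
  if (mode == "held_out") {
    if (!identical(ensemble$train_fingerprint,
                   object_fingerprint(cohort$phenotype$subject_id)))
      stop("held_out mode is only valid for the training cohort",
           call. = FALSE)
    pred <- ensemble$heldout
    pred$source <- "held_out"
    return(list(predictions = pred,
                metrics = bae_metrics(pred[!pred$outlier, , drop = FALSE])))
  }
  age <- cohort$phenotype$chronological_age
  per_fold <- vapply(ensemble$fold_models, function(fm) {
    raw <- predict_learner(fm$fit, cohort$features)
    apply_bias_correction(raw, age, fm$bias_alpha, fm$bias_beta)
  }, numeric(nrow(cohort$features)))
  per_fold <- matrix(per_fold, nrow = nrow(cohort$features))
  raw_fold <- vapply(ensemble$fold_models, function(fm) {
    predict_learner(fm$fit, cohort$features)
  }, numeric(nrow(cohort$features)))
  raw_fold <- matrix(raw_fold, nrow = nrow(cohort$features))
  corrected <- rowMeans(per_fold)
  pred <- data.frame(subject_id = cohort$phenotype$subject_id,
                     chronological_age = age,
                     raw_predicted_age = rowMeans(raw_fold),
                     corrected_predicted_age = corrected,
                     bag = corrected - age,
                     source = "ensemble", stringsAsFactors = FALSE)
  colnames(per_fold) <- sprintf("fold_%d", seq_len(ncol(per_fold)))
  pred <- cbind(pred, as.data.frame(per_fold))
  list(predictions = pred, metrics = bae_metrics(pred))
}

#' Serialize / restore a trained ensemble
#'
#' The archive is a single RDS file holding the ensemble (fold models,
#' bias parameters, config, fingerprints).
#' @param ensemble a `bae_ensemble`.
#' @param path file path.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "bae_ensemble"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "bae_ensemble")) stop("not an ensemble archive",
                                           call. = FALSE)
  obj
}
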