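#' Reference-anchored standardized residuals
#'
#' Fits `values ~ covariates` (with intercept) by least squares on the
#' reference rows only (normally the cognitively stable subjects of a
#' training fold), computes residuals against that fit for all rows, and
#' standardizes by the reference-group residual standard deviation. The
#' reference residuals have mean zero by construction.
#'
#' @param values numeric vector.
#' @param covariates matrix / data.frame, or `NULL` for a plain z-score
#'   against the reference mean and SD.
#' @param reference_mask logical vector marking the reference rows
#'   (`sum(reference_mask)` must exceed the covariate count + 2).
#' @return standardized residual vector over all rows.
#' @export
residualize <- function(values, covariates = NULL, reference_mask) {
  cov_mat <- if (is.null(covariates)) {
    matrix(numeric(0), length(values), 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  stopifnot(length(reference_mask) == length(values),
            nrow(cov_mat) == length(values), is.logical(reference_mask))
  n_ref <- sum(reference_mask)
  if (n_ref <= ncol(cov_mat) + 2)
    stop(sprintf("reference subset too small: %d rows for %d covariates",
                 n_ref, ncol(cov_mat)), call. = FALSE)
  Z <- cbind(intercept = rep(1, length(values)), cov_mat)
  Zr <- Z[reference_mask, , drop = FALSE]
  if (qr(Zr)$rank < ncol(Zr))
    stop("singular covariate design on the reference rows", call. = FALSE)
  beta <- stats::lm.fit(Zr, values[reference_mask])$coefficients
  res <- values - as.numeric(Z %*% beta)
  ref_sd <- stats::sd(res[reference_mask])
  if (ref_sd <= 1e-10 * max(1e-300, stats::sd(values[reference_mask])))
    stop("zero residual variance in the reference group", call. = FALSE)
  res / ref_sd
}

#' Area under the ROC curve
#'
#' Rank-based AUC, identical to the Mann-Whitney U probability that a
#' positive-class score exceeds a negative-class score, with ties counted
#' one half.
#'
#' @param scores numeric vector.
#' @param labels binary labels; the positive class is `"decliner"`, `1`, or
#'   `TRUE`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  labels <- as.character(labels)
  u <- unique(labels)
  if (!all(u %in% c("decliner", "stable")))
    stop("labels must be stable/decliner (or 0/1, FALSE/TRUE)",
         call. = FALSE)
  labels == "decliner"
}

#' A-priori-probability classification cutoff
#'
#' The probability cutoff for calling a subject a decliner is the decliner
#' prevalence of the training fold; classification uses `>=` (ties called
#' decliner).
#'
#' @param training_labels binary labels of the training fold.
#' @return cutoff in (0, 1).
#' @export
derive_cutoff <- function(training_labels) {
  pos <- as_positive(training_labels)
  if (!any(pos) || all(pos))
    stop("training fold has a single class; cannot derive a cutoff",
         call. = FALSE)
  mean(pos)
}

# Stratified k-fold assignment preserving class proportions; seeded.
stratified_folds <- function(labels, k, seed) {
  pos <- as_positive(labels)
  folds <- integer(length(labels))
  local_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(pos == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

#' Cross-validated single-feature progression classifier
#'
#' Stratified k-fold cross-validation of a one-predictor logistic
#' regression for stable-vs-decliner status. In each fold the predictor is
#' residualized on the covariates with [residualize()] anchored on the
#' *stable subjects of the training fold*, the classifier is fit on the
#' training rows, and the validation rows are scored. Reported are the
#' per-fold and mean validation AUCs, the per-fold a-priori cutoffs
#' ([derive_cutoff()]), and sensitivity/specificity of the pooled
#' validation predictions at the mean cutoff. A tiny ridge penalty (1e-8)
#' stabilizes separable folds without distorting predicted probabilities.
#'
#' @param feature numeric predictor vector.
#' @param labels stable/decliner labels.
#' @param covariates matrix / data.frame or `NULL`.
#' @param n_folds default 10; every class must have at least `n_folds`
#'   members.
#' @param seed fold assignment seed.
#' @param predictor_name label carried into the result.
#' @return object of class `progression_cv`: `predictor_name`, `fold_aucs`,
#'   `mean_auc`, `cutoff_per_fold`, `mean_cutoff`, `cutoff_range`,
#'   `sensitivity`, `specificity`, `n_folds`, `seed`, `covariates`,
#'   `final_model` (coefficients of the logistic fit on all rows, with the
#'   residualization anchored on all stable subjects, used for external
#'   validation).
#' @export
cv_single_feature_auc <- function(feature, labels, covariates = NULL,
                                  n_folds = 10, seed = 1L,
                                  predictor_name = deparse1(substitute(feature))) {
  cov_mat <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(feature, labels,
                              if (is.null(cov_mat)) rep(TRUE, length(feature))
                              else cov_mat)
  feature <- feature[ok]
  labels <- labels[ok]
  if (!is.null(cov_mat)) cov_mat <- cov_mat[ok, , drop = FALSE]
  pos <- as_positive(labels)
  if (min(sum(pos), sum(!pos)) < n_folds)
    stop(sprintf("smallest class has %d members; use n_folds <= that",
                 min(sum(pos), sum(!pos))), call. = FALSE)
  folds <- stratified_folds(labels, n_folds,
                            derive_seed(seed, "progression_folds"))
  fold_aucs <- numeric(n_folds)
  cutoffs <- numeric(n_folds)
  pooled_prob <- rep(NA_real_, length(feature))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    ref <- tr & !pos            # stable subjects of the training fold
    resid <- residualize(feature, cov_mat, reference_mask = ref)
    fit <- fit_logistic1(resid[tr], pos[tr])
    prob <- stats::plogis(fit[1] + fit[2] * resid[!tr])
    fold_aucs[k] <- roc_auc(prob, pos[!tr])
    cutoffs[k] <- derive_cutoff(pos[tr])
    pooled_prob[!tr] <- prob
  }
  mean_cutoff <- mean(cutoffs)
  cls <- pooled_prob >= mean_cutoff
  final_resid <- residualize(feature, cov_mat, reference_mask = !pos)
  final_fit <- fit_logistic1(final_resid, pos)
  structure(list(predictor_name = predictor_name, fold_aucs = fold_aucs,
                 mean_auc = mean(fold_aucs), cutoff_per_fold = cutoffs,
                 mean_cutoff = mean_cutoff, cutoff_range = range(cutoffs),
                 sensitivity = mean(cls[pos]), specificity = mean(!cls[!pos]),
                 n_folds = n_folds, seed = seed,
                 covariates = colnames(cov_mat) %||% character(0),
                 final_model = final_fit),
            class = "progression_cv")
}

# One-feature logistic regression with a negligible ridge (1e-8) for
# numerical stability on (near-)separable data; IRLS.
fit_logistic1 <- function(x, y, lambda = 1e-8, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(stats::qlogis(mean(y)), 0)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    A <- crossprod(X, w * X) + diag(lambda, 2)
    new <- solve(A, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  as.numeric(beta)
}

#' @export
print.progression_cv <- function(x, ...) {
  cat(sprintf(
    "<progression_cv> %s: mean AUC %.3f over %d folds; cutoff %.3f (%.3f-%.3f); sens %.2f spec %.2f\n",
    x$predictor_name, x$mean_auc, x$n_folds, x$mean_cutoff,
    x$cutoff_range[1], x$cutoff_range[2], x$sensitivity, x$specificity))
  invisible(x)
}

#' Validate a progression classifier on an external cohort
#'
#' Applies the internally fit logistic model and the internally derived
#' mean cutoff to an external cohort. Following the training rule, the
#' covariate residualization is refit on the *external stable subjects*;
#' only the classifier coefficients and the cutoff are carried over.
#'
#' @param cv_result a `progression_cv`.
#' @param feature external predictor vector.
#' @param labels external stable/decliner labels.
#' @param covariates external covariates (same columns as in training).
#' @return list `sensitivity`, `specificity`, `auc`, `cutoff`, `n`.
#' @export
validate_external <- function(cv_result, feature, labels, covariates = NULL) {
  stopifnot(inherits(cv_result, "progression_cv"))
  cov_mat <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(feature, labels,
                              if (is.null(cov_mat)) rep(TRUE, length(feature))
                              else cov_mat)
  if (!all(ok)) {
    feature <- feature[ok]; labels <- labels[ok]
    if (!is.null(cov_mat)) cov_mat <- cov_mat[ok, , drop = FALSE]
  }
  pos <- as_positive(labels)
  if (!any(pos) || all(pos))
    stop("external cohort must contain both classes", call. = FALSE)
  resid <- residualize(feature, cov_mat, reference_mask = !pos)
  prob <- stats::plogis(cv_result$final_model[1] +
                          cv_result$final_model[2] * resid)
  cls <- prob >= cv_result$mean_cutoff
  list(sensitivity = mean(cls[pos]), specificity = mean(!cls[!pos]),
       auc = roc_auc(prob, pos), cutoff = cv_result$mean_cutoff,
       n = length(prob))
}

#' Run the progression battery over several predictors
#'
#' Applies [cv_single_feature_auc()] with shared covariates, fold count and
#' seed to each named predictor column of `data` -- the comparison battery
#' of candidate prognostic markers (BAG per modality, cognitive scores,
#' pathology markers, age) uses identical machinery for every predictor.
#'
#' @param data data.frame holding predictors, labels and covariates.
#' @param predictors character vector of predictor column names.
#' @param label_col name of the stable/decliner column.
#' @param covariate_cols character vector of covariate column names.
#' @param n_folds,seed passed through.
#' @param auc_gate predictors whose mean AUC exceeds this gate (default
#'   0.7) are marked as candidates for external validation.
#' @return list of `progression_cv` plus a `summary` data.frame.
#' @export
progression_battery <- function(data, predictors,
                                label_col = "progression_status",
                                covariate_cols = character(0),
                                n_folds = 10, seed = 1L, auc_gate = 0.7) {
  results <- lapply(predictors, function(pn) {
    covs <- if (length(covariate_cols)) data[, covariate_cols, drop = FALSE]
            else NULL
    if (!is.null(covs)) {
      # a predictor cannot be residualized on (a copy of) itself
      dup <- vapply(covs, function(cv) {
        isTRUE(abs(suppressWarnings(stats::cor(cv, data[[pn]],
                                               use = "complete.obs"))) > 0.999)
      }, logical(1))
      covs <- covs[, !dup, drop = FALSE]
      if (!ncol(covs)) covs <- NULL
    }
    cv_single_feature_auc(data[[pn]], data[[label_col]], covs,
                          n_folds = n_folds,
                          seed = derive_seed(seed, paste0("battery_", pn)),
                          predictor_name = pn)
  })
  names(results) <- predictors
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(predictor = r$predictor_name, mean_auc = r$mean_auc,
               cutoff_mean = r$mean_cutoff,
               cutoff_low = r$cutoff_range[1],
               cutoff_high = r$cutoff_range[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               passes_gate = r$mean_auc > auc_gate,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary, auc_gate = auc_gate)
}
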