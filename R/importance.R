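#' Permutation importance of one fold model
#'
#' The importance delta of a region is the mean increase in mean absolute
#' error (years) when that region's feature column is randomly permuted in
#' the evaluation set, over `n_repeats` independent seeded permutations.
#' Predictions are bias-corrected with the fold's own parameters so the
#' delta lives on the same accuracy scale as the reported MAE.
#'
#' @param fold_model a `fold_model` from a fitted ensemble.
#' @param eval_features matrix of evaluation subjects (must be disjoint from
#'   the model's training subjects for an honest estimate).
#' @param eval_ages chronological ages of the evaluation subjects.
#' @param n_repeats permutations per region (>= 1), default 10.
#' @param seed integer; permutations are seeded and independent per repeat.
#' @return named numeric vector of deltas, one per region.
#' @export
permutation_importance <- function(fold_model, eval_features, eval_ages,
                                   n_repeats = 10, seed = 1L) {
  stopifnot(inherits(fold_model, "fold_model"), n_repeats >= 1)
  eval_features <- as.matrix(eval_features)
  if (ncol(eval_features) != length(fold_model$fit$center))
    stop(sprintf("region count mismatch: model has %d, features have %d",
                 length(fold_model$fit$center), ncol(eval_features)),
         call. = FALSE)
  n <- nrow(eval_features)
  predict_corrected <- function(x) {
    apply_bias_correction(predict_learner(fold_model$fit, x), eval_ages,
                          fold_model$bias_alpha, fold_model$bias_beta)
  }
  base_mae <- mean(abs(predict_corrected(eval_features) - eval_ages))
  p <- ncol(eval_features)
  delta <- matrix(NA_real_, n_repeats, p)
  for (r in seq_len(n_repeats)) {
    perm <- local_seed(derive_seed(seed, paste0("perm_repeat_", r)), {
      replicate(p, sample.int(n))
    })
    for (j in seq_len(p)) {
      xp <- eval_features
      xp[, j] <- xp[perm[, j], j]
      delta[r, j] <- mean(abs(predict_corrected(xp) - eval_ages)) - base_mae
    }
  }
  stats::setNames(colMeans(delta), colnames(eval_features))
}

#' Average permutation importance over an ensemble
#'
#' Evaluates [permutation_importance()] for each fold model on that fold's
#' own outer-validation subjects of the training cohort, then averages the
#' per-region deltas over folds.
#'
#' @param ensemble a `bae_ensemble`.
#' @param train_cohort the cohort the ensemble was trained on.
#' @param n_repeats,seed passed per fold (fold-specific derived seeds).
#' @return object of class `importance_map`: list with `delta` (named
#'   vector), `n_repeats`, `seed`, `folds`, `modality_tag`.
#' @export
ensemble_importance <- function(ensemble, train_cohort, n_repeats = 10,
                                seed = 1L) {
  stopifnot(inherits(ensemble, "bae_ensemble"))
  if (!identical(ensemble$train_fingerprint,
                 object_fingerprint(train_cohort$phenotype$subject_id)))
    stop("`train_cohort` is not the cohort this ensemble was trained on",
         call. = FALSE)
  folds <- ensemble$heldout$fold
  deltas <- vapply(ensemble$fold_models, function(fm) {
    idx <- which(folds == fm$fold_index)
    permutation_importance(
      fm, train_cohort$features[idx, , drop = FALSE],
      train_cohort$phenotype$chronological_age[idx],
      n_repeats = n_repeats,
      seed = derive_seed(seed, paste0("importance_fold_", fm$fold_index)))
  }, numeric(ncol(train_cohort$features)))
  structure(list(delta = rowMeans(deltas), n_repeats = n_repeats,
                 seed = seed,
                 folds = vapply(ensemble$fold_models, `[[`, 0L, "fold_index"),
                 modality_tag = ensemble$modality_tag),
            class = "importance_map")
}

#' Summarize an importance map anatomically
#'
#' Median delta per lobe, hemisphere, or lobe-by-hemisphere cell, following
#' the atlas grouping; groups without member regions are omitted.
#'
#' @param map an `importance_map` (or named delta vector).
#' @param atlas an `atlas_spec` covering every region in the map.
#' @param grouping `"lobe"`, `"hemisphere"` or `"lobe_by_hemisphere"`.
#' @return data.frame with the grouping column(s) and `median_delta`.
#' @export
summarize_by_anatomy <- function(map, atlas = default_atlas(),
                                 grouping = c("lobe", "hemisphere",
                                              "lobe_by_hemisphere")) {
  grouping <- match.arg(grouping)
  delta <- if (inherits(map, "importance_map")) map$delta else map
  cols <- region_columns(atlas)
  unmapped <- setdiff(names(delta), cols)
  if (length(unmapped))
    stop("region(s) not in atlas: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  if (length(setdiff(cols, names(delta))))
    stop("atlas region(s) missing from importance map: ",
         paste(setdiff(cols, names(delta)), collapse = ", "), call. = FALSE)
  delta <- delta[cols]
  key <- switch(grouping,
    lobe = list(lobe = atlas$lobe),
    hemisphere = list(hemisphere = atlas$hemisphere),
    lobe_by_hemisphere = list(lobe = atlas$lobe,
                              hemisphere = atlas$hemisphere))
  agg <- stats::aggregate(delta, by = key, FUN = stats::median)
  names(agg)[ncol(agg)] <- "median_delta"
  agg
}

#' Correlate two importance maps across regions
#'
#' Pearson correlation of per-region deltas with a two-sided p-value and a
#' Fisher-z 95% confidence interval; used to ask whether two modalities
#' rely on the same anatomy.
#'
#' @param map_a,map_b `importance_map`s (or named delta vectors) over the
#'   same region set.
#' @return list `r`, `p_value`, `ci_95`, `n`.
#' @export
compare_maps <- function(map_a, map_b) {
  a <- if (inherits(map_a, "importance_map")) map_a$delta else map_a
  b <- if (inherits(map_b, "importance_map")) map_b$delta else map_b
  if (!identical(names(a), names(b)))
    stop("maps cover different region sets", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in an importance map", call. = FALSE)
  n <- length(a)
  r <- stats::cor(a, b)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  z <- atanh(r)
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(r = r, p_value = p, ci_95 = tanh(c(z - hw, z + hw)), n = n)
}

#' Write an importance map and its anatomical summaries as CSVs
#'
#' @param map an `importance_map`.
#' @param atlas an `atlas_spec`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_importance <- function(map, atlas = default_atlas(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regional <- data.frame(atlas[, c("region_id", "region_name", "lobe",
                                   "hemisphere")],
                         delta = unname(map$delta[region_columns(atlas)]))
  utils::write.csv(regional, file.path(dir, "importance_regions.csv"),
                   row.names = FALSE)
  for (g in c("lobe", "hemisphere", "lobe_by_hemisphere"))
    utils::write.csv(summarize_by_anatomy(map, atlas, g),
                     file.path(dir, sprintf("importance_by_%s.csv", g)),
                     row.names = FALSE)
  invisible(dir)
}
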