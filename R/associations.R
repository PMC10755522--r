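#' Choose Pearson vs Spearman by normality
#'
#' Applies a Shapiro-Wilk test to each focal variable; Pearson is selected
#' iff both are compatible with normality (p >= `alpha`), otherwise
#' Spearman. The W statistics and p-values are attached so the decision is
#' auditable.
#'
#' @param x,y numeric vectors (n >= 8; below that the normality screen is
#'   unreliable and the caller must choose a method explicitly).
#' @param alpha normality screen level, default 0.05.
#' @return `"pearson"` or `"spearman"` with attribute `shapiro` (data.frame
#'   of W and p per variable).
#' @export
select_method <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 8)
    stop("n < 8: too few observations for the normality screen; ",
         "pass an explicit method", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) variable", call. = FALSE)
  sx <- stats::shapiro.test(x)
  sy <- stats::shapiro.test(y)
  method <- if (sx$p.value >= alpha && sy$p.value >= alpha) "pearson"
            else "spearman"
  attr(method, "shapiro") <- data.frame(
    variable = c("x", "y"), W = c(sx$statistic, sy$statistic),
    p = c(sx$p.value, sy$p.value), row.names = NULL)
  method
}

residualize_on <- function(v, Z) {
  fit <- stats::lm.fit(Z, v)
  fit$residuals
}

#' Covariate-adjusted correlation
#'
#' Partial correlation of `x` and `y` given covariates: both variables are
#' residualized on the covariates (with intercept) by least squares and the
#' residuals correlated. The Spearman variant rank-transforms `x` and `y`
#' (average ranks for ties) before residualization, i.e. a partial Pearson
#' on ranks. Significance uses the t distribution with `n - k - 2` degrees
#' of freedom (`k` covariates); the 95% CI is Fisher-z. Rows with missing
#' data in `x`, `y`, or any covariate are removed listwise.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix / data.frame of covariate columns, or
#'   `NULL` for a plain correlation.
#' @param method `"auto"` (Shapiro-Wilk screen via [select_method()]),
#'   `"pearson"`, or `"spearman"`.
#' @param x_name,y_name labels carried into the result.
#' @return object of class `association_result`: list with `x_name`,
#'   `y_name`, `method`, `statistic`, `p_value`, `ci_95`, `n_used`,
#'   `n_excluded`, `covariates`, `tier` (`NA` until tiered).
#' @seealso [apply_significance_tiers()]
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("auto", "pearson", "spearman"),
                                x_name = deparse1(substitute(x)),
                                y_name = deparse1(substitute(y))) {
  method <- match.arg(method)
  cov_mat <- if (is.null(covariates)) {
    matrix(numeric(0), length(x), 0)
  } else {
    as.matrix(as.data.frame(covariates))
  }
  stopifnot(length(x) == length(y), nrow(cov_mat) == length(x))
  ok <- stats::complete.cases(x, y, cov_mat)
  n_total <- length(x)
  x <- x[ok]; y <- y[ok]
  cov_mat <- cov_mat[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(cov_mat)
  if (n <= k + 3)
    stop(sprintf("insufficient data: n = %d after listwise deletion with %d covariates",
                 n, k), call. = FALSE)
  if (method == "auto") method <- as.character(select_method(x, y))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  Z <- cbind(intercept = rep(1, n), cov_mat)
  if (qr(Z)$rank < ncol(Z))
    stop("singular covariate matrix", call. = FALSE)
  rx <- residualize_on(x, Z)
  ry <- residualize_on(y, Z)
  if (stats::sd(rx) <= 1e-10 * max(1e-300, stats::sd(x)) ||
      stats::sd(ry) <= 1e-10 * max(1e-300, stats::sd(y)))
    stop("degenerate residuals (a focal variable is fully explained ",
         "by the covariates)", call. = FALSE)
  r <- stats::cor(rx, ry)
  dof <- n - k - 2
  t <- r * sqrt(dof / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), dof)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- stats::qnorm(0.975) / sqrt(n - k - 3)
  structure(list(x_name = x_name, y_name = y_name, method = method,
                 statistic = r, p_value = p,
                 ci_95 = tanh(c(z - hw, z + hw)),
                 n_used = n, n_excluded = n_total - n,
                 covariates = colnames(cov_mat) %||% character(0),
                 tier = NA_character_),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  sym <- if (x$method == "pearson") "r" else "rho"
  cat(sprintf("%s ~ %s | %s: %s = %.3f, p = %.4g, 95%% CI [%.3f, %.3f], n = %d%s\n",
              x$x_name, x$y_name,
              if (length(x$covariates)) paste(x$covariates, collapse = "+")
              else "(none)",
              sym, x$statistic, x$p_value, x$ci_95[1], x$ci_95[2], x$n_used,
              if (!is.na(x$tier)) paste0(" [", x$tier, "]") else ""))
  invisible(x)
}

#' Paired comparison of per-subject absolute errors
#'
#' Two-sided paired t-test on matched vectors of absolute prediction
#' errors, used to compare estimation accuracy of two modalities on the
#' same subjects.
#'
#' @param abs_err_a,abs_err_b equal-length vectors of absolute errors for
#'   the same subjects (n >= 3).
#' @return object of class `group_comparison`: list with `test`,
#'   `statistic`, `dof`, `p_value`, `ci_95` (mean difference a - b),
#'   `estimate`, `n`.
#' @export
compare_mae_paired <- function(abs_err_a, abs_err_b) {
  if (length(abs_err_a) != length(abs_err_b))
    stop("paired comparison needs equal-length vectors", call. = FALSE)
  if (length(abs_err_a) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- abs_err_a - abs_err_b
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # degenerate but well-defined: identical vectors give t = 0, p = 1; a
    # constant shift gives a point interval at the shift
    return(structure(list(
      test = "paired_t",
      statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
      dof = length(d) - 1,
      p_value = if (mean(d) == 0) 1 else 0,
      ci_95 = c(mean(d), mean(d)), estimate = mean(d),
      n = length(d), covariates = character(0)),
      class = "group_comparison"))
  }
  tt <- stats::t.test(abs_err_a, abs_err_b, paired = TRUE)
  structure(list(test = "paired_t", statistic = unname(tt$statistic),
                 dof = unname(tt$parameter), p_value = tt$p.value,
                 ci_95 = as.numeric(tt$conf.int),
                 estimate = unname(tt$estimate),
                 n = length(abs_err_a), covariates = character(0)),
            class = "group_comparison")
}

#' Welch two-sample comparison
#'
#' Welch's t-test (unequal variances, Welch-Satterthwaite dof) of two
#' independent groups, e.g. BAG of a clinical group vs the normative group.
#'
#' @param values_a,values_b numeric vectors (each n >= 3).
#' @return `group_comparison` (difference a - b).
#' @export
compare_groups_t <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs n >= 3", call. = FALSE)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    stop("degenerate variance in both groups", call. = FALSE)
  tt <- stats::t.test(values_a, values_b)
  structure(list(test = "two_sample_t", statistic = unname(tt$statistic),
                 dof = unname(tt$parameter), p_value = tt$p.value,
                 ci_95 = as.numeric(tt$conf.int),
                 estimate = unname(diff(rev(tt$estimate))),
                 n = c(length(values_a), length(values_b)),
                 covariates = character(0)),
            class = "group_comparison")
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits `outcome ~ group + covariates` and tests the group term with an F
#' statistic on (1, n - k - 2) degrees of freedom (equivalent to the
#' type-III test for a single binary factor). Covariate coefficients are
#' returned alongside.
#'
#' @param outcome numeric vector.
#' @param group binary factor / character / 0-1 vector.
#' @param covariates matrix or data.frame (may be `NULL`).
#' @return `group_comparison` with `statistic` = F, plus
#'   `covariate_coefficients`.
#' @export
ancova_group_effect <- function(outcome, group, covariates = NULL) {
  cov_df <- if (is.null(covariates)) {
    data.frame(row.names = seq_along(outcome))
  } else {
    as.data.frame(covariates)
  }
  g <- as.factor(group)
  ok <- stats::complete.cases(outcome, g, cov_df)
  outcome <- outcome[ok]; g <- droplevels(g[ok])
  cov_df <- cov_df[ok, , drop = FALSE]
  if (nlevels(g) != 2)
    stop("`group` must have exactly two levels after listwise deletion",
         call. = FALSE)
  dat <- data.frame(.outcome = outcome, .group = g, cov_df)
  X <- stats::model.matrix(~ ., dat[, -1, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(.outcome ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  grow <- grep("^\\.group", rownames(co))
  tval <- co[grow, "t value"]
  dof2 <- fit$df.residual
  structure(list(test = "ancova", statistic = unname(tval^2),
                 dof = c(1, dof2),
                 p_value = unname(co[grow, "Pr(>|t|)"]),
                 ci_95 = unname(stats::confint(fit)[grow, ]),
                 estimate = unname(co[grow, "Estimate"]),
                 n = length(outcome),
                 covariates = colnames(cov_df),
                 covariate_coefficients = co[-c(1, grow), , drop = FALSE]),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  stat <- if (x$test == "ancova") sprintf("F(%d,%d) = %.3f", x$dof[1],
                                          x$dof[2], x$statistic)
          else sprintf("t(%.1f) = %.3f", x$dof, x$statistic)
  cat(sprintf("%s: %s, p = %.4g\n", x$test, stat, x$p_value))
  invisible(x)
}

#' Assign significance tiers within a test family
#'
#' Tiers: `ns` (p >= 0.1), `trend` (p < 0.1), `significant` (p < 0.05),
#' `bonferroni_significant` (p < 0.05 / m for a family of m tests, e.g.
#' m = 2 for the two cognitive composites, m = 3 for the three pathology
#' markers).
#'
#' @param results list of `association_result`s (or a single one).
#' @param family label recorded on each result.
#' @param m number of tests in the family (>= 1).
#' @return the list with `tier` and `family` filled in.
#' @export
apply_significance_tiers <- function(results, family = "default", m = 1) {
  stopifnot(m >= 1)
  single <- inherits(results, "association_result")
  if (single) results <- list(results)
  results <- lapply(results, function(res) {
    p <- res$p_value
    res$tier <- if (p < 0.05 / m) "bonferroni_significant"
      else if (p < 0.05) "significant"
      else if (p < 0.1) "trend"
      else "ns"
    res$family <- family
    res$bonferroni_m <- m
    res
  })
  if (single) results[[1]] else results
}

#' Flatten association results to a tidy table
#'
#' @param results list of `association_result`s.
#' @return data.frame, one row per association.
#' @export
association_table <- function(results) {
  if (inherits(results, "association_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(x_name = r$x_name, y_name = r$y_name, method = r$method,
               statistic = r$statistic, p_value = r$p_value,
               ci_low = r$ci_95[1], ci_high = r$ci_95[2], n_used = r$n_used,
               covariates = paste(r$covariates, collapse = "+"),
               tier = r$tier, family = r$family %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
}
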