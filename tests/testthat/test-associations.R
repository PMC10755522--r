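test_that("normality screen picks Pearson for normal, Spearman for skewed", {
  set.seed(1)                       # fixture seed screened with shapiro.test
  x <- rnorm(200); y <- rnorm(200)
  m <- select_method(x, y)
  expect_equal(as.character(m), "pearson")
  sw <- attr(m, "shapiro")
  expect_true(all(sw$p >= 0.05))
  set.seed(1)
  x2 <- rnorm(200); y2 <- exp(rnorm(200))
  expect_equal(as.character(select_method(x2, y2)), "spearman")
  expect_error(select_method(rep(1, 50), rnorm(50)), "degenerate")
  expect_error(select_method(rnorm(5), rnorm(5)), "n < 8")
})

test_that("partial correlation has exact degenerate behaviour", {
  set.seed(2)
  x <- rnorm(40)
  r <- partial_correlation(x, x, method = "pearson")
  expect_equal(r$statistic, 1, tolerance = 1e-12)
  z <- rnorm(40)
  # y identical to a covariate: residuals are numerically zero
  expect_error(partial_correlation(x, z, covariates = data.frame(z = z),
                                   method = "pearson"),
               "fully explained")
})

test_that("partial correlations match the normal-equations oracle", {
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 40
    covs <- matrix(rnorm(n * 3), n, 3)
    x <- covs %*% c(1, -0.5, 0.2) + rnorm(n)
    y <- covs %*% c(0.3, 0.4, -1) + 0.5 * x + rnorm(n)
    got <- partial_correlation(as.numeric(x), as.numeric(y), covs,
                               method = "pearson")
    oracle <- oracle_partial_r(as.numeric(x), as.numeric(y), covs)
    expect_equal(got$statistic, oracle$r, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
    expect_equal(got$n_used, n)
    # Spearman variant = Pearson partial on rank-transformed inputs, exactly
    sp <- partial_correlation(as.numeric(x), as.numeric(y), covs,
                              method = "spearman")
    rk <- oracle_partial_r(rank(x), rank(y), covs)
    expect_equal(sp$statistic, rk$r, tolerance = 1e-12)
  }
})

test_that("listwise deletion is accounted for exactly", {
  set.seed(3)
  x <- rnorm(50); y <- rnorm(50); z <- rnorm(50)
  x[c(3, 7)] <- NA; y[10] <- NA; z[c(10, 20)] <- NA
  res <- partial_correlation(x, y, data.frame(z = z), method = "pearson")
  expect_equal(res$n_used, 50 - 4)   # union of missing rows {3, 7, 10, 20}
  expect_equal(res$n_used + res$n_excluded, 50)
})

test_that("paired MAE comparison equals the textbook paired t-test", {
  a <- c(2.1, 3.0, 1.2, 4.5, 2.2, 3.3)
  same <- compare_mae_paired(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(4)
  b <- a + rnorm(6, 0.5, 0.3)
  got <- compare_mae_paired(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 5), tolerance = 1e-12)
  hw <- qt(0.975, 5) * sd(d) / sqrt(6)
  expect_equal(got$ci_95, c(mean(d) - hw, mean(d) + hw), tolerance = 1e-12)
  shift <- compare_mae_paired(a, a + 1)
  expect_equal(shift$estimate, -1, tolerance = 1e-12)
  expect_lt(shift$ci_95[2], 0)
  expect_error(compare_mae_paired(a, a[-1]), "equal-length")
})

test_that("group comparison equals the Welch formulas", {
  set.seed(5)
  a <- rnorm(30, 0, 1); b <- rnorm(45, 5, 2)
  got <- compare_groups_t(a, b)
  se <- sqrt(var(a) / 30 + var(b) / 45)
  tstat <- (mean(a) - mean(b)) / se
  dof <- se^4 / ((var(a) / 30)^2 / 29 + (var(b) / 45)^2 / 44)
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$dof, dof, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(tstat), dof), tolerance = 1e-12)
  expect_lt(got$ci_95[2], 0)       # b sits ~5 above a
  expect_equal(compare_groups_t(a, a)$statistic, 0, tolerance = 1e-12)
  expect_error(compare_groups_t(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("ANCOVA group F matches the explicit nested-model oracle", {
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 30
    g <- rep(c(0, 1), each = n / 2)
    covs <- matrix(rnorm(n * 2), n, 2)
    y <- 1.5 * g + covs %*% c(0.5, -1) + rnorm(n)
    got <- ancova_group_effect(as.numeric(y), g, covs)
    X1 <- cbind(1, g, covs)
    X0 <- cbind(1, covs)
    rss <- function(X) {
      beta <- solve(t(X) %*% X, t(X) %*% y)
      sum((y - X %*% beta)^2)
    }
    Fstat <- (rss(X0) - rss(X1)) / (rss(X1) / (n - ncol(X1)))
    expect_equal(got$statistic, Fstat, tolerance = 1e-8)
    expect_equal(got$dof, c(1, n - 4))
    expect_equal(got$p_value, pf(Fstat, 1, n - 4, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("ANCOVA reports covariate coefficients and rejects collinearity", {
  set.seed(6)
  n <- 60
  g <- rep(c("stable", "decliner"), each = 30)
  covs <- data.frame(sex = rbinom(n, 1, 0.5), edu = rnorm(n, 16, 2))
  y <- 2 * (g == "decliner") + 0.5 * covs$sex + rnorm(n)
  got <- ancova_group_effect(y, g, covs)
  expect_true(all(c("sex", "edu") %in% rownames(got$covariate_coefficients)))
  covs$dup <- covs$sex
  expect_error(ancova_group_effect(y, g, covs), "collinear")
})

test_that("ANCOVA detects a planted group effect with high power", {
  hits <- 0
  for (s in 1:40) {
    set.seed(300 + s)
    n <- 400
    g <- rbinom(n, 1, 0.3)
    covs <- matrix(rnorm(n * 3), n, 3)
    y <- 2 * g + rnorm(n)
    if (ancova_group_effect(y, g, covs)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 38)   # >= 95% power expected at this effect size
})

test_that("significance tiers follow the trend/bonferroni thresholds", {
  mk <- function(p) structure(list(x_name = "x", y_name = "y",
                                   method = "pearson", statistic = 0.1,
                                   p_value = p, ci_95 = c(-1, 1), n_used = 50,
                                   n_excluded = 0, covariates = character(0),
                                   tier = NA), class = "association_result")
  tiers <- vapply(apply_significance_tiers(list(mk(0.2), mk(0.07), mk(0.02),
                                                mk(0.01)),
                                           family = "pathology", m = 3),
                  `[[`, "", "tier")
  expect_identical(tiers, c("ns", "trend", "significant",
                            "bonferroni_significant"))
  # m = 1: 0.02 clears the family threshold directly
  one <- apply_significance_tiers(mk(0.02), family = "single", m = 1)
  expect_identical(one$tier, "bonferroni_significant")
  tab <- association_table(apply_significance_tiers(list(mk(0.2)), "f", 2))
  expect_identical(tab$tier, "ns")
  expect_identical(tab$family, "f")
})
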