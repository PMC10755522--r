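# Shared fixtures: small cohorts and a light learner grid so unit tests run
# in seconds. Acceptance-scale settings live in test-acceptance.R.

fast_bae_config <- function(seed = 1L, ...) {
  bae_config(
    svr_grid = expand.grid(kernel = "linear", cost = c(0.01, 0.1, 1),
                           epsilon = 0.1, stringsAsFactors = FALSE),
    rvr_grid = data.frame(kernel = "linear", stringsAsFactors = FALSE),
    seed = seed, ...)
}

# Grid that can interpolate noiseless data essentially exactly.
exact_bae_config <- function(seed = 1L, ...) {
  bae_config(
    svr_grid = expand.grid(kernel = "linear", cost = c(1, 100),
                           epsilon = 0.01, stringsAsFactors = FALSE),
    rvr_grid = data.frame(kernel = "linear", stringsAsFactors = FALSE),
    seed = seed, ...)
}

noiseless_cohort <- function(n = 100, seed = 1L, n_regions = 90) {
  generate_cohort(cohort_spec(n_subjects = n, n_regions = n_regions,
                              noise_sd = 0, seed = seed))
}

noisy_cohort <- function(n = 150, target_mae = 2.5, seed = 1L, ...) {
  spec0 <- cohort_spec(n_subjects = n, seed = seed, ...)
  generate_cohort(cohort_spec(n_subjects = n, seed = seed,
                              noise_sd = calibrate_noise_sd(spec0, target_mae),
                              ...))
}

# Explicit least-squares residualization via normal equations (independent
# of lm/lm.fit), used as the brute-force oracle throughout.
oracle_residuals <- function(v, Z) {
  beta <- solve(t(Z) %*% Z, t(Z) %*% v)
  as.numeric(v - Z %*% beta)
}

oracle_partial_r <- function(x, y, cov_mat) {
  Z <- cbind(1, cov_mat)
  rx <- oracle_residuals(x, Z)
  ry <- oracle_residuals(y, Z)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x); k <- ncol(cov_mat)
  tstat <- r * sqrt((n - k - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - k - 2)
  list(r = r, p = p)
}
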