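#' Specify a synthetic cohort
#'
#' Builds the parameter object for [generate_cohort()]. The generator
#' emulates the statistical structure a brain-age analysis assumes: regional
#' features decline linearly with age (region-specific slopes), a latent
#' brain-age-gap (BAG) offset shifts each subject's apparent brain age on
#' the age axis, cognitive composites and pathology markers are coupled to
#' the latent BAG, and a binary 2-year progression label follows a logistic
#' model in the latent BAG.
#'
#' Default regional baselines and slopes depend on the modality tag: the
#' `"MRI"` profile mimics regional gray-matter volumes in arbitrary units
#' (baselines 50..150, decline 0.2--1.2 units/y), the `"FDG"` profile mimics
#' SUVR-scale values (baselines 0.9..1.5, decline 0.001--0.006 per year).
#' Both are affine in `age + bag`, which makes the latent BAG a well-defined
#' ground truth: the brain simply "looks" `bag` years older.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param age_range numeric length-2, years; ages are uniform on this range.
#' @param n_regions number of atlas regions (default 90).
#' @param baseline_per_region,aging_slope_per_region numeric vectors of
#'   length `n_regions` (or scalars, recycled); slopes are feature-units per
#'   year, negative = decline.
#' @param noise_sd feature-units; iid Gaussian measurement noise.
#' @param modality_tag `"MRI"` or `"FDG"`.
#' @param group diagnosis label: `"CN"`, `"SCD"` or `"MCI"`.
#' @param bag_shift_mean,bag_shift_sd years; the latent accelerated-aging
#'   offset of the group is `N(bag_shift_mean, bag_shift_sd^2)`.
#' @param cognition_coupling slope (score units per BAG year) with which the
#'   memory composite *decreases* per latent BAG year; the executive
#'   composite uses 0.8 of it.
#' @param pathology_coupling scalar multiplier on the canonical per-marker
#'   slopes (amyloid PET +0.02 SUVR/y, CSF A-beta-42 -15 pg/mL/y,
#'   p-tau/A-beta ratio +0.015/y of latent BAG).
#' @param cognition_noise_sd,pathology_noise_scale residual noise of the
#'   coupled measures (composite SD units; multiplier on canonical marker
#'   SDs 0.15 SUVR / 180 pg/mL / 0.04).
#' @param progression_base_rate probability of decline at latent BAG 0.
#' @param progression_logodds_per_bag_year log-odds increase per BAG year.
#' @param covariate_confounding optional list with any of `sex`,
#'   `education`, `apoe4`: per-region slopes (scalar or length `n_regions`)
#'   of features on the covariate. Defaults to no confounding.
#' @param missing_rate_per_measure MCAR missingness applied to cognition and
#'   pathology measures only, never to age/sex/education/APOE.
#' @param seed integer; fully determines the generated cohort.
#' @return object of class `cohort_spec`.
#' @seealso [generate_cohort()], [calibrate_noise_sd()]
#' @export
cohort_spec <- function(n_subjects,
                        age_range = c(60, 90),
                        n_regions = 90,
                        baseline_per_region = NULL,
                        aging_slope_per_region = NULL,
                        noise_sd = 0,
                        modality_tag = c("MRI", "FDG"),
                        group = c("CN", "SCD", "MCI"),
                        bag_shift_mean = 0,
                        bag_shift_sd = 0,
                        cognition_coupling = 0,
                        pathology_coupling = 0,
                        cognition_noise_sd = 1,
                        pathology_noise_scale = 1,
                        progression_base_rate = 0.25,
                        progression_logodds_per_bag_year = 0,
                        covariate_confounding = NULL,
                        missing_rate_per_measure = 0,
                        seed = 1L) {
  modality_tag <- match.arg(modality_tag)
  group <- match.arg(group)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1 ||
      n_subjects != round(n_subjects))
    stop_field("n_subjects", "must be a positive integer")
  if (!is.numeric(age_range) || length(age_range) != 2 ||
      !all(is.finite(age_range)) || age_range[1] >= age_range[2])
    stop_field("age_range", "must be (low, high) with low < high")
  if (age_range[1] < 60)
    stop_field("age_range", "cohorts are restricted to ages 60 and over")
  if (!is.numeric(n_regions) || n_regions < 1)
    stop_field("n_regions", "must be a positive count")
  n_regions <- as.integer(n_regions)
  if (is.null(baseline_per_region))
    baseline_per_region <- switch(modality_tag,
      MRI = seq(50, 150, length.out = n_regions),
      FDG = seq(0.9, 1.5, length.out = n_regions))
  if (is.null(aging_slope_per_region))
    aging_slope_per_region <- switch(modality_tag,
      MRI = seq(-1.2, -0.2, length.out = n_regions),
      FDG = seq(-0.006, -0.001, length.out = n_regions))
  baseline_per_region <- rep_len(baseline_per_region, n_regions)
  aging_slope_per_region <- rep_len(aging_slope_per_region, n_regions)
  check_finite(baseline_per_region, "baseline_per_region")
  check_finite(aging_slope_per_region, "aging_slope_per_region")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || !is.finite(noise_sd) ||
      noise_sd < 0)
    stop_field("noise_sd", "must be a non-negative number")
  check_finite(bag_shift_mean, "bag_shift_mean")
  if (bag_shift_sd < 0) stop_field("bag_shift_sd", "must be >= 0")
  check_finite(cognition_coupling, "cognition_coupling")
  check_finite(pathology_coupling, "pathology_coupling")
  check_scalar_prob(progression_base_rate, "progression_base_rate")
  if (progression_base_rate %in% c(0, 1))
    stop_field("progression_base_rate", "must be strictly inside (0, 1)")
  check_finite(progression_logodds_per_bag_year,
               "progression_logodds_per_bag_year")
  check_scalar_prob(missing_rate_per_measure, "missing_rate_per_measure")
  conf <- list(sex = 0, education = 0, apoe4 = 0)
  if (!is.null(covariate_confounding)) {
    if (!is.list(covariate_confounding) ||
        length(setdiff(names(covariate_confounding), names(conf))))
      stop_field("covariate_confounding",
                 "must be a named list with elements among sex/education/apoe4")
    conf[names(covariate_confounding)] <- covariate_confounding
  }
  conf <- lapply(conf, function(s) {
    check_finite(s, "covariate_confounding")
    rep_len(s, n_regions)
  })
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop_field("seed", "must be a single integer")
  spec <- list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    n_regions = n_regions, baseline_per_region = baseline_per_region,
    aging_slope_per_region = aging_slope_per_region, noise_sd = noise_sd,
    modality_tag = modality_tag, group = group,
    bag_shift_mean = bag_shift_mean, bag_shift_sd = bag_shift_sd,
    cognition_coupling = cognition_coupling,
    pathology_coupling = pathology_coupling,
    cognition_noise_sd = cognition_noise_sd,
    pathology_noise_scale = pathology_noise_scale,
    progression_base_rate = progression_base_rate,
    progression_logodds_per_bag_year = progression_logodds_per_bag_year,
    covariate_confounding = conf,
    missing_rate_per_measure = missing_rate_per_measure,
    seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Canonical scales of the pathology markers: baseline value, slope per latent
# BAG year at pathology_coupling = 1 (signs follow the expected direction of
# AD pathology: amyloid PET up, CSF A-beta-42 down, p-tau ratio up), and
# residual SD at pathology_noise_scale = 1.
pathology_scales <- data.frame(
  measure = c("amyloid_pet_suvr", "csf_abeta42", "ptau_abeta_ratio"),
  baseline = c(1.10, 950, 0.08),
  unit_slope = c(0.02, -15, 0.015),
  noise_sd = c(0.15, 180, 0.04))

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()]. Feature row i is
#' `baseline + slope * (age_i + bag_i) + confounding * covariates_i + noise`;
#' the memory composite is `-cognition_coupling * bag_i + noise` (executive:
#' 0.8 of the coupling); pathology markers are affine in `bag_i` on their
#' canonical scales; the 2-year progression label is Bernoulli with
#' `logit(p_i) = logit(base_rate) + logodds_per_bag_year * bag_i`.
#' MCAR missingness is applied last and only to cognition/pathology
#' measures. The spec seed fully determines the output.
#'
#' @param spec a `cohort_spec`.
#' @return object of class `cohort`: list with `phenotype` (data.frame),
#'   `features` (matrix, `region_<id>` columns), `modality_tag`, `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 20, seed = 7))
#' dim(co$features)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must come from cohort_spec()", call. = FALSE)
  n <- spec$n_subjects
  p <- spec$n_regions
  local_seed(spec$seed, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    sex <- stats::rbinom(n, 1, 0.53)              # 1 = female
    education <- pmin(22, pmax(8, round(stats::rnorm(n, 16, 2.5))))
    apoe4 <- stats::rbinom(n, 1, 0.29)
    bag <- stats::rnorm(n, spec$bag_shift_mean, spec$bag_shift_sd)
    conf <- spec$covariate_confounding
    feat <- outer(rep(1, n), spec$baseline_per_region) +
      outer(age + bag, spec$aging_slope_per_region) +
      outer(sex, conf$sex) + outer(education, conf$education) +
      outer(apoe4, conf$apoe4)
    if (spec$noise_sd > 0)
      feat <- feat + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    memory <- -spec$cognition_coupling * bag +
      stats::rnorm(n, 0, spec$cognition_noise_sd)
    executive <- -0.8 * spec$cognition_coupling * bag +
      stats::rnorm(n, 0, spec$cognition_noise_sd)
    path <- lapply(seq_len(nrow(pathology_scales)), function(i) {
      s <- pathology_scales[i, ]
      s$baseline + spec$pathology_coupling * s$unit_slope * bag +
        stats::rnorm(n, 0, s$noise_sd * spec$pathology_noise_scale)
    })
    names(path) <- pathology_scales$measure
    eta <- stats::qlogis(spec$progression_base_rate) +
      spec$progression_logodds_per_bag_year * bag
    decliner <- stats::rbinom(n, 1, stats::plogis(eta))
    phen <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      chronological_age = age,
      sex = ifelse(sex == 1, "female", "male"),
      education = as.numeric(education),
      apoe4_carrier = apoe4,
      diagnosis_group = spec$group,
      progression_status = ifelse(decliner == 1, "decliner", "stable"),
      memory_composite = memory,
      executive_composite = executive,
      amyloid_pet_suvr = path$amyloid_pet_suvr,
      csf_abeta42 = path$csf_abeta42,
      ptau_abeta_ratio = path$ptau_abeta_ratio,
      latent_bag_true = bag,
      stringsAsFactors = FALSE)
    if (spec$missing_rate_per_measure > 0) {
      for (cn in c("memory_composite", "executive_composite",
                   pathology_scales$measure)) {
        drop <- stats::runif(n) < spec$missing_rate_per_measure
        phen[[cn]][drop] <- NA_real_
      }
    }
    colnames(feat) <- sprintf("region_%d", seq_len(p))
    rownames(feat) <- phen$subject_id
    structure(list(phenotype = phen, features = feat,
                   modality_tag = spec$modality_tag, spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d regions, modality %s, group %s\n",
              nrow(x$phenotype), ncol(x$features), x$modality_tag,
              x$phenotype$diagnosis_group[1]))
  invisible(x)
}

subset_cohort <- function(cohort, idx) {
  structure(list(phenotype = cohort$phenotype[idx, , drop = FALSE],
                 features = cohort$features[idx, , drop = FALSE],
                 modality_tag = cohort$modality_tag, spec = cohort$spec),
            class = "cohort")
}

#' Partition a cohort into disjoint sub-cohorts
#'
#' @param cohort a `cohort`.
#' @param fractions probabilities summing to 1 (within 1e-9); sub-cohort
#'   sizes are the rounded shares, with remainders assigned to the earliest
#'   parts.
#' @param seed integer; the shuffled assignment is seed-deterministic.
#' @return list of `cohort` objects forming a disjoint partition of the input.
#' @export
split_cohort <- function(cohort, fractions, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must sum to 1", call. = FALSE)
  n <- nrow(cohort$phenotype)
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  if (any(sizes == 0))
    stop("split produces an empty cohort; use fewer or larger fractions",
         call. = FALSE)
  ord <- local_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_along(sizes), function(k) {
    subset_cohort(cohort, sort(ord[starts[k]:ends[k]]))
  })
}

#' Write / read a cohort as CSV files
#'
#' A cohort round-trips as `features.csv` (subject_id + region columns) and
#' `phenotype.csv` (all remaining per-subject fields) in a directory.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   `cohort` (without the generating spec).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat <- data.frame(subject_id = cohort$phenotype$subject_id,
                     cohort$features, check.names = FALSE)
  utils::write.csv(feat, file.path(dir, "features.csv"), row.names = FALSE)
  phen <- cohort$phenotype
  phen$modality_tag <- cohort$modality_tag
  utils::write.csv(phen, file.path(dir, "phenotype.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  feat <- utils::read.csv(file.path(dir, "features.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  phen <- utils::read.csv(file.path(dir, "phenotype.csv"),
                          stringsAsFactors = FALSE)
  modality <- phen$modality_tag[1] %||% "MRI"
  phen$modality_tag <- NULL
  m <- as.matrix(feat[, setdiff(names(feat), "subject_id"), drop = FALSE])
  rownames(m) <- feat$subject_id
  structure(list(phenotype = phen, features = m, modality_tag = modality,
                 spec = NULL),
            class = "cohort")
}

#' Analytic error predictions for a synthetic cohort
#'
#' For the generator's affine feature model, the best possible age estimate
#' given one subject's features has posterior variance
#' `1 / (1/v_age + S/sigma^2)` where `S` is the sum of squared regional
#' slopes, `sigma` the feature noise SD and `v_age` the age prior variance
#' (uniform on the spec range). `predicted_mae_floor()` converts that
#' Gaussian error SD into an expected absolute error; `predicted_mae()`
#' additionally inflates the variance by `(1 + p / n_train)` to account for
#' estimating `p` regional weights from `n_train` training subjects, the
#' standard excess-risk factor of a fitted linear read-out.
#' `calibrate_noise_sd()` inverts the floor: it returns the feature noise SD
#' at which the floor equals `target_mae`.
#'
#' @param spec a `cohort_spec`.
#' @param n_train training-set size available to the learner.
#' @param target_mae years.
#' @return years (or a noise SD in feature units for the calibration).
#' @export
predicted_mae_floor <- function(spec) {
  sqrt(2 / pi) * sqrt(posterior_age_var(spec))
}

#' @rdname predicted_mae_floor
#' @export
predicted_mae <- function(spec, n_train) {
  stopifnot(n_train > 0)
  sqrt(2 / pi) *
    sqrt(posterior_age_var(spec) * (1 + spec$n_regions / n_train))
}

#' @rdname predicted_mae_floor
#' @export
calibrate_noise_sd <- function(spec, target_mae) {
  stopifnot(target_mae > 0)
  v_age <- diff(spec$age_range)^2 / 12
  v_t <- (target_mae / sqrt(2 / pi))^2
  if (v_t >= v_age)
    stop("target MAE is not below the age-prior error; nothing to calibrate",
         call. = FALSE)
  S <- sum(spec$aging_slope_per_region^2)
  sqrt(S / (1 / v_t - 1 / v_age))
}

posterior_age_var <- function(spec) {
  v_age <- diff(spec$age_range)^2 / 12
  if (spec$noise_sd == 0) return(0)
  S <- sum(spec$aging_slope_per_region^2)
  1 / (1 / v_age + S / spec$noise_sd^2)
}

#' Expected decliner prevalence under a cohort spec
#'
#' Integrates the logistic progression model over the latent BAG
#' distribution `N(bag_shift_mean, bag_shift_sd^2)` by Gauss-Legendre-free
#' numerical quadrature ([stats::integrate()]).
#' @param spec a `cohort_spec`.
#' @return expected fraction of decliners.
#' @export
expected_decliner_rate <- function(spec) {
  b0 <- stats::qlogis(spec$progression_base_rate)
  b1 <- spec$progression_logodds_per_bag_year
  if (spec$bag_shift_sd == 0)
    return(stats::plogis(b0 + b1 * spec$bag_shift_mean))
  stats::integrate(function(z) {
    stats::plogis(b0 + b1 * z) *
      stats::dnorm(z, spec$bag_shift_mean, spec$bag_shift_sd)
  }, -Inf, Inf)$value
}
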