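# Seeded synthetic cohorts with the covariate, survival and financial-toxicity
# structure the downstream analyses assume: a right-skewed log-normal SIRI,
# categorical performance-status / smoking structure, proportional-hazards
# survival times with *threshold* (step) covariate effects at plantable
# cutoffs, censoring as the minimum of an exponential dropout time and an
# administrative horizon, and ordinal financial-toxicity labels with a
# monotone location shift on log2(SIRI).

#' Log-normal parameters for a SIRI distribution from printed quantiles
#'
#' Fits the two log-normal parameters to a published median and interquartile
#' range by quantile matching: `meanlog = log(median)` and
#' `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#'
#' @param median median SIRI (default 1.34, a typical head-and-neck cohort).
#' @param iqr length-2 vector of the 25th and 75th percentiles
#'   (default `c(0.88, 2.19)`).
#' @return list with `meanlog` and `sdlog`.
#' @export
siri_lognormal_params <- function(median = 1.34, iqr = c(0.88, 2.19)) {
  check_positive_scalar(median, "median")
  stopifnot(length(iqr) == 2L, all(iqr > 0), iqr[1] < iqr[2])
  list(meanlog = log(median),
       sdlog = log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75)))
}

#' Configuration of a synthetic cohort's covariate distribution
#'
#' Marginals default to a head-and-neck radiotherapy cohort: log-normal SIRI
#' with median 1.34 and IQR (0.88, 2.19); Karnofsky performance status
#' 100 / 80-90 / <=70 with probabilities 0.27 / 0.64 / 0.09; smoking
#' never / former / current 0.31 / 0.54 / 0.15; BMI ~ Normal(27.5, 5.5)
#' truncated below at 14 kg/m^2; age ~ Normal(61, 9.5) truncated to 18-95.
#'
#' @param n_subjects number of subjects (positive integer).
#' @param siri_log_median location of log(SIRI).
#' @param siri_log_sd scale of log(SIRI); default from [siri_lognormal_params()].
#' @param kps_probs probability vector over KPS categories 100, 80-90, <=70.
#' @param smoking_probs probability vector over never, former, current.
#' @param bmi_mean,bmi_sd BMI normal parameters (kg/m^2).
#' @param age_mean,age_sd age normal parameters (years).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          siri_log_median = siri_lognormal_params()$meanlog,
                          siri_log_sd = siri_lognormal_params()$sdlog,
                          kps_probs = c("100" = 0.27, "80-90" = 0.64, "<=70" = 0.09),
                          smoking_probs = c(never = 0.31, former = 0.54, current = 0.15),
                          bmi_mean = 27.5, bmi_sd = 5.5,
                          age_mean = 61, age_sd = 9.5,
                          seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 1 || n_subjects != round(n_subjects))
    stop("invalid config: n_subjects must be a positive integer", call. = FALSE)
  stopifnot(is.numeric(siri_log_median), is.finite(siri_log_median))
  check_positive_scalar(siri_log_sd, "siri_log_sd")
  check_prob_vector(kps_probs, "kps_probs")
  check_prob_vector(smoking_probs, "smoking_probs")
  if (length(kps_probs) != 3L) stop("invalid config: kps_probs needs 3 categories", call. = FALSE)
  if (length(smoking_probs) != 3L) stop("invalid config: smoking_probs needs 3 categories", call. = FALSE)
  check_positive_scalar(bmi_mean, "bmi_mean"); check_positive_scalar(bmi_sd, "bmi_sd")
  check_positive_scalar(age_mean, "age_mean"); check_positive_scalar(age_sd, "age_sd")
  structure(list(n_subjects = as.integer(n_subjects),
                 siri_log_median = siri_log_median, siri_log_sd = siri_log_sd,
                 kps_probs = kps_probs, smoking_probs = smoking_probs,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Hazard specification with planted threshold effects
#'
#' Event times are exponential with subject-level rate
#' `baseline_rate * exp(sum of active log-hazard increments)`; an increment is
#' active when the subject's value crosses the planted cutoff. Observed time
#' is the minimum of the event time, an exponential random-censoring time and
#' the administrative horizon.
#'
#' @param baseline_rate events per month (> 0).
#' @param threshold_effects list of effects, each a list with `variable`,
#'   `cutoff` (numeric threshold, or a character vector of category levels),
#'   `direction` (`">="`, `"<"` or `"in"`) and `loghr` (log-hazard increment).
#' @param censor_horizon administrative censoring time, months (> 0).
#' @param random_censor_rate exponential dropout rate per month (>= 0).
#' @return an object of class `hazard_spec`.
#' @export
hazard_spec <- function(baseline_rate, threshold_effects = list(),
                        censor_horizon = 60, random_censor_rate = 0) {
  check_positive_scalar(baseline_rate, "baseline_rate", strict = FALSE)
  check_positive_scalar(censor_horizon, "censor_horizon")
  check_positive_scalar(random_censor_rate, "random_censor_rate", strict = FALSE)
  for (eff in threshold_effects) {
    if (is.null(eff$variable) || is.null(eff$cutoff) || is.null(eff$loghr))
      stop("each threshold effect needs variable, cutoff and loghr", call. = FALSE)
  }
  structure(list(baseline_rate = baseline_rate,
                 threshold_effects = threshold_effects,
                 censor_horizon = censor_horizon,
                 random_censor_rate = random_censor_rate),
            class = "hazard_spec")
}

#' Ordinal financial-toxicity label specification
#'
#' @param ft_probs probability vector over FT levels 0-3.
#' @param shift_per_level additive shift of the log2(SIRI) location per FT
#'   level; a positive shift makes expected log2(SIRI) increase monotonically
#'   with FT.
#' @return an object of class `ft_spec`.
#' @export
ft_spec <- function(ft_probs = c(0.45, 0.25, 0.18, 0.12), shift_per_level = 0) {
  check_prob_vector(ft_probs, "ft_probs")
  if (length(ft_probs) != 4L) stop("invalid config: ft_probs needs 4 levels (0-3)", call. = FALSE)
  stopifnot(is.numeric(shift_per_level), length(shift_per_level) == 1L,
            is.finite(shift_per_level))
  structure(list(ft_probs = ft_probs, shift_per_level = shift_per_level),
            class = "ft_spec")
}

#' Draw the covariate table of a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `id`, `siri`, `kps_cat`, `bmi`, `smoking`,
#'   `age`. Fully reproducible given `config$seed`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  siri <- stats::rlnorm(n, config$siri_log_median, config$siri_log_sd)
  kps_cat <- factor(sample(names(config$kps_probs), n, TRUE, config$kps_probs),
                    levels = names(config$kps_probs))
  smoking <- factor(sample(names(config$smoking_probs), n, TRUE, config$smoking_probs),
                    levels = names(config$smoking_probs))
  # truncated-normal draws via the probability-integral transform keep one
  # uniform per subject, so truncation bounds do not change the draw count
  bmi <- stats::qnorm(stats::runif(n, stats::pnorm(14, config$bmi_mean, config$bmi_sd), 1),
                      config$bmi_mean, config$bmi_sd)
  p_lo <- stats::pnorm(18, config$age_mean, config$age_sd)
  p_hi <- stats::pnorm(95, config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, p_lo, p_hi), config$age_mean, config$age_sd)
  data.frame(id = seq_len(n), siri = siri, kps_cat = kps_cat,
             bmi = bmi, smoking = smoking, age = age)
}

effect_active <- function(covariates, eff) {
  if (!eff$variable %in% names(covariates))
    stop(sprintf("threshold effect references unknown variable '%s'", eff$variable),
         call. = FALSE)
  x <- covariates[[eff$variable]]
  dir <- eff$direction %||% ">="
  switch(dir,
         ">=" = as.numeric(x) >= eff$cutoff,
         "<"  = as.numeric(x) < eff$cutoff,
         "in" = as.character(x) %in% eff$cutoff,
         stop(sprintf("unknown effect direction '%s'", dir), call. = FALSE))
}

#' Attach proportional-hazards survival outcomes to a covariate table
#'
#' @param covariates data.frame from [generate_covariates()] (any data.frame
#'   containing the variables named by the hazard spec works).
#' @param spec a [hazard_spec()].
#' @param seed integer RNG seed (independent of the covariate seed).
#' @return the covariate table with `time_months` (> 0) and `event` (0/1)
#'   appended; events + censored = n by construction.
#' @export
assign_survival <- function(covariates, spec, seed) {
  stopifnot(inherits(spec, "hazard_spec"), is.data.frame(covariates))
  n <- nrow(covariates)
  loghr <- rep(0, n)
  for (eff in spec$threshold_effects)
    loghr <- loghr + eff$loghr * effect_active(covariates, eff)
  rate <- spec$baseline_rate * exp(loghr)
  set.seed(seed)
  t_event <- stats::rexp(n) / rate # Inf when rate == 0
  t_cens <- if (spec$random_censor_rate > 0)
    stats::rexp(n) / spec$random_censor_rate else rep(Inf, n)
  t_cens <- pmin(t_cens, spec$censor_horizon)
  out <- covariates
  out$time_months <- pmin(t_event, t_cens)
  out$event <- as.integer(t_event <= t_cens)
  out
}

#' Sample ordinal financial-toxicity labels with a monotone SIRI shift
#'
#' FT levels 0-3 are sampled independently from `spec$ft_probs`; SIRI is then
#' re-located multiplicatively by `2^(shift_per_level * level)`, so the
#' expected log2(SIRI) is a linear (monotone when the shift is positive)
#' function of the FT level.
#'
#' @param cohort data.frame with a `siri` column.
#' @param spec an [ft_spec()].
#' @param seed integer RNG seed.
#' @return the cohort with `ft_level` appended and `siri` shifted.
#' @export
generate_ft_labels <- function(cohort, spec, seed) {
  stopifnot(inherits(spec, "ft_spec"), is.data.frame(cohort))
  if (is.null(cohort$siri)) stop("cohort must contain a siri column", call. = FALSE)
  set.seed(seed)
  level <- sample(0:3, nrow(cohort), TRUE, spec$ft_probs)
  cohort$ft_level <- level
  cohort$siri <- cohort$siri * 2^(spec$shift_per_level * level)
  cohort
}

#' Simulate a complete cohort (covariates, survival, optional FT labels)
#'
#' Each stage draws from its own substream of the master seed
#' (see [substream_seed()]), so e.g. regenerating FT labels leaves the
#' survival draws untouched.
#'
#' @param config a [cohort_config()]; its `seed` is the master seed.
#' @param hazard a [hazard_spec()].
#' @param ft optional [ft_spec()].
#' @return a cohort data.frame.
#' @export
simulate_cohort <- function(config, hazard, ft = NULL) {
  cov_config <- config
  cov_config$seed <- substream_seed(config$seed, "covariates")
  cov <- generate_covariates(cov_config)
  cohort <- assign_survival(cov, hazard, substream_seed(config$seed, "survival"))
  if (!is.null(ft))
    cohort <- generate_ft_labels(cohort, ft, substream_seed(config$seed, "ft"))
  cohort
}

cohort_columns <- c("id", "siri", "kps_cat", "bmi", "smoking", "age",
                    "time_months", "event", "ft_level")

#' Write / read a cohort as CSV with the standard column schema
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort with categorical columns restored
#'   as factors.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(x$kps_cat))
    x$kps_cat <- factor(x$kps_cat, levels = c("100", "80-90", "<=70"))
  if (!is.null(x$smoking))
    x$smoking <- factor(x$smoking, levels = c("never", "former", "current"))
  x
}
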