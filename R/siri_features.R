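# SIRI and the categorical codings used downstream.

#' Systemic inflammatory response index (SIRI)
#'
#' SIRI = (absolute neutrophil count x absolute monocyte count) /
#' absolute lymphocyte count, from a pre-treatment complete blood count.
#' All counts are absolute (10^9/L); the ratio is invariant to a common
#' rescaling of neutrophils and lymphocytes. The base-2 logarithm is
#' returned alongside because associations with ordinal financial-toxicity
#' levels are modelled on the log2 scale.
#'
#' @param neutrophils,monocytes,lymphocytes absolute counts (10^9/L);
#'   vectors of equal length, all values finite and > 0.
#' @return data.frame with columns `siri` and `log2_siri`.
#' @examples
#' compute_siri(2, 1, 2) # siri 1, log2 0
#' @export
compute_siri <- function(neutrophils, monocytes, lymphocytes) {
  for (nm in c("neutrophils", "monocytes", "lymphocytes")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("%s must be finite and > 0", nm), call. = FALSE)
  }
  siri <- neutrophils * monocytes / lymphocytes
  data.frame(siri = siri, log2_siri = log2(siri))
}

#' Standard BMI strata
#'
#' Underweight (< 18.5), normal (18.5-24.9), overweight (25-29.9),
#' obese (>= 30); boundary values belong to the higher category.
#'
#' @param bmi numeric vector, kg/m^2, finite and > 0.
#' @return factor with levels underweight, normal, overweight, obese.
#' @export
categorize_bmi <- function(bmi) {
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0))
    stop("bmi must be finite and > 0", call. = FALSE)
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Dichotomize an ordinal financial-toxicity response
#'
#' Levels 0-1 -> FT-Low, 2-3 -> FT-High (4-point Likert responses to the
#' EORTC QLQ-C30 financial-difficulties item).
#'
#' @param level integer vector with values in 0-3.
#' @return factor with levels `FT-Low`, `FT-High`.
#' @export
categorize_ft <- function(level) {
  if (!all(level %in% 0:3))
    stop("ft level must be in 0-3", call. = FALSE)
  factor(ifelse(level <= 1, "FT-Low", "FT-High"), levels = c("FT-Low", "FT-High"))
}

#' Ensure a cohort has a SIRI column
#'
#' Accepts either a precomputed `siri` column (the external-validation
#' workflow starts from SIRI) or the three CBC columns `neutrophils`,
#' `monocytes`, `lymphocytes`, from which SIRI is computed.
#'
#' @param cohort data.frame.
#' @return the cohort with `siri` and `log2_siri` columns.
#' @export
add_siri <- function(cohort) {
  if (is.null(cohort$siri)) {
    needed <- c("neutrophils", "monocytes", "lymphocytes")
    if (!all(needed %in% names(cohort)))
      stop("cohort needs either a siri column or neutrophils/monocytes/lymphocytes",
           call. = FALSE)
    s <- compute_siri(cohort$neutrophils, cohort$monocytes, cohort$lymphocytes)
    cohort$siri <- s$siri
  }
  cohort$log2_siri <- log2(cohort$siri)
  cohort
}
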