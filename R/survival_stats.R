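# Validation statistics: Kaplan-Meier curves, k-group log-rank test,
# univariable Cox fits (Efron ties), Holm-Bonferroni multiplicity control.

#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative follow-up times.
#' @param events event indicators (0/1).
#' @return a `survival_curve`: data.frame with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (starting at 1, non-increasing).
#' @export
kaplan_meier <- function(times, events) {
  check_surv_vectors(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       survival = fit$surv),
            class = c("survival_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a [kaplan_meier()] result.
#' @param t times at which to evaluate (right-continuous step convention).
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' k-group log-rank test
#'
#' Chi-square statistic on k-1 degrees of freedom with hypergeometric
#' variance and standard tie handling.
#'
#' @param times,events survival outcome.
#' @param groups group labels (>= 2 non-empty groups).
#' @return a `test_result` list: `statistic`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_vectors(times, events)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  structure(list(statistic = unname(fit$chisq), df = df,
                 p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
                 method = "log-rank"),
            class = "test_result")
}

#' Univariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie correction; the hazard
#' ratio, its Wald 95% confidence interval from the observed information,
#' and the two-sided Wald p-value are reported. `x` must be numeric or a
#' two-level factor (k-level comparisons are run as separate two-group
#' fits feeding [holm_bonferroni()]).
#'
#' @param times,events survival outcome.
#' @param x a single non-constant covariate.
#' @param conf_level confidence level (default 0.95).
#' @return an `effect_estimate` list: `hr`, `ci_lower`, `ci_upper`, `beta`,
#'   `se`, `p_value`, `n`, `n_event`, `converged`.
#' @export
cox_univariable <- function(times, events, x, conf_level = 0.95) {
  check_surv_vectors(times, events)
  if (is.character(x)) x <- factor(x)
  if (length(unique(x)) < 2)
    stop("covariate is constant; Cox fit undefined", call. = FALSE)
  if (is.factor(x) && nlevels(droplevels(x)) != 2)
    stop("factor covariate must have exactly 2 levels (fit pairwise instead)",
         call. = FALSE)
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (monotone || !is.finite(beta) || abs(beta) > 15)
    stop("monotone partial likelihood: Cox estimate did not converge",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(hr = exp(beta), ci_lower = exp(beta - z * se),
                 ci_upper = exp(beta + z * se), beta = beta, se = se,
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 n = fit$n, n_event = fit$nevent, converged = TRUE),
            class = "effect_estimate")
}

#' Holm-Bonferroni step-down correction
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param alpha family-wise error level (default 0.05).
#' @param labels optional comparison labels.
#' @return data.frame with `label`, `p`, `p_adjusted` (monotone in the
#'   sorted order), and `reject` (adjusted p <= alpha).
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05, labels = NULL) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "holm")
  data.frame(label = labels %||% paste0("H", seq_along(p_values)),
             p = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Pairwise two-group survival comparisons with Holm correction
#'
#' Runs all pairwise two-group log-rank tests and univariable Cox fits
#' between group levels and applies Holm-Bonferroni to the log-rank
#' p-values.
#'
#' @param times,events survival outcome.
#' @param groups group labels.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with one row per pair: `comparison`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `p_adjusted`, `reject`.
#' @export
pairwise_survival_comparisons <- function(times, events, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  lv <- levels(groups)
  if (length(lv) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- groups %in% pr
    g <- droplevels(groups[sel])
    lr <- logrank_test(times[sel], events[sel], g)
    cx <- tryCatch(cox_univariable(times[sel], events[sel], g),
                   error = function(e) NULL)
    data.frame(comparison = paste(pr[2], "vs", pr[1]),
               hr = cx$hr %||% NA_real_,
               ci_lower = cx$ci_lower %||% NA_real_,
               ci_upper = cx$ci_upper %||% NA_real_,
               p = lr$p_value)
  })
  out <- do.call(rbind, rows)
  hb <- holm_bonferroni(out$p, alpha = alpha, labels = out$comparison)
  out$p_adjusted <- hb$p_adjusted
  out$reject <- hb$reject
  out
}
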