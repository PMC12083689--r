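# Ordered-trend testing (Jonckheere-Terpstra) and multiple linear
# regression of log2(SIRI) on financial-toxicity group plus confounders.

jt_statistic <- function(values, group_idx, k) {
  J <- 0
  for (i in 1:(k - 1)) {
    vi <- values[group_idx == i]
    if (!length(vi)) next
    for (j in (i + 1):k) {
      vj <- values[group_idx == j]
      if (!length(vj)) next
      J <- J + sum(outer(vi, vj, "<")) + 0.5 * sum(outer(vi, vj, "=="))
    }
  }
  J
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' The statistic J sums, over all ordered group pairs (i < j), the number of
#' cross-group value pairs in increasing order (ties count 1/2); with two
#' groups it reduces to the Mann-Whitney U statistic. The p-value uses the
#' tie-corrected normal approximation of J by default, or a label-permutation
#' reference.
#'
#' @param values numeric responses.
#' @param groups ordered group labels (ordered factor, or coercible with the
#'   natural sort order of its unique values).
#' @param alternative `"increasing"` (default), `"decreasing"` or
#'   `"two.sided"` trend in location with group order.
#' @param method `"normal"` (tie-corrected approximation) or
#'   `"permutation"`.
#' @param n_perm permutation replicates (default 10000).
#' @param seed RNG seed for the permutation reference.
#' @return a `test_result` list: `statistic` (J), `mean`, `sd`, `z`,
#'   `p_value`, `method`.
#' @export
jonckheere_test <- function(values, groups,
                            alternative = c("increasing", "decreasing", "two.sided"),
                            method = c("normal", "permutation"),
                            n_perm = 10000, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(values) == length(groups))
  g <- if (is.ordered(groups)) droplevels(groups) else
    factor(groups, levels = sort(unique(groups)))
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2) stop("Jonckheere test needs at least 2 non-empty ordered groups",
                  call. = FALSE)
  gi <- as.integer(g)
  J <- jt_statistic(values, gi, k)
  ni <- tabulate(gi, k)
  N <- sum(ni)
  mu <- (N^2 - sum(ni^2)) / 4
  tj <- as.numeric(table(values)) # tie-group sizes
  f <- function(x, a, b, c) sum(x * (x - a) * (b * x + c))
  v1 <- (N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
           sum(tj * (tj - 1) * (2 * tj + 5))) / 72
  v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
  sigma <- sqrt(v1 + v2 + v3)
  z <- (J - mu) / sigma
  if (method == "normal") {
    p <- switch(alternative,
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    p <- min(p, 1)
  } else {
    set.seed(seed)
    Jp <- replicate(n_perm, jt_statistic(values, sample(gi), k))
    p <- switch(alternative,
                increasing = (1 + sum(Jp >= J)) / (n_perm + 1),
                decreasing = (1 + sum(Jp <= J)) / (n_perm + 1),
                two.sided = (1 + sum(abs(Jp - mu) >= abs(J - mu))) / (n_perm + 1))
  }
  structure(list(statistic = J, mean = mu, sd = sigma, z = z, p_value = p,
                 method = paste0("Jonckheere-Terpstra (", method, ", ",
                                 alternative, ")")),
            class = "test_result")
}

#' Multiple linear regression with treatment coding
#'
#' Ordinary least squares for a continuous response (typically log2(SIRI))
#' on a financial-toxicity group term plus confounders. Categorical terms
#' use treatment coding against explicitly declared reference levels;
#' classical standard errors, t-based 95% confidence intervals and
#' two-sided p-values are reported.
#'
#' @param data data.frame containing response and terms.
#' @param response response column name.
#' @param terms character vector of predictor column names.
#' @param reference_levels optional named list/character vector giving the
#'   reference level of categorical terms.
#' @param conf_level confidence level (default 0.95).
#' @return a `regression_fit`: list with `table` (term, estimate, ci_lower,
#'   ci_upper, p_value), `sigma2` (residual variance), `n`, and the
#'   underlying `lm` fit.
#' @export
ols_regression <- function(data, response, terms, reference_levels = NULL,
                           conf_level = 0.95) {
  miss <- setdiff(c(response, terms), names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- data[, c(response, terms), drop = FALSE]
  for (nm in names(reference_levels %||% list())) {
    if (!is.factor(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    df[[nm]] <- stats::relevel(df[[nm]], ref = reference_levels[[nm]])
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  if (nrow(df) <= length(cf))
    stop("more coefficients than observations", call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  structure(list(
    table = data.frame(term = names(cf), estimate = unname(cf),
                       ci_lower = ci[, 1], ci_upper = ci[, 2],
                       p_value = sm$coefficients[, 4], row.names = NULL),
    sigma2 = sm$sigma^2, n = nrow(df), fit = fit),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit, n = %d, residual variance = %.4g\n", x$n, x$sigma2))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$method, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %d", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("HR = %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d (%d events)\n",
              x$hr, x$ci_lower, x$ci_upper, x$p_value, x$n, x$n_event))
  invisible(x)
}
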