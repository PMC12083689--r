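# Random survival forest layer: fitting (via ranger's log-rank splitting),
# ensemble mortality scores, concordance, permutation importance,
# time-dependent IPCW AUC, and extraction of the forest's split thresholds
# for downstream cutoff distillation.

#' Random survival forest configuration
#'
#' Defaults mirror the conventional survival-forest defaults: 1000 trees,
#' `ceiling(sqrt(p))` candidate variables per split, minimum terminal node
#' size 15. Candidate thresholds at a node are the midpoints between sorted
#' unique in-node values (all of them; the log-rank statistic is maximized
#' over variable x threshold).
#'
#' @param n_trees number of bootstrap trees (default 1000).
#' @param variables_per_split variables tried per split; default
#'   `ceiling(sqrt(p))`, resolved at fit time.
#' @param min_terminal_size minimum terminal node size (default 15).
#' @param seed integer seed; the whole fit is reproducible given it.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000, variables_per_split = NULL,
                          min_terminal_size = 15, seed = 1L) {
  stopifnot(n_trees >= 1, min_terminal_size >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 variables_per_split = variables_per_split,
                 min_terminal_size = as.integer(min_terminal_size),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Fit a random survival forest
#'
#' Trees are grown on independent bootstrap resamples with log-rank
#' splitting; each leaf carries the Nelson-Aalen cumulative hazard of its
#' in-bag members, and out-of-bag membership is recorded per tree. Factors
#' are treated as ordered by their coded level order so that split rules
#' stay single thresholds. Permutation importance (out-of-bag C-index drop)
#' is computed during the fit.
#'
#' @param data cohort data.frame containing the model variables plus the
#'   time and event columns.
#' @param variables character vector of covariate names.
#' @param config a [forest_config()].
#' @param time_col,event_col outcome column names.
#' @return an object of class `survival_forest`.
#' @export
fit_forest <- function(data, variables, config = forest_config(),
                       time_col = "time_months", event_col = "event") {
  stopifnot(inherits(config, "forest_config"))
  missing_vars <- setdiff(c(variables, time_col, event_col), names(data))
  if (length(missing_vars))
    stop("missing columns: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  check_surv_vectors(data[[time_col]], data[[event_col]])
  if (sum(data[[event_col]]) == 0)
    stop("cohort has no events; cannot fit a survival forest", call. = FALSE)
  mtry <- config$variables_per_split %||% ceiling(sqrt(length(variables)))
  df <- data[, c(variables, time_col, event_col)]
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ .", time_col, event_col))
  rf <- ranger::ranger(fml, data = df,
                       num.trees = config$n_trees,
                       mtry = min(mtry, length(variables)),
                       min.node.size = config$min_terminal_size,
                       splitrule = "logrank",
                       keep.inbag = TRUE,
                       importance = "permutation",
                       respect.unordered.factors = "ignore",
                       seed = config$seed,
                       num.threads = 1)
  structure(list(engine = rf, variables = variables,
                 time_col = time_col, event_col = event_col,
                 config = config, train_data = df,
                 event_times = rf$unique.death.times),
            class = "survival_forest")
}

#' Grow a single survival tree on the full sample
#'
#' A one-tree forest grown without resampling and with all variables
#' available at every split: greedy recursive partitioning by the two-sample
#' log-rank statistic. `max_depth` optionally caps the depth.
#'
#' @inheritParams fit_forest
#' @param max_depth optional depth cap (0 = unlimited).
#' @return a `survival_forest` with one tree.
#' @export
grow_survival_tree <- function(data, variables, config = forest_config(n_trees = 1),
                               max_depth = 0,
                               time_col = "time_months", event_col = "event") {
  missing_vars <- setdiff(c(variables, time_col, event_col), names(data))
  if (length(missing_vars))
    stop("missing columns: ", paste(missing_vars, collapse = ", "), call. = FALSE)
  if (sum(data[[event_col]]) == 0)
    stop("cohort has no events; cannot grow a survival tree", call. = FALSE)
  df <- data[, c(variables, time_col, event_col)]
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ .", time_col, event_col))
  rf <- ranger::ranger(fml, data = df, num.trees = 1,
                       mtry = length(variables),
                       min.node.size = config$min_terminal_size,
                       max.depth = max_depth,
                       splitrule = "logrank",
                       replace = FALSE, sample.fraction = 1,
                       keep.inbag = TRUE,
                       respect.unordered.factors = "ignore",
                       seed = config$seed, num.threads = 1)
  structure(list(engine = rf, variables = variables,
                 time_col = time_col, event_col = event_col,
                 config = config, train_data = df,
                 event_times = rf$unique.death.times),
            class = "survival_forest")
}

#' Ensemble mortality score
#'
#' The ensemble cumulative hazard of a subject is the mean of its leaf
#' Nelson-Aalen cumulative hazards across trees; the mortality score is the
#' sum of the ensemble cumulative hazard over all unique training event
#' times. Higher score = higher predicted risk.
#'
#' @param forest a fitted [fit_forest()] object.
#' @param newdata covariate data.frame; when `NULL` with `oob = TRUE`,
#'   out-of-bag predictions on the training data are returned.
#' @param oob use out-of-bag ensemble predictions (training data only).
#' @return numeric vector of mortality scores.
#' @export
predict_mortality <- function(forest, newdata = NULL, oob = FALSE) {
  stopifnot(inherits(forest, "survival_forest"))
  if (oob) return(rowSums(forest$engine$chf))
  if (is.null(newdata)) newdata <- forest$train_data
  missing_vars <- setdiff(forest$variables, names(newdata))
  if (length(missing_vars))
    stop("newdata lacks model variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  p <- stats::predict(forest$engine, data = newdata, num.threads = 1)
  rowSums(p$chf)
}

#' Ensemble cumulative hazard curves
#'
#' @inheritParams predict_mortality
#' @return list with `time` (unique training event times) and `chf`
#'   (subjects x times matrix, non-decreasing along each row).
#' @export
predict_chf <- function(forest, newdata = NULL, oob = FALSE) {
  stopifnot(inherits(forest, "survival_forest"))
  chf <- if (oob) forest$engine$chf
  else stats::predict(forest$engine, data = newdata %||% forest$train_data,
                      num.threads = 1)$chf
  list(time = forest$event_times, chf = chf)
}

#' Harrell's concordance index for censored data
#'
#' A pair is evaluable when it is orderable under right-censoring: the
#' member with the shorter observed time experienced the event (pairs with
#' equal observed times are not orderable). A pair is concordant when the
#' shorter-lived member has the higher risk score; score ties count 1/2.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param times observed times.
#' @param events event indicators (0/1).
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(scores, times, events) {
  check_surv_vectors(times, events)
  stopifnot(length(scores) == length(times))
  earlier <- outer(times, times, "<") & matrix(events == 1, length(times),
                                               length(times))
  # earlier[i, j] TRUE: i died before j was last seen -> pair orderable
  higher <- outer(scores, scores, ">")
  tied <- outer(scores, scores, "==")
  n_eval <- sum(earlier)
  if (n_eval == 0)
    stop("no evaluable pair: concordance undefined", call. = FALSE)
  (sum(earlier & higher) + 0.5 * sum(earlier & tied)) / n_eval
}

#' Out-of-bag concordance of a forest
#'
#' @param forest a fitted [fit_forest()] object.
#' @return OOB C-index (one minus ranger's OOB prediction error).
#' @export
oob_concordance <- function(forest) {
  stopifnot(inherits(forest, "survival_forest"))
  1 - forest$engine$prediction.error
}

#' Permutation variable importance
#'
#' VIMP of a variable is the drop in out-of-bag C-index when the variable is
#' randomly shuffled, averaged over trees (each tree contributes one
#' permutation of its out-of-bag rows). Computed during [fit_forest()] and
#' reproducible under the forest seed.
#'
#' @param forest a fitted [fit_forest()] object.
#' @param variables optional subset of model variables.
#' @return named numeric vector of C-index drops.
#' @export
permutation_vimp <- function(forest, variables = NULL) {
  stopifnot(inherits(forest, "survival_forest"))
  vimp <- forest$engine$variable.importance
  if (is.null(vimp)) stop("forest was fitted without importance", call. = FALSE)
  if (!is.null(variables)) {
    absent <- setdiff(variables, names(vimp))
    if (length(absent))
      stop("variable absent from model: ", paste(absent, collapse = ", "),
           call. = FALSE)
    vimp <- vimp[variables]
  }
  vimp
}

# Kaplan-Meier estimate of the censoring distribution G, returned as a
# left-continuous step-function evaluator: G(t-) = P(C >= t).
censoring_survfit <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  step_t <- fit$time; step_s <- fit$surv
  function(t, left = FALSE) {
    idx <- if (left) findInterval(t - 1e-12, step_t) else findInterval(t, step_t)
    ifelse(idx == 0, 1, step_s[pmax(idx, 1)])
  }
}

#' Time-dependent cumulative/dynamic AUC with IPCW
#'
#' Cases at horizon t are subjects with an observed event by t; controls are
#' subjects still under observation beyond t. Cases are weighted by the
#' inverse probability of remaining uncensored up to their event time
#' (Kaplan-Meier estimate of the censoring distribution); score ties count
#' 1/2. This is the Uno-type cumulative/dynamic estimator.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param times,events observed follow-up and event indicator.
#' @param horizon evaluation time (within the follow-up range).
#' @return AUC(t) in `[0, 1]`.
#' @export
time_dependent_auc <- function(scores, times, events, horizon) {
  check_surv_vectors(times, events)
  stopifnot(length(scores) == length(times), is.finite(horizon))
  is_case <- times <= horizon & events == 1
  is_control <- times > horizon
  if (!any(is_case) || !any(is_control))
    stop("AUC undefined: no cases or no controls at the horizon", call. = FALSE)
  G <- censoring_survfit(times, events)
  w <- 1 / G(times[is_case], left = TRUE)
  sc <- scores[is_case]; sk <- scores[is_control]
  comp <- outer(sc, sk, ">") + 0.5 * outer(sc, sk, "==")
  sum(w * rowSums(comp)) / (sum(w) * length(sk))
}

#' Extract the forest's split thresholds for one variable
#'
#' Every internal node that splits on the variable contributes its threshold
#' once, together with the in-bag sample size of the node (obtained by
#' routing each tree's bootstrap sample down the tree) and the tree index.
#'
#' @param forest a fitted [fit_forest()] object.
#' @param variable a continuous model variable name.
#' @return data.frame with columns `threshold`, `node_size`, `tree`
#'   (zero rows when the forest never splits on the variable).
#' @export
extract_split_thresholds <- function(forest, variable) {
  stopifnot(inherits(forest, "survival_forest"))
  rf <- forest$engine
  # numeric codings used for routing (factors were fitted in coded order)
  xnum <- lapply(forest$train_data[forest$variables], function(v)
    if (is.factor(v)) as.numeric(v) else as.numeric(v))
  out <- vector("list", rf$num.trees)
  for (t in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, t)
    inbag <- rf$inbag.counts[[t]]
    # node_members[[nodeID + 1]]: training row indices in the node's in-bag
    # sample; children always have larger IDs than their parent, so one
    # forward pass in nodeID order suffices.
    node_members <- vector("list", nrow(ti))
    node_members[[1]] <- which(inbag > 0)
    sizes <- numeric(nrow(ti))
    for (r in seq_len(nrow(ti))) {
      rows <- node_members[[ti$nodeID[r] + 1]]
      sizes[r] <- if (length(rows)) sum(inbag[rows]) else 0
      if (!ti$terminal[r] && length(rows)) {
        left <- xnum[[ti$splitvarName[r]]][rows] <= ti$splitval[r]
        node_members[[ti$leftChild[r] + 1]] <- rows[left]
        node_members[[ti$rightChild[r] + 1]] <- rows[!left]
      }
    }
    keep <- !ti$terminal & ti$splitvarName == variable
    keep[is.na(keep)] <- FALSE
    if (any(keep))
      out[[t]] <- data.frame(threshold = ti$splitval[keep],
                             node_size = sizes[keep], tree = t)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(threshold = numeric(0), node_size = numeric(0),
                      tree = integer(0))
  res
}

#' Stratified 70/30 train/test split
#'
#' Splits row indices into a training/validation set and a held-out test
#' set, stratified by the event indicator so small test sets keep a stable
#' event fraction.
#'
#' @param events event indicator vector.
#' @param train_fraction training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (disjoint, covering
#'   all rows).
#' @export
split_cohort <- function(events, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  idx <- seq_along(events)
  train <- unlist(lapply(unique(events), function(e) {
    rows <- idx[events == e]
    sample(rows, round(length(rows) * train_fraction))
  }))
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}
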