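# Parsimonious clinic-facing decision tree on discretized variables:
# greedy log-rank splitting over category subsets with a depth cap and a
# minimum leaf size, followed by merging of statistically indistinguishable
# leaves into ordered risk groups.

#' Risk-tree configuration
#'
#' Defaults follow the shallow-tree convention for clinic-facing rules:
#' maximal depth 3 (to avoid overly complicated rules) and minimum node
#' size 40.
#'
#' @param max_depth maximal tree depth (>= 1, default 3).
#' @param min_node_size minimum subjects per leaf (>= 2, default 40).
#' @param alpha pairwise log-rank level used when merging adjacent leaves
#'   (default 0.05).
#' @param target_groups optional fixed number of output groups (overrides
#'   `alpha`-driven merging).
#' @return an object of class `risk_tree_config`.
#' @export
risk_tree_config <- function(max_depth = 3, min_node_size = 40,
                             alpha = 0.05, target_groups = NULL) {
  stopifnot(max_depth >= 1, min_node_size >= 2)
  structure(list(max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 alpha = alpha, target_groups = target_groups),
            class = "risk_tree_config")
}

#' Discretize continuous variables with distilled cutoffs
#'
#' Each continuous value is mapped to the index of its interval among the
#' left-closed intervals induced by the variable's cutoffs; boundary values
#' go to the upper interval. An empty cutoff set collapses the variable to
#' a single category (with a warning).
#'
#' @param data data.frame.
#' @param cutoff_sets list of `cutoff_set` objects (one per continuous
#'   variable to discretize).
#' @return the data.frame with each listed variable replaced by a factor
#'   with human-readable interval labels.
#' @export
discretize <- function(data, cutoff_sets) {
  for (cs in cutoff_sets) {
    stopifnot(inherits(cs, "cutoff_set"))
    v <- cs$variable
    if (is.null(data[[v]]))
      stop(sprintf("variable '%s' missing from data", v), call. = FALSE)
    if (anyNA(data[[v]]))
      stop(sprintf("variable '%s' has missing values", v), call. = FALSE)
    if (length(cs$cutoffs) == 0) {
      warning(sprintf("empty cutoff set for '%s': single category", v),
              call. = FALSE)
      data[[v]] <- factor(rep("all", nrow(data)))
      next
    }
    cuts <- sort(cs$cutoffs)
    labs <- c(sprintf("<%.3g", cuts[1]),
              if (length(cuts) > 1)
                sprintf("[%.3g,%.3g)", utils::head(cuts, -1), utils::tail(cuts, -1)),
              sprintf(">=%.3g", cuts[length(cuts)]))
    data[[v]] <- cut(data[[v]], breaks = c(-Inf, cuts, Inf), right = FALSE,
                     labels = labs)
  }
  data
}

# two-sample log-rank chi-square for a candidate split; -Inf when the split
# is not evaluable (no events, degenerate groups)
logrank_chisq <- function(times, events, left) {
  if (sum(events) == 0) return(-Inf)
  tryCatch(survival::survdiff(survival::Surv(times, events) ~ left)$chisq,
           error = function(e) -Inf)
}

# all binary partitions of a level set (up to complement): 2^(k-1) - 1
level_partitions <- function(levels_present) {
  k <- length(levels_present)
  if (k < 2) return(list())
  if (k > 6) stop("more than 6 categories in one variable; refusing exhaustive search",
                  call. = FALSE)
  parts <- list()
  for (code in 1:(2^(k - 1) - 1)) {
    parts[[length(parts) + 1]] <- levels_present[as.logical(bitwAnd(
      code, 2^(seq_len(k) - 1)))]
  }
  parts
}

grow_node <- function(data, times, events, depth, config, counter) {
  n <- length(times)
  make_leaf <- function() {
    counter$id <- counter$id + 1L
    list(is_leaf = TRUE, leaf_id = counter$id, n = n, depth = depth)
  }
  if (depth >= config$max_depth || n < 2 * config$min_node_size ||
      sum(events) == 0)
    return(make_leaf())
  best <- list(chisq = -Inf)
  for (v in names(data)) {
    lv <- levels(droplevels(data[[v]]))
    for (part in level_partitions(lv)) {
      left <- data[[v]] %in% part
      if (sum(left) < config$min_node_size || sum(!left) < config$min_node_size)
        next
      cs <- logrank_chisq(times, events, left)
      if (is.finite(cs) && cs > best$chisq)
        best <- list(chisq = cs, variable = v, left_levels = part, left = left)
    }
  }
  if (!is.finite(best$chisq)) return(make_leaf())
  list(is_leaf = FALSE, variable = best$variable,
       left_levels = best$left_levels, n = n, depth = depth,
       chisq = best$chisq,
       left = grow_node(data[best$left, , drop = FALSE], times[best$left],
                        events[best$left], depth + 1, config, counter),
       right = grow_node(data[!best$left, , drop = FALSE], times[!best$left],
                         events[!best$left], depth + 1, config, counter))
}

#' Grow a shallow log-rank decision tree on categorical covariates
#'
#' Greedy recursive partitioning: at each node, the binary partition of one
#' variable's categories maximizing the two-sample log-rank statistic is
#' chosen among all `2^(k-1) - 1` subsets (k <= 6); splits producing a child
#' below `min_node_size` are inadmissible, and depth is capped.
#'
#' @param data data.frame of factor covariates only.
#' @param times,events survival outcome vectors.
#' @param config a [risk_tree_config()].
#' @return an object of class `risk_tree`.
#' @export
grow_risk_tree <- function(data, times, events, config = risk_tree_config()) {
  stopifnot(inherits(config, "risk_tree_config"))
  check_surv_vectors(times, events)
  if (!all(vapply(data, is.factor, logical(1))))
    stop("all risk-tree covariates must be factors (discretize first)", call. = FALSE)
  if (sum(events) == 0) stop("no events; cannot grow a risk tree", call. = FALSE)
  counter <- new.env(); counter$id <- 0L
  root <- grow_node(data, times, events, 0L, config, counter)
  if (root$is_leaf)
    warning("no admissible first split: single-leaf tree", call. = FALSE)
  structure(list(root = root, variables = names(data), config = config,
                 n_leaves = counter$id),
            class = "risk_tree")
}

# vectorized leaf routing
route_leaf <- function(node, data, rows, out) {
  if (node$is_leaf) { out[rows] <- node$leaf_id; return(out) }
  if (length(rows) == 0) return(out)
  left <- data[[node$variable]][rows] %in% node$left_levels
  out <- route_leaf(node$left, data, rows[left], out)
  route_leaf(node$right, data, rows[!left], out)
}

#' Leaf membership of a risk tree
#'
#' @param tree a `risk_tree`.
#' @param data data.frame with the tree's covariates.
#' @return integer vector of leaf ids (1..n_leaves).
#' @export
assign_leaf <- function(tree, data) {
  stopifnot(inherits(tree, "risk_tree"))
  missing_vars <- setdiff(tree$variables, names(data))
  if (length(missing_vars))
    stop("data lacks tree variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  route_leaf(tree$root, data, seq_len(nrow(data)), integer(nrow(data)))
}

#' Merge risk-tree leaves into ordered risk groups
#'
#' Leaves are ordered by their training-set mean mortality score; the
#' adjacent pair whose survival curves are least distinguishable (largest
#' pairwise log-rank p) is merged while p exceeds `alpha`, or until
#' `target_groups` remain. Groups are numbered 1..G by increasing risk.
#'
#' @param tree a [grow_risk_tree()] result.
#' @param data training covariates (factors).
#' @param times,events training outcome.
#' @param scores training mortality scores (e.g. from [predict_mortality()])
#'   used to order leaves by risk.
#' @param alpha pairwise log-rank merge level (default from the tree config).
#' @param target_groups optional fixed group count.
#' @return an object of class `risk_group_model`.
#' @export
merge_leaves <- function(tree, data, times, events, scores,
                         alpha = NULL, target_groups = NULL) {
  stopifnot(inherits(tree, "risk_tree"), length(scores) == length(times))
  alpha <- alpha %||% tree$config$alpha
  target_groups <- target_groups %||% tree$config$target_groups
  leaf <- assign_leaf(tree, data)
  leaf_ids <- sort(unique(leaf))
  leaf_mean <- vapply(leaf_ids, function(l) mean(scores[leaf == l]), numeric(1))
  ord <- leaf_ids[order(leaf_mean)]
  groups <- as.list(ord) # each element: vector of leaf ids, in risk order
  pair_p <- function(a, b) {
    ia <- leaf %in% a; ib <- leaf %in% b
    sel <- ia | ib
    if (sum(events[sel]) == 0) return(1)
    cs <- logrank_chisq(times[sel], events[sel], ia[sel])
    if (!is.finite(cs)) return(1)
    stats::pchisq(cs, df = 1, lower.tail = FALSE)
  }
  while (length(groups) > 1) {
    p <- vapply(seq_len(length(groups) - 1), function(i)
      pair_p(groups[[i]], groups[[i + 1]]), numeric(1))
    if (!is.null(target_groups)) {
      if (length(groups) <= target_groups) break
    } else if (max(p) <= alpha) break
    i <- which.max(p)
    groups[[i]] <- c(groups[[i]], groups[[i + 1]])
    groups[[i + 1]] <- NULL
  }
  leaf_group <- integer(max(leaf_ids))
  for (g in seq_along(groups)) leaf_group[groups[[g]]] <- g
  group <- leaf_group[leaf]
  stats_df <- data.frame(
    group = seq_along(groups),
    n = as.integer(tabulate(group, length(groups))),
    events = vapply(seq_along(groups), function(g) sum(events[group == g]), numeric(1)),
    mean_mortality = vapply(seq_along(groups), function(g) mean(scores[group == g]),
                            numeric(1)))
  km <- lapply(seq_along(groups), function(g)
    kaplan_meier(times[group == g], events[group == g]))
  names(km) <- paste0("group", seq_along(groups))
  structure(list(tree = tree, leaf_group = leaf_group,
                 group_stats = stats_df, km = km,
                 alpha = alpha, target_groups = target_groups),
            class = "risk_group_model")
}

#' Assign patients to ordered risk groups
#'
#' Deterministic leaf routing through the decision tree followed by the
#' leaf-to-group mapping.
#'
#' @param model a [merge_leaves()] result.
#' @param data data.frame with all tree variables.
#' @return integer group indices (1 = lowest risk).
#' @export
assign_risk_group <- function(model, data) {
  stopifnot(inherits(model, "risk_group_model"))
  model$leaf_group[assign_leaf(model$tree, data)]
}

#' Dichotomize risk scores at a reference quantile
#'
#' Labels a subject high-risk when its score strictly exceeds the given
#' empirical quantile (linear-interpolation convention, [stats::quantile()]
#' type 7) of the reference scores -- typically the 75th percentile of the
#' training-set predictions.
#'
#' @param scores scores to label.
#' @param reference_scores scores defining the threshold (default: `scores`).
#' @param quantile quantile level (default 0.75).
#' @return factor with levels `low`, `high`, plus attribute `threshold`.
#' @export
threshold_high_risk <- function(scores, reference_scores = scores,
                                quantile = 0.75) {
  if (length(reference_scores) < 4)
    stop("need at least 4 reference scores", call. = FALSE)
  if (length(unique(reference_scores)) == 1)
    stop("all reference scores tied: no stratification possible", call. = FALSE)
  thr <- stats::quantile(reference_scores, quantile, names = FALSE, type = 7)
  out <- factor(ifelse(scores > thr, "high", "low"), levels = c("low", "high"))
  attr(out, "threshold") <- thr
  out
}

render_rules <- function(node, path) {
  if (node$is_leaf)
    return(data.frame(leaf_id = node$leaf_id, n = node$n,
                      rule = if (nchar(path)) path else "(all)"))
  fmt <- function(lv) if (length(lv) == 1) lv else
    paste0("{", paste(lv, collapse = ","), "}")
  sep <- if (nchar(path)) " & " else ""
  rbind(
    render_rules(node$left, paste0(path, sep, node$variable, " in ",
                                   fmt(node$left_levels))),
    render_rules(node$right, paste0(path, sep, node$variable, " not in ",
                                    fmt(node$left_levels))))
}

#' Human-readable rule list of a risk-group model
#'
#' @param model a `risk_group_model` (or a bare `risk_tree`).
#' @return data.frame with one row per leaf: `leaf_id`, `n`, `rule`,
#'   and `group` when a model is given.
#' @export
risk_group_rules <- function(model) {
  tree <- if (inherits(model, "risk_group_model")) model$tree else model
  out <- render_rules(tree$root, "")
  out <- out[order(out$leaf_id), ]
  if (inherits(model, "risk_group_model"))
    out$group <- model$leaf_group[out$leaf_id]
  rownames(out) <- NULL
  out
}

#' @export
print.risk_group_model <- function(x, ...) {
  cat("Risk-group model:", nrow(x$group_stats), "ordered groups\n")
  print(x$group_stats, row.names = FALSE)
  rules <- risk_group_rules(x)
  for (i in seq_len(nrow(rules)))
    cat(sprintf("  %s -> Group %d\n", rules$rule[i], rules$group[i]))
  invisible(x)
}

#' Kaplan-Meier curves of the ordered risk groups
#'
#' Step curves of the per-group training-set Kaplan-Meier estimates stored
#' in the model, lowest-risk group first.
#'
#' @param x a `risk_group_model`.
#' @param ... passed to [plot()].
#' @export
plot.risk_group_model <- function(x, ...) {
  G <- length(x$km)
  cols <- grDevices::hcl.colors(max(G, 2), "Dark 2")
  xmax <- max(vapply(x$km, function(k) max(k$time), numeric(1)))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = "months",
       ylab = "survival probability", ...)
  for (g in seq_len(G)) {
    k <- x$km[[g]]
    graphics::lines(stats::stepfun(k$time, c(1, k$survival)), do.points = FALSE,
                    col = cols[g], lwd = 2)
  }
  graphics::legend("bottomleft", paste("Group", seq_len(G)), col = cols[seq_len(G)],
                   lwd = 2, bty = "n")
  invisible(x)
}

node_to_list <- function(node) {
  if (node$is_leaf)
    return(list(leaf_id = node$leaf_id, n = node$n))
  list(variable = node$variable, left_levels = as.list(node$left_levels),
       n = node$n, left = node_to_list(node$left),
       right = node_to_list(node$right))
}

#' Serialize a risk-group model to JSON
#'
#' Writes the decision tree, the leaf-to-group mapping, the rule list and
#' per-group summaries.
#'
#' @param model a `risk_group_model`.
#' @param path file path.
#' @export
write_risk_group_model <- function(model, path) {
  stopifnot(inherits(model, "risk_group_model"))
  jsonlite::write_json(list(
    tree = node_to_list(model$tree$root),
    leaf_group = model$leaf_group,
    rules = risk_group_rules(model),
    group_stats = model$group_stats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
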