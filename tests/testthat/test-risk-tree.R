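# Discretization, the shallow log-rank tree, leaf merging into ordered
# groups, patient assignment, and quantile-based high/low stratification.

fake_cutoff_set <- function(variable, cutoffs) {
  structure(list(variable = variable, cutoffs = cutoffs, status = "ok",
                 min_group_proportion = 0.1), class = "cutoff_set")
}

# one categorical covariate with per-level hazard rates; used to exercise
# tree growth and leaf merging against known group structure
leveled_cohort <- function(n, rates, seed, horizon = 60) {
  set.seed(seed)
  lev <- paste0("L", seq_along(rates))
  g <- factor(sample(lev, n, TRUE), levels = lev)
  t_ev <- rexp(n) / rates[as.integer(g)]
  data.frame(g = g, time_months = pmin(t_ev, horizon),
             event = as.integer(t_ev <= horizon))
}

test_that("discretization maps values to left-closed intervals", {
  cs_bmi <- fake_cutoff_set("bmi", c(25, 30))
  d <- discretize(data.frame(bmi = c(27.0, 24.9, 25.0, 30.0, 18.0)),
                  list(cs_bmi))
  expect_equal(nlevels(d$bmi), 3L)
  expect_equal(as.integer(d$bmi), c(2L, 1L, 2L, 3L, 1L))
  # boundary value goes to the upper interval
  d2 <- discretize(data.frame(siri = c(3.4999, 3.5)),
                   list(fake_cutoff_set("siri", 3.5)))
  expect_equal(as.integer(d2$siri), c(1L, 2L))
  # empty cutoff set collapses to one category, with a warning
  empty <- structure(list(variable = "x", cutoffs = numeric(0), status = "empty",
                          min_group_proportion = 0.1), class = "cutoff_set")
  expect_warning(d3 <- discretize(data.frame(x = rnorm(5)), list(empty)),
                 "single category")
  expect_equal(nlevels(d3$x), 1L)
  expect_error(discretize(data.frame(y = 1), list(fake_cutoff_set("x", 1))),
               "missing from data")
  expect_error(discretize(data.frame(x = c(1, NA)), list(fake_cutoff_set("x", 1))),
               "missing values")
})

test_that("risk tree honors depth and node-size constraints over simulated runs", {
  cfg <- risk_tree_config()
  expect_equal(cfg$max_depth, 3L)
  expect_equal(cfg$min_node_size, 40L)
  for (s in 1:8) {
    coh <- leveled_cohort(400, c(0.01, 0.02, 0.04, 0.08), seed = s)
    coh$h <- factor(sample(c("a", "b"), 400, TRUE))
    tree <- grow_risk_tree(coh[, c("g", "h")], coh$time_months, coh$event, cfg)
    leaves <- assign_leaf(tree, coh[, c("g", "h")])
    sizes <- table(leaves)
    expect_equal(sum(sizes), 400)
    expect_gte(min(sizes), 40)
    depth <- function(node) if (node$is_leaf) node$depth else
      max(depth(node$left), depth(node$right))
    expect_lte(depth(tree$root), 3)
  }
})

test_that("a binary covariate yields at most two leaves; degenerate trees warn", {
  coh <- leveled_cohort(300, c(0.01, 0.06), seed = 3)
  tree <- grow_risk_tree(coh[, "g", drop = FALSE], coh$time_months, coh$event,
                         risk_tree_config())
  expect_lte(tree$n_leaves, 2L)
  # constant covariate: no admissible split
  flat <- data.frame(g = factor(rep("a", 300)))
  expect_warning(t2 <- grow_risk_tree(flat, coh$time_months, coh$event),
                 "single-leaf")
  expect_equal(t2$n_leaves, 1L)
  expect_error(grow_risk_tree(data.frame(g = 1:10), rexp(10), rep(1, 10)),
               "factors")
})

test_that("the tree recovers planted threshold variables", {
  pars <- siri_lognormal_params(1.96, c(1.28, 3.14))
  hits <- 0
  for (s in 1:10) {
    cc <- cohort_config(n_subjects = 700, siri_log_median = pars$meanlog,
                        siri_log_sd = pars$sdlog, seed = 700 + s)
    hz <- hazard_spec(baseline_rate = 0.012,
                      threshold_effects = list(
                        list(variable = "siri", cutoff = 3.5, direction = ">=",
                             loghr = log(2.5)),
                        list(variable = "kps_cat", cutoff = "<=70",
                             direction = "in", loghr = log(2.2)),
                        list(variable = "smoking", cutoff = "current",
                             direction = "in", loghr = log(1.8))),
                      censor_horizon = 60, random_censor_rate = 0.005)
    coh <- simulate_cohort(cc, hz)
    cat_df <- discretize(coh[, c("siri", "kps_cat", "smoking")],
                         list(fake_cutoff_set("siri", 3.5)))
    tree <- grow_risk_tree(cat_df, coh$time_months, coh$event)
    used <- unique(unlist(lapply(risk_group_rules(tree)$rule, function(r)
      regmatches(r, gregexpr("siri|kps_cat|smoking", r))[[1]])))
    if (length(used) >= 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("leaves from a shared hazard merge; well-separated leaves do not", {
  merged_to_3 <- 0
  for (s in 1:10) {
    coh <- leveled_cohort(900, c(0.005, 0.02, 0.08, 0.08), seed = 40 + s)
    tree <- grow_risk_tree(coh[, "g", drop = FALSE], coh$time_months, coh$event,
                           risk_tree_config(max_depth = 3, min_node_size = 40))
    if (tree$n_leaves != 4) next
    scores <- stats::ave(coh$event, assign_leaf(tree, coh), FUN = mean)
    model <- merge_leaves(tree, coh[, "g", drop = FALSE], coh$time_months,
                          coh$event, scores)
    if (nrow(model$group_stats) == 3) merged_to_3 <- merged_to_3 + 1
  }
  expect_gte(merged_to_3, 8)

  # clearly distinct hazards at alpha = 0.05: nothing merges
  coh <- leveled_cohort(1200, c(0.004, 0.03, 0.2), seed = 77)
  tree <- grow_risk_tree(coh[, "g", drop = FALSE], coh$time_months, coh$event)
  scores <- stats::ave(coh$event, assign_leaf(tree, coh), FUN = mean)
  model <- merge_leaves(tree, coh[, "g", drop = FALSE], coh$time_months,
                        coh$event, scores)
  expect_equal(nrow(model$group_stats), tree$n_leaves)
  # forcing one group merges everything
  one <- merge_leaves(tree, coh[, "g", drop = FALSE], coh$time_months,
                      coh$event, scores, target_groups = 1)
  expect_equal(nrow(one$group_stats), 1L)
})

test_that("group assignment is deterministic, ordered, and checks inputs", {
  coh <- leveled_cohort(800, c(0.005, 0.03, 0.1), seed = 5)
  tree <- grow_risk_tree(coh[, "g", drop = FALSE], coh$time_months, coh$event)
  scores <- stats::ave(coh$event, assign_leaf(tree, coh), FUN = mean)
  model <- merge_leaves(tree, coh[, "g", drop = FALSE], coh$time_months,
                        coh$event, scores)
  # group means strictly increase with the index
  expect_true(all(diff(model$group_stats$mean_mortality) > 0))
  # identical patients get identical groups
  newpat <- data.frame(g = factor(c("L2", "L2"), levels = levels(coh$g)))
  gr <- assign_risk_group(model, newpat)
  expect_equal(gr[1], gr[2])
  expect_error(assign_risk_group(model, data.frame(other = 1)),
               "lacks tree variables")
  # observed event rate non-decreasing in group index on fresh data
  fresh <- leveled_cohort(3000, c(0.005, 0.03, 0.1), seed = 6)
  fg <- assign_risk_group(model, fresh[, "g", drop = FALSE])
  rates <- tapply(fresh$event, fg, mean)
  expect_true(all(diff(rates) >= 0))
})

test_that("high-risk thresholding follows the linear-interpolation quantile", {
  lab <- threshold_high_risk(c(1, 2, 3, 4))
  expect_equal(as.character(lab), c("low", "low", "low", "high"))
  expect_equal(attr(lab, "threshold"), 3.25)
  set.seed(8)
  sc <- rnorm(4000)
  expect_lt(abs(mean(threshold_high_risk(sc) == "high") - 0.25), 0.02)
  # training-derived threshold applied to an identically distributed test set
  ref <- rnorm(2000)
  lab2 <- threshold_high_risk(rnorm(2000), reference_scores = ref)
  expect_lt(abs(mean(lab2 == "high") - 0.25), 0.05)
  expect_error(threshold_high_risk(rep(1, 10)), "tied")
  expect_error(threshold_high_risk(1:3), "at least 4")
})

test_that("rule rendering and model serialization round-trip", {
  coh <- leveled_cohort(500, c(0.01, 0.08), seed = 9)
  tree <- grow_risk_tree(coh[, "g", drop = FALSE], coh$time_months, coh$event)
  scores <- stats::ave(coh$event, assign_leaf(tree, coh), FUN = mean)
  model <- merge_leaves(tree, coh[, "g", drop = FALSE], coh$time_months,
                        coh$event, scores)
  rules <- risk_group_rules(model)
  expect_equal(nrow(rules), tree$n_leaves)
  expect_true(all(c("rule", "group") %in% names(rules)))
  path <- tempfile(fileext = ".json")
  write_risk_group_model(model, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$leaf_group, model$leaf_group)
  expect_equal(nrow(back$rules), nrow(rules))
})
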