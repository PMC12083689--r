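# Forest layer: configuration, tree growth, mortality scores, concordance,
# VIMP, time-dependent AUC, split-threshold extraction.

make_signal_cohort <- function(n, seed) {
  set.seed(seed)
  x <- runif(n, 0, 7)
  z <- rnorm(n)
  rate <- 0.03 * exp(log(2.5) * (x >= 3.5))
  t_ev <- rexp(n) / rate
  t_c <- pmin(rexp(n) / 0.01, 60)
  data.frame(x = x, z = z, time_months = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c))
}

test_that("forest configuration carries the conventional defaults", {
  cfg <- forest_config()
  expect_equal(cfg$n_trees, 1000L)
  expect_equal(cfg$min_terminal_size, 15L)
  f <- fit_forest(make_signal_cohort(120, 1), c("x", "z"),
                  forest_config(n_trees = 25, seed = 1))
  expect_equal(f$engine$num.trees, 25)
  expect_error(fit_forest(data.frame(x = 1:5, time_months = 1:5,
                                     event = rep(0, 5)), "x"),
               "no events")
})

test_that("a tree with terminal size n is a single root leaf; growth is deterministic", {
  d <- make_signal_cohort(80, 2)
  tr <- grow_survival_tree(d, c("x", "z"),
                           forest_config(n_trees = 1,
                                         min_terminal_size = nrow(d), seed = 3))
  info <- ranger::treeInfo(tr$engine, 1)
  expect_equal(nrow(info), 1L)
  expect_true(info$terminal[1])
  # identical rng stream => identical tree
  tr2 <- grow_survival_tree(d, c("x", "z"),
                            forest_config(n_trees = 1, min_terminal_size = 15,
                                          seed = 9))
  tr3 <- grow_survival_tree(d, c("x", "z"),
                            forest_config(n_trees = 1, min_terminal_size = 15,
                                          seed = 9))
  expect_identical(ranger::treeInfo(tr2$engine, 1), ranger::treeInfo(tr3$engine, 1))
})

test_that("root split of a single-covariate tree recovers a planted step", {
  hits <- 0
  for (s in 1:10) {
    d <- make_signal_cohort(500, 100 + s)
    tr <- grow_survival_tree(d[, c("x", "time_months", "event")], "x",
                             forest_config(n_trees = 1, min_terminal_size = 15,
                                           seed = s))
    root <- ranger::treeInfo(tr$engine, 1)[1, ]
    if (!root$terminal && abs(root$splitval - 3.5) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("mortality scores: constant on a stump, ordered across a planted threshold", {
  d <- make_signal_cohort(150, 4)
  stump <- grow_survival_tree(d, c("x", "z"),
                              forest_config(n_trees = 1,
                                            min_terminal_size = nrow(d), seed = 1))
  expect_equal(length(unique(predict_mortality(stump, d))), 1L)

  f <- fit_forest(d, c("x", "z"), forest_config(n_trees = 100, seed = 5))
  twins <- data.frame(x = c(2.0, 5.0), z = c(0, 0))
  sc <- predict_mortality(f, twins)
  expect_gt(sc[2], sc[1]) # crossing the high-risk threshold raises the score
  # ensemble CHF is non-decreasing in time for every subject
  chf <- predict_chf(f, d)$chf
  expect_true(all(apply(chf, 1, function(r) all(diff(r) >= -1e-12))))
  expect_error(predict_mortality(f, data.frame(x = 1)), "lacks model variables")
})

test_that("concordance matches its definition and the survival package", {
  times <- c(5, 3, 9, 1, 7)
  events <- rep(1, 5)
  expect_equal(concordance_index(-rank(times), times, events), 1.0)
  expect_equal(concordance_index(rank(times), times, events), 0.0)

  inst <- random_surv_instance(60, seed = 31)
  ours <- concordance_index(inst$scores, inst$times, inst$events)
  expect_equal(ours, oracle_concordance(inst$scores, inst$times, inst$events))
  # independent implementation: survival::concordance counts score ties 1/2
  cfit <- survival::concordance(survival::Surv(inst$times, inst$events) ~
                                  inst$scores, reverse = TRUE)
  expect_equal(ours, unname(cfit$concordance), tolerance = 1e-10)
  # invariance under a strictly monotone transform of the scores
  expect_equal(concordance_index(exp(inst$scores), inst$times, inst$events), ours)
  expect_error(concordance_index(1:3, c(2, 2, 2), c(1, 1, 1)), "no evaluable pair")
})

test_that("permutation VIMP separates a planted signal from noise, reproducibly", {
  d <- make_signal_cohort(400, 6)
  d$noise1 <- rnorm(400); d$noise2 <- runif(400)
  f <- fit_forest(d, c("x", "noise1", "noise2"),
                  forest_config(n_trees = 200, seed = 7))
  v <- permutation_vimp(f)
  expect_true(v["x"] > v["noise1"] && v["x"] > v["noise2"])
  expect_lt(abs(v["noise1"]), 0.02)
  f2 <- fit_forest(d, c("x", "noise1", "noise2"),
                   forest_config(n_trees = 200, seed = 7))
  expect_identical(v, permutation_vimp(f2))
  expect_error(permutation_vimp(f, "absent"), "absent")
})

test_that("time-dependent AUC: degenerate cases and the IPCW fixture", {
  times <- c(2, 4, 6, 8, 10, 12, 14, 16)
  events <- rep(1, 8)
  expect_equal(time_dependent_auc(rep(1, 8), times, events, 9), 0.5)
  # scores perfectly separating events before the horizon from survivors
  expect_equal(time_dependent_auc(-times, times, events, 9), 1.0)
  expect_error(time_dependent_auc(1:8, times, events, 1), "no cases")

  # frozen independent reference (scikit-survival cumulative_dynamic_auc)
  time <- c(10.328, 20.415, 4.821, 7.411, 7.456, 15.077, 6.009, 6.46, 51.892,
            35.139, 26.222, 77.664, 23.835, 3.145, 0.698, 37.558, 52.885, 0.57,
            76.527, 16.197, 56.505, 11.076, 124.25, 11.7, 11.4, 14.465, 24.93,
            6.285, 4.855, 26.414, 22.363, 2.58, 36.811, 23.857, 33.952, 16.188,
            22.101, 56.954, 29.576, 36.249)
  event <- c(1, 0, 1, 1, 1, 1, 1, 1, 1, 0, 1, 0, 0, 0, 1, 1, 0, 0, 1, 1, 1, 1,
             1, 0, 1, 0, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 1, 0, 1, 1)
  score <- c(4.6961, 4.6539, 4.5051, 4.7466, 4.7497, 3.8621, 4.4086, 4.3746,
             3.3629, 4.2772, 4.7429, 1.9849, 4.4015, 5.7737, 4.756, 2.7666,
             2.5683, 4.8505, 3.1943, 4.0247, 3.1689, 5.5612, 1.6303, 5.1635,
             5.2223, 5.0384, 5.0945, 5.5452, 6.2467, 4.2417, 5.2269, 4.5667,
             4.2955, 3.7829, 4.1952, 4.2193, 5.5583, 3.1812, 3.7969, 4.0702)
  expect_equal(time_dependent_auc(score, time, event, 12), 0.85022624,
               tolerance = 1e-7)
  expect_equal(time_dependent_auc(score, time, event, 24), 0.88015012,
               tolerance = 1e-7)
})

test_that("split-threshold extraction matches a treeInfo recount with consistent node sizes", {
  d <- make_signal_cohort(250, 8)
  f <- fit_forest(d, c("x", "z"), forest_config(n_trees = 40, seed = 9))
  for (v in c("x", "z")) {
    th <- extract_split_thresholds(f, v)
    recount <- 0
    for (t in seq_len(40)) {
      info <- ranger::treeInfo(f$engine, t)
      recount <- recount + sum(!info$terminal & info$splitvarName == v,
                               na.rm = TRUE)
    }
    expect_equal(nrow(th), recount)
    expect_true(all(th$node_size >= 1))
  }
  # root nodes carry the whole bootstrap sample
  th <- extract_split_thresholds(f, "x")
  for (t in unique(th$tree)) {
    info <- ranger::treeInfo(f$engine, t)
    if (!info$terminal[1] && info$splitvarName[1] == "x") {
      root_size <- th$node_size[th$tree == t][1]
      expect_equal(root_size, sum(f$engine$inbag.counts[[t]]))
    }
  }
  # a variable the forest never splits on yields an empty multiset
  d$flat <- rep(1, nrow(d))
  f2 <- fit_forest(d, c("x", "flat"), forest_config(n_trees = 20, seed = 2))
  expect_equal(nrow(extract_split_thresholds(f2, "flat")), 0L)
})

test_that("stratified split is disjoint, covering, and event-balanced", {
  ev <- rep(c(0, 1), c(120, 80))
  sp <- split_cohort(ev, 0.7, seed = 13)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(ev))
  expect_equal(sum(ev[sp$train]), round(0.7 * 80))
})
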