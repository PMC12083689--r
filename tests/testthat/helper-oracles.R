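# Independent oracles used across the suite. These re-derive quantities by
# brute force / closed form and are deliberately written without reference
# to the package's implementations.

# concordance by explicit pair loops over the definition: a pair is
# evaluable when the shorter observed time carries an event; ties in score
# count one half.
oracle_concordance <- function(scores, times, events) {
  n <- length(times)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) next
      s <- if (times[i] < times[j]) i else j # shorter-lived member
      l <- if (s == i) j else i
      if (events[s] != 1) next
      den <- den + 1
      if (scores[s] > scores[l]) num <- num + 1
      else if (scores[s] == scores[l]) num <- num + 0.5
    }
  }
  num / den
}

# two-group log-rank statistic from the risk-set table (O - E and
# hypergeometric variance with tie handling), written from the formula.
oracle_logrank_chisq <- function(times, events, g1) {
  ut <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & g1)
    O <- O + d1_j
    E <- E + d_j * n1_j / n_j
    if (n_j > 1)
      V <- V + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  (O - E)^2 / V
}

# permutation reference distribution for the two-group log-rank statistic
oracle_logrank_perm_p <- function(times, events, g1, n_perm, seed) {
  obs <- oracle_logrank_chisq(times, events, g1)
  set.seed(seed)
  hits <- 0
  for (r in seq_len(n_perm)) {
    gp <- sample(g1)
    if (oracle_logrank_chisq(times, events, gp) >= obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}

# Efron partial log-likelihood for a single covariate, evaluated on a beta
# grid; written directly from the likelihood.
oracle_cox_efron_loglik <- function(beta, times, events, x) {
  ut <- sort(unique(times[events == 1]))
  sapply(beta, function(b) {
    ll <- 0
    for (t in ut) {
      D <- which(times == t & events == 1)
      R <- which(times >= t)
      d <- length(D)
      sum_r <- sum(exp(b * x[R]))
      sum_d <- sum(exp(b * x[D]))
      ll <- ll + b * sum(x[D])
      for (l in seq_len(d) - 1)
        ll <- ll - log(sum_r - (l / d) * sum_d)
    }
    ll
  })
}

oracle_cox_grid_beta <- function(times, events, x, lo = -3, hi = 3, tol = 1e-5) {
  # coarse-to-fine grid maximization
  grid <- seq(lo, hi, length.out = 601)
  for (pass in 1:4) {
    ll <- oracle_cox_efron_loglik(grid, times, events, x)
    b <- grid[which.max(ll)]
    w <- (grid[2] - grid[1]) * 2
    grid <- seq(b - w, b + w, length.out = 401)
    if (grid[2] - grid[1] < tol / 4) break
  }
  b
}

# Jonckheere-Terpstra J and its exact permutation p-value by exhaustive
# enumeration of all assignments of values to ordered groups of the given
# sizes (feasible for sizes like {3,3,3}).
oracle_jt_J <- function(values, gi) {
  k <- max(gi); J <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    vi <- values[gi == i]; vj <- values[gi == j]
    J <- J + sum(outer(vi, vj, "<")) + 0.5 * sum(outer(vi, vj, "=="))
  }
  J
}

oracle_jt_exact_p <- function(values, sizes, alternative = "increasing") {
  n <- sum(sizes)
  obs <- oracle_jt_J(values, rep(seq_along(sizes), sizes))
  idx <- seq_len(n)
  Js <- c()
  g1s <- utils::combn(idx, sizes[1], simplify = FALSE)
  for (g1 in g1s) {
    rest <- setdiff(idx, g1)
    g2s <- utils::combn(rest, sizes[2], simplify = FALSE)
    for (g2 in g2s) {
      gi <- integer(n)
      gi[g1] <- 1; gi[g2] <- 2; gi[setdiff(rest, g2)] <- 3
      Js <- c(Js, oracle_jt_J(values, gi))
    }
  }
  switch(alternative,
         increasing = mean(Js >= obs - 1e-12),
         two.sided = {
           mu <- mean(Js)
           mean(abs(Js - mu) >= abs(obs - mu) - 1e-12)
         })
}

# hand product-limit estimate over (1 - d/r)
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1; out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    r <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / r)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# small random censored survival instance
random_surv_instance <- function(n, seed, event_prob = 0.7) {
  set.seed(seed)
  list(times = round(rexp(n, 0.05), 2) + 0.01,
       events = as.integer(runif(n) < event_prob),
       scores = round(rnorm(n), 3))
}

# cohort with a single planted SIRI step effect on the wide SIRI scale
# (median 1.96, IQR 1.28-3.14) where a 3.5 cutoff is admissible
planted_siri_cohort <- function(n, seed, loghr = log(2.5), cutoff = 3.5,
                                baseline = 0.012, censor = 0.005,
                                horizon = 60, siri_median = 1.96,
                                siri_iqr = c(1.28, 3.14)) {
  pars <- siri_lognormal_params(siri_median, siri_iqr)
  cc <- cohort_config(n_subjects = n, siri_log_median = pars$meanlog,
                      siri_log_sd = pars$sdlog, seed = seed)
  hz <- hazard_spec(baseline_rate = baseline,
                    threshold_effects = list(list(variable = "siri",
                                                  cutoff = cutoff,
                                                  direction = ">=",
                                                  loghr = loghr)),
    censor_horizon = horizon, random_censor_rate = censor)
  simulate_cohort(cc, hz)
}

# balanced high-information design for parameter-recovery checks: the SIRI
# median sits at the planted cutoff (so both arms are large) and censoring
# is light, keeping the log-HR standard error near 0.05 at n = 2000
hr_recovery_cohort <- function(n, seed, loghr = log(2))
  planted_siri_cohort(n, seed, loghr = loghr, baseline = 0.02,
                      censor = 0.002, horizon = 120,
                      siri_median = 3.5, siri_iqr = c(2.29, 5.61))
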