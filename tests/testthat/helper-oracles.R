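# Independent oracles used across the suite. Deliberately brute-force and
# self-contained: none of them share code with the implementation paths
# they check.

# Breslow-tie Cox partial log-likelihood for a single predictor.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(event == 1 & time == t)
    at_risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) -
      length(d) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Two-stage grid maximization of the Breslow partial likelihood over
# beta in [-5, 5], final resolution 1e-6.
grid_cox_beta <- function(time, event, x) {
  grid <- seq(-5, 5, by = 0.01)
  ll <- vapply(grid, breslow_loglik, numeric(1), time, event, x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-6)
  llf <- vapply(fine, breslow_loglik, numeric(1), time, event, x)
  fine[which.max(llf)]
}

# Mann-Whitney AUC by explicit pair enumeration (ties count one half).
pairwise_auc <- function(case_scores, control_scores) {
  wins <- 0
  for (a in case_scores) for (b in control_scores)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(case_scores) * length(control_scores))
}

# A tiny manifest + cohort for hand-checkable fixtures.
toy_manifest <- function() {
  predictor_manifest(c("group", "severity_M3", "prevalence_M3"),
                     c("binary", "ordinal", "binary"))
}

toy_cohort <- function(time, event, group = NULL, severity = NULL,
                       prevalence = NULL) {
  n <- length(time)
  severity <- severity %||% rep(2, n)
  cohort_table(
    data.frame(subject_id = sprintf("T%02d", seq_len(n)),
               time_months = time, event = event,
               group = group %||% rep(0:1, length.out = n),
               severity_M3 = severity,
               prevalence_M3 = prevalence %||% as.numeric(severity >= 1)),
    manifest = toy_manifest())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small synthetic cohorts for the expensive nested-validation tests.
small_generator <- function(seed, n = 30, events = 9,
                            missing_fraction = 0.06) {
  generator_config(n_subjects = n, target_events = events,
                   missing_fraction = missing_fraction,
                   true_betas = c(prevalence_M3 = 1.2, severity_M8 = 0.3),
                   seed = seed)
}
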