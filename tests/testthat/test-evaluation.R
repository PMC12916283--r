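# Time-resolved AUC and AIC risk stratification against brute-force
# oracles and null calibration.

fake_risk <- function(scores, strategy = "loocv") {
  structure(list(scores = data.frame(subject_id = seq_along(scores),
                                     score = scores,
                                     n_contributions = 1L),
                 strategy = strategy, seed = 1L),
            class = "out_of_sample_risk")
}

test_that("AUC endpoints: perfect ranking and all-ties", {
  times <- c(2, 4, 6, 10, 14, 20, 30, 40)
  events <- c(1, 1, 1, 0, 0, 0, 0, 0)
  perfect <- c(8, 7, 6, 5, 4, 3, 2, 1)
  expect_equal(cumulative_auc_at(perfect, times, events, 12), 1.0)
  expect_equal(cumulative_auc_at(rep(3, 8), times, events, 12), 0.5)
  expect_equal(cumulative_auc_at(-perfect, times, events, 12), 0.0)
})

test_that("AUC equals brute-force pair enumeration on censoring-free toys", {
  set.seed(51)
  for (rep in 1:10) {
    times <- sample(1:12, 8, replace = TRUE)
    events <- rep(1, 8)
    scores <- round(rnorm(8), 1)   # ties likely
    for (mo in c(3, 6, 9, 12)) {
      case <- times <= mo
      if (!any(case) || all(case)) next
      expect_equal(cumulative_auc_at(scores, times, events, mo),
                   pairwise_auc(scores[case], scores[!case]))
    }
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(52)
  times <- rexp(40, 0.05) + 0.5
  events <- rbinom(40, 1, 0.4)
  scores <- rnorm(40)
  for (mo in c(10, 20)) {
    base <- cumulative_auc_at(scores, times, events, mo)
    expect_equal(cumulative_auc_at(exp(2 * scores), times, events, mo), base)
    expect_equal(cumulative_auc_at(rank(scores), times, events, mo), base)
  }
})

test_that("undefined months return the NA marker, not an error", {
  times <- c(5, 10, 15); events <- c(0, 0, 1)
  expect_true(is.na(cumulative_auc_at(c(1, 2, 3), times, events, 2)))
  # no controls left beyond the last follow-up
  expect_true(is.na(cumulative_auc_at(c(1, 2, 3), times, events, 16)))
})

test_that("subjects censored before the month are excluded from the AUC", {
  times <- c(2, 3, 10, 12)
  events <- c(1, 0, 0, 0)
  scores <- c(5, 99, 1, 2)   # high score on the early-censored subject
  # subject 2 (censored at 3) must not count as a control at month 6
  expect_equal(cumulative_auc_at(scores, times, events, 6),
               pairwise_auc(5, c(1, 2)))
})

test_that("curve CIs bracket the point estimate and flag significance", {
  sim <- generate_cohort(generator_config(
    true_betas = c(prevalence_M3 = 2.5), missing_fraction = 0, seed = 61))
  risk <- fake_risk(predictor_matrix(sim$cohort)[, "prevalence_M3"] +
                      rnorm(105, 0, 0.1))
  curve <- auc_curve_with_ci(risk, sim$cohort, n_boot = 300, seed = 2)$curve
  ok <- !is.na(curve$auc) & !is.na(curve$ci_low)
  expect_true(any(ok))
  expect_true(all(curve$ci_low[ok] <= curve$auc[ok] + 1e-12))
  expect_true(all(curve$ci_high[ok] >= curve$auc[ok] - 1e-12))
  expect_true(all(curve$low_confidence == (curve$n_events < 3)))
  # a strong signal shows a significant stretch at established horizons
  expect_gt(sum(curve$significant[ok & curve$n_events >= 3]), 0)
})

test_that("null scores are calibrated: AUC near 0.5, few significant months", {
  means <- numeric(50); sig_rate <- numeric(50)
  for (s in 1:50) {
    cfg <- generator_config(true_betas = c(prevalence_M3 = 0),
                            missing_fraction = 0, seed = 300 + s)
    sim <- generate_cohort(cfg)
    risk <- fake_risk(with_seed_local <- local({set.seed(s); rnorm(105)}))
    curve <- auc_curve_with_ci(risk, sim$cohort, n_boot = 200,
                               seed = s)$curve
    ok <- !is.na(curve$auc) & curve$n_events >= 3
    means[s] <- mean(curve$auc[ok])
    sig_rate[s] <- mean(curve$significant[ok])
  }
  expect_lt(abs(mean(means) - 0.5), 0.05)
  expect_lte(mean(sig_rate), 0.10)
})

test_that("AIC split matches exhaustive enumeration and separates top-k", {
  set.seed(71)
  n <- 40
  times <- rexp(n, 0.05) + 0.5
  scores <- sort(rnorm(n))                 # distinct, increasing
  events <- as.numeric(seq_len(n) > n - 8) # events are the top-8 scorers
  split <- aic_threshold_split(scores, times, events, min_group = 5)

  # exhaustive oracle over every admissible midpoint
  s <- sort(unique(scores)); mids <- (s[-1] + s[-length(s)]) / 2
  mids <- mids[vapply(mids, function(th)
    sum(scores > th) >= 5 && sum(scores <= th) >= 5, logical(1))]
  aics <- vapply(mids, function(th) {
    hi <- as.numeric(scores > th)
    fit <- suppressWarnings(   # separated strata converge to finite loglik
      survival::coxph(survival::Surv(times, events) ~ hi, ties = "breslow"))
    2 - 2 * fit$loglik[2]
  }, numeric(1))
  expect_equal(split$threshold, mids[which.min(aics)])
  expect_equal(split$aic, min(aics))
  expect_equal(nrow(split$profile), length(mids))
  # events all sit in the returned high group
  expect_true(all(split$group[events == 1] == "high"))
})

test_that("AIC split depends on scores only through ranks", {
  set.seed(72)
  n <- 30
  times <- rexp(n, 0.08) + 0.5
  events <- rbinom(n, 1, 0.3); events[1:2] <- 1
  scores <- rnorm(n)
  a <- aic_threshold_split(scores, times, events)
  b <- aic_threshold_split(plogis(3 * scores), times, events)
  expect_identical(a$group, b$group)
  expect_equal(a$aic, b$aic)
})

test_that("risk-group KM curves order as discrimination predicts", {
  sim <- generate_cohort(generator_config(
    true_betas = c(prevalence_M3 = 2.0, severity_M8 = 0.4),
    missing_fraction = 0, seed = 73))
  truthy <- generate_cohort(generator_config(
    true_betas = c(prevalence_M3 = 2.0, severity_M8 = 0.4),
    missing_fraction = 0, seed = 73))$truth
  split <- aic_threshold_split(truthy$linear_predictor,
                               sim$cohort$time_months, sim$cohort$event)
  last <- max(sim$cohort$time_months[sim$cohort$event == 1])
  expect_gte(cumulative_risk_at(split$km$high, last),
             cumulative_risk_at(split$km$low, last))
  expect_error(aic_threshold_split(rep(1, 105), sim$cohort$time_months,
                                   sim$cohort$event),
               "no split possible")
})
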