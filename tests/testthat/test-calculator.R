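# The published four-item risk calculator: score arithmetic, cutoff
# convention, linearity/monotonicity, and the horizon-probability mapping.

test_that("each published coefficient is reproduced in isolation", {
  model <- calculator_model()
  expect_equal(score_profile(calculator_profile(1, 0, 0, 0), model), 0.833)
  expect_equal(score_profile(calculator_profile(0, 1, 0, 0), model), 0.079)
  expect_equal(score_profile(calculator_profile(0, 0, 1, 0), model), 0.030)
  expect_equal(score_profile(calculator_profile(0, 0, 0, 1), model), 0.035)
  expect_equal(score_profile(calculator_profile(0, 0, 0, 0), model), 0)
  expect_equal(score_profile(calculator_profile(1, 1, 6, 6), model),
               0.833 + 0.079 + 6 * 0.030 + 6 * 0.035)
})

test_that("profiles validate their ranges", {
  expect_error(calculator_profile(2, 0, 0, 0), "0/1")
  expect_error(calculator_profile(1, 0, 7, 0), "0-6")
  expect_error(calculator_profile(NA, 0, 1, 0), "missing")
})

test_that("risk classification uses a strict cutoff at 0.172", {
  model <- calculator_model()
  expect_equal(classify_risk(0, model), "low")
  expect_equal(classify_risk(0.172, model), "low")     # boundary convention
  expect_equal(classify_risk(0.1720001, model), "high")
  expect_equal(classify_risk(0.833, model), "high")
  expect_equal(classify_risk(c(0.05, 0.9), model), c("low", "high"))
})

test_that("the score is linear over disjoint-support profiles", {
  model <- calculator_model()
  p1 <- calculator_profile(1, 0, 3, 0)
  p2 <- calculator_profile(0, 1, 0, 2)
  sum12 <- calculator_profile(1, 1, 3, 2)
  expect_equal(score_profile(p1, model) + score_profile(p2, model),
               score_profile(sum12, model))
})

test_that("raising any profile entry never lowers the risk class", {
  model <- calculator_model()
  base <- expand.grid(m3 = 0:1, m6 = 0:1, m5 = c(0, 3), m8 = c(0, 3))
  for (r in seq_len(nrow(base))) {
    p <- base[r, ]
    s0 <- score_profile(calculator_profile(p$m3, p$m6, p$m5, p$m8), model)
    for (bump in list(c(1, 0, 0, 0), c(0, 0, 3, 0))) {
      q <- pmin(unlist(p) + bump, c(1, 1, 6, 6))
      s1 <- score_profile(calculator_profile(q[1], q[2], q[3], q[4]), model)
      expect_gte(s1, s0)
      expect_false(classify_risk(s0, model) == "high" &&
                     classify_risk(s1, model) == "low")
    }
  }
})

test_that("horizon mapping is finite at zero and monotone in the score", {
  set.seed(81)
  n <- 200
  scores <- c(rep(0, 40), runif(160, 0, 1.3))
  lp <- 2.5 * scores - 2
  times <- rexp(n, 0.02 * exp(lp))
  events <- as.numeric(times <= 40); times <- pmin(times, 40) + 1e-6
  model <- fit_horizon_mapping(calculator_model(), scores, times, events)
  expect_gte(model$logistic$slope, 0)
  p0 <- probability_at_horizon(0, model)
  expect_true(is.finite(p0) && p0 > 0 && p0 < 1)
  grid <- seq(0, 1.3, by = 0.01)
  probs <- probability_at_horizon(grid, model)
  expect_true(all(diff(probs) >= -1e-12))
  expect_true(all(probs > 0 & probs < 1))
  # unfitted model refuses to map
  expect_error(probability_at_horizon(0.5, calculator_model()),
               "not fitted")
})

test_that("fitted curve recovers a known 20-month event fraction", {
  set.seed(82)
  n <- 600
  scores <- runif(n, 0, 1.2)
  # true 20-month event probability rises smoothly with the score and
  # passes 0.2 at score 0.35
  p_true <- plogis(qlogis(0.2) + 4 * (scores - 0.35))
  events <- rbinom(n, 1, p_true)
  times <- ifelse(events == 1, runif(n, 0.5, 19.5), 60)
  model <- fit_horizon_mapping(calculator_model(), scores, times, events)
  expect_lt(abs(probability_at_horizon(0.35, model) - 0.2), 0.1)
})

test_that("subjects with undeterminable 20-month status are excluded", {
  scores <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3)
  times <- c(5, 10, 15, 10, 25, 30)   # subject 4 censored before 20 months
  events <- c(1, 1, 1, 0, 0, 0)
  model <- suppressWarnings(
    fit_horizon_mapping(calculator_model(), scores, times, events))
  expect_equal(model$logistic$n, 5)
  expect_equal(model$logistic$n_events, 3)
  expect_error(fit_horizon_mapping(calculator_model(), scores[4:6],
                                   times[4:6], events[4:6]),
               "fewer than 3 events")
})

test_that("batch scoring matches per-profile scoring", {
  sim <- generate_cohort(generator_config(missing_fraction = 0, seed = 83))
  model <- calculator_model()
  tab <- score_cohort(sim$cohort, model)
  i <- 5
  p <- calculator_profile(sim$cohort$prevalence_M3[i],
                          sim$cohort$prevalence_M6[i],
                          sim$cohort$severity_M5[i],
                          sim$cohort$severity_M8[i])
  expect_equal(tab$score[i], score_profile(p, model))
  expect_equal(tab$risk_group, classify_risk(tab$score, model))
})

test_that("relevance table is sorted and consistent with the definition", {
  fit <- structure(list(family = "cox", lambda = 0.1,
                        coefficients = c(a = 0.9, b = -0.1, c = 0),
                        coefficients_raw = c(a = 1.8, b = -0.2, c = 0)),
                   class = "lasso_fit")
  tab <- relevance_table(fit)
  expect_equal(tab$name, c("a", "b"))
  expect_equal(tab$relevance, c(0.9, 0.1))
  expect_equal(tab$beta_raw, c(1.8, -0.2))
  single <- structure(list(family = "cox", lambda = 0.1,
                           coefficients = c(a = 0.4),
                           coefficients_raw = c(a = 0.4)),
                      class = "lasso_fit")
  expect_equal(relevance_table(single)$relevance, 1.0)
})
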