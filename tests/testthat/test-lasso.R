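# Penalized-regression engines: closed-form and unpenalized oracles, KKT
# optimality, penalty selection, and the relevance metric.

make_orthonormal <- function(n, p, seed) {
  set.seed(seed)
  x0 <- matrix(rnorm(n * p), n, p)
  x0 <- sweep(x0, 2, colMeans(x0))
  q <- qr.Q(qr(x0)) * sqrt(n)   # columns: mean 0, population SD 1, X'X = nI
  colnames(q) <- paste0("v", seq_len(p))
  q
}

test_that("standardization is exact and invertible", {
  set.seed(1)
  x <- cbind(a = rnorm(50, 10, 3), b = runif(50), c = rep(2, 50))
  expect_message(d <- standardize_design(x), "zero-variance")
  expect_equal(d$dropped, "c")
  expect_equal(colMeans(d$x), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(colMeans(d$x^2), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(unstandardize_design(d), x[, c("a", "b")],
               tolerance = 1e-12)
  expect_error(standardize_design(cbind(a = c(1, NA))), "missing")
})

test_that("gaussian lasso equals soft-thresholding on orthonormal designs", {
  q <- make_orthonormal(64, 5, seed = 2)
  set.seed(3)
  y <- drop(q %*% c(1, -0.5, 0.25, 0, 0)) + rnorm(64, sd = 0.5)
  d <- standardize_design(q)
  ols <- drop(crossprod(d$x, y - mean(y))) / 64
  for (lam in c(0.02, 0.1, 0.4)) {
    fit <- fit_lasso(d, y, lam, "gaussian")
    oracle <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_equal(unname(fit$coefficients[colnames(q)]), unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("lambda at or above lambda_max zeroes every coefficient", {
  set.seed(4)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- x[, 1] + rnorm(50)
  d <- standardize_design(x)
  lmax <- max(abs(crossprod(d$x, y - mean(y)))) / 50
  fit <- fit_lasso(d, y, lmax * 1.001, "gaussian")
  expect_true(all(fit$coefficients == 0))
  expect_length(fit$active, 0)
})

test_that("cox lasso at lambda 0 matches the unpenalized Newton oracle", {
  set.seed(5)
  x <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "z"))
  time <- rexp(60, exp(0.6 * x[, 1]))
  event <- rbinom(60, 1, 0.7)
  d <- standardize_design(x)
  fit <- fit_lasso(d, survival::Surv(time, event), 0, "cox")
  cph <- survival::coxph(survival::Surv(time, event) ~ x[, 1],
                         ties = "breslow")
  expect_equal(unname(fit$coefficients_raw["z"]), unname(coef(cph)),
               tolerance = 1e-4)
})

test_that("KKT conditions hold at returned solutions for every family", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 80; p <- 6
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    d <- standardize_design(x)
    eta <- drop(d$x %*% c(1, -0.8, 0.5, 0, 0, 0))
    lam <- runif(1, 0.02, 0.2)

    yg <- eta + rnorm(n)
    expect_lt(kkt_violation(fit_lasso(d, yg, lam, "gaussian"), d, yg), 1e-6)
    yb <- rbinom(n, 1, plogis(eta))
    expect_lt(kkt_violation(fit_lasso(d, yb, lam, "binomial"), d, yb), 1e-6)
    ys <- survival::Surv(rexp(n, exp(eta)), rbinom(n, 1, 0.8))
    expect_lt(kkt_violation(fit_lasso(d, ys, lam, "cox"), d, ys), 1e-6)
  }
})

test_that("in-sample deviance is non-increasing along the path", {
  set.seed(7)
  x <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- x[, 1] - x[, 2] + rnorm(100)
  d <- standardize_design(x)
  lams <- exp(seq(log(0.5), log(0.005), length.out = 12))
  rss <- vapply(lams, function(l) {
    f <- fit_lasso(d, y, l, "gaussian")
    sum((y - (f$intercept + drop(d$x %*% f$coefficients)))^2)
  }, numeric(1))
  expect_true(all(diff(rss) < 1e-8))
})

test_that("penalty selection is seeded and deterministic", {
  set.seed(8)
  x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 1.5 * x[, 1] + rnorm(100)
  d <- standardize_design(x)
  p1 <- select_lambda(d, y, "gaussian", seed = 99)
  p2 <- select_lambda(d, y, "gaussian", seed = 99)
  expect_identical(p1$lambda, p2$lambda)
  expect_equal(p1$rule, "min")
  expect_true("x1" %in% p1$fit$active)
})

test_that("fold count shrinks with a warning when cox events are scarce", {
  set.seed(9)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("x", 1:5)))
  time <- rexp(40); event <- c(rep(1, 5), rep(0, 35))
  d <- standardize_design(x)
  expect_warning(
    p <- select_lambda(d, survival::Surv(time, event), "cox", seed = 1),
    "reduced folds")
})

test_that("strong signals are selected; pure noise is not", {
  # strong single signal, cox family via the generator
  hits <- 0; runs <- 15
  for (s in seq_len(runs)) {
    cfg <- generator_config(n_subjects = 300, target_events = 100,
                            true_betas = c(severity_M5 = 2),
                            missing_fraction = 0, seed = 100 + s)
    sim <- generate_cohort(cfg)
    d <- suppressMessages(standardize_design(predictor_matrix(sim$cohort)))
    y <- survival::Surv(sim$cohort$time_months, sim$cohort$event)
    path <- select_lambda(d, y, "cox", seed = s)
    hits <- hits + ("severity_M5" %in% path$fit$active)
  }
  expect_gte(hits / runs, 0.95)

  # pure noise: the conservative selection rule returns an empty or
  # near-empty model in nearly every run (the prediction-oriented min rule
  # keeps spurious noise predictors too often to make that guarantee)
  near_empty <- 0; runs <- 40
  for (s in seq_len(runs)) {
    set.seed(1000 + s)
    x <- matrix(rnorm(100 * 15), 100, 15,
                dimnames = list(NULL, paste0("n", 1:15)))
    y <- rnorm(100)
    path <- select_lambda(standardize_design(x), y, "gaussian", seed = s,
                          rule = "1se")
    near_empty <- near_empty + (length(path$fit$active) <= 1)
  }
  expect_gte(near_empty / runs, 0.80)
})

test_that("relevance follows its definition and normalizes", {
  fit <- structure(list(family = "gaussian", lambda = 0.1,
                        coefficients = c(a = 2, b = 1, c = -1, d = 0)),
                   class = "lasso_fit")
  rel <- compute_relevance(fit)
  expect_equal(unname(rel), c(0.50, 0.25, 0.25))
  expect_equal(sum(rel), 1, tolerance = 1e-12)
  # negation leaves relevance unchanged; single coefficient normalizes to 1
  fit$coefficients <- c(a = -2, b = 1, c = 1, d = 0)
  expect_equal(compute_relevance(fit), rel)
  fit$coefficients <- c(a = 0.3, b = 0)
  expect_equal(unname(compute_relevance(fit)), 1)
  fit$coefficients <- c(a = 0, b = 0)
  expect_error(compute_relevance(fit), "no predictors selected")
})

test_that("relevances normalize on genuinely fitted models", {
  set.seed(10)
  x <- matrix(rnorm(400), 80, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(80)
  fit <- fit_lasso(standardize_design(x), y, 0.05, "gaussian")
  rel <- compute_relevance(fit)
  expect_true(all(rel >= 0))
  expect_equal(sum(rel), 1, tolerance = 1e-12)
})
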