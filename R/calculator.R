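# The published four-item BSD risk calculator: a linear score over two
# prevalence flags and two severity ratings, a fixed high/low cutoff, and a
# logistic mapping of the score to a 20-month onset probability. Only the
# linear coefficients and the cutoff are published; the logistic intercept
# and slope are refit on whatever cohort is supplied.

#' The published BSD risk-calculator model
#'
#' Linear score
#' `0.833 * prevalence_M3 + 0.079 * prevalence_M6 +
#'  0.030 * severity_M5 + 0.035 * severity_M8`
#' (M3 inflated self-esteem/grandiosity, M6 racing thoughts, M5
#' overtalkativeness, M8 increased energy), with high- vs low-risk cutoff
#' 0.172. The probability mapping uses `log(score + epsilon)` with
#' `epsilon = 1e-16` (the score can be exactly zero) as the predictor of
#' observed onset status at the 20-month horizon.
#'
#' @param coefficients named non-negative coefficients of the linear score.
#' @param cutoff high/low risk cutoff on the score scale.
#' @param epsilon offset added to the score before taking logs.
#' @param horizon_months horizon of the probability mapping.
#' @return an object of class `calculator_model`.
#' @export
calculator_model <- function(coefficients = c(prevalence_M3 = 0.833,
                                              prevalence_M6 = 0.079,
                                              severity_M5 = 0.030,
                                              severity_M8 = 0.035),
                             cutoff = 0.172, epsilon = 1e-16,
                             horizon_months = 20) {
  stopifnot(all(coefficients >= 0), cutoff > 0, epsilon > 0,
            horizon_months > 0)
  structure(list(coefficients = coefficients, cutoff = cutoff,
                 epsilon = epsilon, horizon_months = horizon_months,
                 logistic = NULL),
            class = "calculator_model")
}

#' @export
print.calculator_model <- function(x, ...) {
  terms <- paste(sprintf("%.3f*%s", x$coefficients, names(x$coefficients)),
                 collapse = " + ")
  cat(sprintf("<calculator_model> score = %s; cutoff %.3f%s\n", terms,
              x$cutoff,
              if (is.null(x$logistic)) "" else
                sprintf("; %g-month mapping fitted", x$horizon_months)))
  invisible(x)
}

#' A four-item calculator profile
#'
#' @param prevalence_M3 inflated self-esteem/grandiosity present (0/1).
#' @param prevalence_M6 racing thoughts present (0/1).
#' @param severity_M5 overtalkativeness severity (ordinal 0-6).
#' @param severity_M8 increased-energy severity (ordinal 0-6).
#' @return an object of class `calculator_profile`. No missing entries are
#'   accepted at scoring time.
#' @export
calculator_profile <- function(prevalence_M3, prevalence_M6, severity_M5,
                               severity_M8) {
  vals <- c(prevalence_M3 = unname(prevalence_M3),
            prevalence_M6 = unname(prevalence_M6),
            severity_M5 = unname(severity_M5),
            severity_M8 = unname(severity_M8))
  if (anyNA(vals)) stopf("calculator profiles accept no missing entries")
  if (!all(vals[c("prevalence_M3", "prevalence_M6")] %in% c(0, 1)))
    stopf("prevalence entries must be 0/1")
  for (nm in c("severity_M5", "severity_M8"))
    if (vals[nm] < 0 || vals[nm] > 6)
      stopf("%s out of the 0-6 severity range", nm)
  structure(as.list(vals), class = "calculator_profile")
}

#' Linear risk score of a profile
#'
#' Dot product of the profile with the published coefficients; deterministic
#' and linear, so disjoint-support profiles add.
#'
#' @param profile a [calculator_profile()].
#' @param model a [calculator_model()].
#' @return the non-negative score.
#' @export
score_profile <- function(profile, model = calculator_model()) {
  stopifnot(inherits(profile, "calculator_profile"),
            inherits(model, "calculator_model"))
  sum(model$coefficients * unlist(profile[names(model$coefficients)]))
}

#' Classify a score as low or high risk
#'
#' High risk iff the score strictly exceeds the cutoff; a score exactly at
#' the cutoff is classified low (documented boundary convention).
#'
#' @param score non-negative score(s).
#' @param model a [calculator_model()].
#' @return character vector of `"low"` / `"high"`.
#' @export
classify_risk <- function(score, model = calculator_model()) {
  stopifnot(all(score >= 0))
  ifelse(score > model$cutoff, "high", "low")
}

#' Fit the 20-month probability mapping
#'
#' Logistic regression of observed onset status at the model's horizon on
#' `log(score + epsilon)`, fitted on subjects whose status at the horizon is
#' determinable: cases are onsets by the horizon and controls are subjects
#' followed event-free to at least the horizon; subjects censored earlier
#' without an event are excluded.
#'
#' @param model a [calculator_model()].
#' @param scores per-subject risk scores (typically out-of-sample).
#' @param times,events outcome vectors aligned with `scores`.
#' @return the model with `logistic` (intercept, slope, n, n_events)
#'   filled in.
#' @export
fit_horizon_mapping <- function(model, scores, times, events) {
  if (inherits(scores, "out_of_sample_risk")) scores <- scores$scores$score
  if (any(scores < 0, na.rm = TRUE))
    stopf(paste("horizon mapping needs non-negative risk scores;",
                "map linear predictors through exp() first"))
  h <- model$horizon_months
  status <- ifelse(events == 1 & times <= h, 1,
                   ifelse(times >= h, 0, NA))
  keep <- !is.na(status) & !is.na(scores)
  if (sum(status[keep]) < 3)
    stopf("fewer than 3 events at the %g-month horizon", h)
  fit <- stats::glm(status[keep] ~ log(scores[keep] + model$epsilon),
                    family = stats::binomial())
  model$logistic <- list(intercept = unname(stats::coef(fit)[1]),
                         slope = unname(stats::coef(fit)[2]),
                         n = sum(keep), n_events = sum(status[keep]))
  model
}

#' Probability of onset within the horizon
#'
#' `plogis(a + b * log(score + epsilon))` with the fitted mapping; bounded
#' in (0, 1), finite at score 0 thanks to the epsilon offset, and monotone
#' non-decreasing in the score whenever the fitted slope is non-negative.
#'
#' @param score non-negative score(s).
#' @param model a [calculator_model()] with a fitted mapping (see
#'   [fit_horizon_mapping()]).
#' @return probabilities in (0, 1).
#' @export
probability_at_horizon <- function(score, model) {
  if (is.null(model$logistic))
    stopf("probability mapping not fitted; call fit_horizon_mapping() first")
  stopifnot(all(score >= 0))
  stats::plogis(model$logistic$intercept +
                  model$logistic$slope * log(score + model$epsilon))
}

#' Score a cohort with the calculator
#'
#' Batch version of [score_profile()]: reads the four calculator columns
#' from a cohort table, adds `score`, `risk_group`, and (when the mapping
#' is fitted) `probability_20m`.
#'
#' @param cohort a `cohort_table` (the four calculator columns must be
#'   observed).
#' @param model a [calculator_model()].
#' @return a `data.frame` of subject_id, score, risk_group and optionally
#'   probability at horizon.
#' @export
score_cohort <- function(cohort, model = calculator_model()) {
  cols <- names(model$coefficients)
  absent <- setdiff(cols, names(cohort))
  if (length(absent))
    stopf("cohort lacks calculator column(s): %s",
          paste(absent, collapse = ", "))
  x <- as.matrix(as.data.frame(cohort)[, cols, drop = FALSE])
  if (anyNA(x))
    stopf("calculator inputs contain missing values; impute or drop first")
  score <- drop(x %*% model$coefficients)
  out <- data.frame(subject_id = cohort$subject_id, score = score,
                    risk_group = classify_risk(score, model),
                    stringsAsFactors = FALSE)
  if (!is.null(model$logistic))
    out[[sprintf("probability_%gm", model$horizon_months)]] <-
      probability_at_horizon(score, model)
  out
}

#' Table of selected predictors, coefficients and relevance
#'
#' The model-card table of a fitted lasso model: one row per active
#' predictor with its standardized and original-scale coefficient and its
#' relevance (see [compute_relevance()]), sorted by descending relevance.
#'
#' @param fit a `lasso_fit` or `final_model` with a nonempty active set.
#' @return a `data.frame` with columns `name`, `beta_std`, `beta_raw`,
#'   `relevance`.
#' @export
relevance_table <- function(fit) {
  stopifnot(inherits(fit, c("lasso_fit", "final_model")))
  b_std <- fit$coefficients
  b_raw <- fit$coefficients_raw
  active <- b_std != 0
  if (!any(active)) stopf("no predictors selected")
  rel <- abs(b_std[active]) / sum(abs(b_std[active]))
  out <- data.frame(name = names(b_std)[active],
                    beta_std = unname(b_std[active]),
                    beta_raw = unname(b_raw[active]),
                    relevance = unname(rel),
                    stringsAsFactors = FALSE)
  out[order(-out$relevance), , drop = FALSE]
}
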