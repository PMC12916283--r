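# Synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes -- a small hospitalized-adolescent cohort followed for up
# to five years, with correlated ordinal symptom ratings, exponential
# proportional-hazards event times, independent exponential dropout,
# administrative censoring at the horizon, and missing predictor values --
# so that every downstream stage can be exercised against known ground truth.

# Baseline marginals the generator targets: item severity means/SDs for the
# 31 BPSS-FP items and prevalences of the demographic/diagnosis/medication
# flags, loosely matched to a published adolescent inpatient sample.
bpss_item_targets <- function() {
  data.frame(
    code = bpss_item_codes(),
    mean = c(1.5, 3.8, 0.7, 0.7, 1.6, 1.6, 3.0, 0.9, 3.8, 3.2,
             4.8, 3.9, 1.7, 1.7, 3.1, 1.7, 2.0, 3.5, 3.8, 3.2, 1.8, 4.3,
             3.2, 2.5, 3.2, 3.6, 2.8, 1.0, 1.4, 0.9, 0.4),
    sd   = c(1.7, 1.4, 1.2, 1.5, 1.9, 2.0, 2.0, 1.3, 1.7, 1.9,
             1.4, 1.8, 2.1, 2.1, 2.1, 2.1, 2.0, 2.0, 1.9, 2.0, 1.7, 2.2,
             2.1, 1.9, 1.9, 2.0, 2.4, 1.6, 2.0, 1.5, 0.9),
    stringsAsFactors = FALSE
  )
}

flag_prevalences <- function() {
  c(sex_male = 0.276,
    race_black = 0.202, race_mixed = 0.152, race_asian_pacific = 0.091,
    race_other = 0.010,
    depressive_disorders = 0.819, persistent_depressive_disorder = 0.114,
    trauma_stressor_disorders = 0.143, personality_disorder_traits = 0.181,
    anxiety_disorders = 0.448, disruptive_behavior_disorders = 0.410,
    adhd = 0.295, substance_use_disorders = 0.124,
    attenuated_psychosis_syndrome = 0.257, eating_disorders = 0.067,
    antipsychotics = 0.619, antidepressants = 0.600,
    mood_stabilizers = 0.362, lithium = 0.286, anxiolytics = 0.229,
    adhd_medications = 0.124)
}

scale_targets <- function() {
  data.frame(
    name = c("madrs_total", "cgi_s", "gaf_current", "gaf_high", "gaf_low",
             "ymrs_total"),
    mean = c(26.5, 4.2, 28.3, 56.6, 23.9, 11.9),
    sd = c(15.1, 1.0, 15.7, 14.1, 14.7, 10.5),
    lo = c(0, 1, 1, 1, 1, 0),
    hi = c(60, 7, 100, 100, 100, 60),
    stringsAsFactors = FALSE
  )
}

#' Generator configuration
#'
#' Defines the study conditions the synthetic cohort emulates. Defaults
#' describe a cohort of 105 adolescents followed for up to 60 months with an
#' expected 18 bipolar-spectrum disorder onsets, 72.4% females, a true risk
#' signal carried by four (hypo)mania-like symptom items, exponential
#' dropout, and 10% of predictor cells missing completely at random.
#'
#' @param n_subjects cohort size (default 105).
#' @param target_events expected number of onsets the baseline hazard is
#'   calibrated to (default 18).
#' @param horizon_months administrative censoring horizon (default 60).
#' @param true_betas named numeric vector of log-hazard-ratio effects on the
#'   predictor columns; unnamed predictors have no effect. Defaults to the
#'   four-item signal `prevalence_M3` 0.833, `prevalence_M6` 0.079,
#'   `severity_M5` 0.030, `severity_M8` 0.035.
#' @param baseline_hazard constant baseline hazard per month; `NULL`
#'   (default) calibrates it to `target_events` by bisection.
#' @param dropout_rate exponential loss-to-follow-up rate per month
#'   (default 0.04, i.e. a 25-month mean time to dropout).
#' @param missing_fraction fraction of predictor cells set missing
#'   (default 0.1).
#' @param missingness `"mcar"` (default) or `"mar"`; under `"mar"` the
#'   missingness probability increases with illness severity (CGI-S).
#' @param item_correlation latent-factor loading shared by the mania items
#'   (default 0.4).
#' @param female_fraction fraction of females (default 0.724).
#' @param seed integer seed; the generator is bit-reproducible given a seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 105,
                             target_events = 18,
                             horizon_months = 60,
                             true_betas = c(prevalence_M3 = 0.833,
                                            prevalence_M6 = 0.079,
                                            severity_M5 = 0.030,
                                            severity_M8 = 0.035),
                             baseline_hazard = NULL,
                             dropout_rate = 0.04,
                             missing_fraction = 0.1,
                             missingness = c("mcar", "mar"),
                             item_correlation = 0.4,
                             female_fraction = 0.724,
                             seed = 1L) {
  missingness <- match.arg(missingness)
  if (n_subjects < 2) stopf("n_subjects must be >= 2")
  if (target_events <= 0 || target_events > n_subjects)
    stopf("target_events must be in (0, n_subjects]")
  if (horizon_months <= 0 || dropout_rate <= 0)
    stopf("horizon_months and dropout_rate must be > 0")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stopf("missing_fraction must be in [0, 1)")
  if (item_correlation < 0 || item_correlation >= 1)
    stopf("item_correlation must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 target_events = target_events,
                 horizon_months = horizon_months,
                 true_betas = true_betas,
                 baseline_hazard = baseline_hazard,
                 dropout_rate = dropout_rate,
                 missing_fraction = missing_fraction,
                 missingness = missingness,
                 item_correlation = item_correlation,
                 female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Draw the complete (pre-missingness) predictor block for n subjects.
draw_predictors <- function(config, n) {
  manifest <- default_manifest()
  items <- bpss_item_targets()
  flags <- flag_prevalences()
  scales <- scale_targets()

  out <- data.frame(age_years = pmin(pmax(stats::rnorm(n, 15.4, 1.3), 12), 18))
  # race one-hots drawn from a single categorical so at most one is set
  race_p <- flags[c("race_black", "race_mixed", "race_asian_pacific",
                    "race_other")]
  race <- apply(stats::rmultinom(n, 1, c(1 - sum(race_p), race_p)), 2,
                which.max)
  out$sex_male <- stats::rbinom(n, 1, flags["sex_male"])
  out$race_black <- as.integer(race == 2)
  out$race_mixed <- as.integer(race == 3)
  out$race_asian_pacific <- as.integer(race == 4)
  out$race_other <- as.integer(race == 5)
  for (nm in setdiff(names(flags), c("sex_male", "race_black", "race_mixed",
                                     "race_asian_pacific", "race_other")))
    out[[nm]] <- stats::rbinom(n, 1, flags[nm])
  for (i in seq_len(nrow(scales)))
    out[[scales$name[i]]] <-
      pmin(pmax(stats::rnorm(n, scales$mean[i], scales$sd[i]),
                scales$lo[i]), scales$hi[i])

  # latent-Gaussian factor model for item severities: mania items share a
  # common factor with loading sqrt(item_correlation); the ordinal 0-6 scale
  # comes from rounding-and-clamping the location-scale latent variable
  rho <- config$item_correlation
  mania_factor <- stats::rnorm(n)
  for (i in seq_len(nrow(items))) {
    code <- items$code[i]
    z <- if (startsWith(code, "M"))
      sqrt(rho) * mania_factor + sqrt(1 - rho) * stats::rnorm(n)
    else stats::rnorm(n)
    sev <- pmin(pmax(round(items$mean[i] + items$sd[i] * z), 0), 6)
    out[[paste0("severity_", code)]] <- sev
    # prevalence tracks severity >= 2 with a little interview noise, while
    # respecting the rule that a flagged symptom has severity >= 1
    p <- ifelse(sev >= 2, 0.95, ifelse(sev == 1, 0.10, 0))
    out[[paste0("prevalence_", code)]] <- stats::rbinom(n, 1, p)
  }
  out[, manifest$name]
}

linear_predictor <- function(predictors, true_betas) {
  lp <- numeric(nrow(predictors))
  if (length(true_betas)) {
    unknown <- setdiff(names(true_betas), names(predictors))
    if (length(unknown))
      stopf("true_betas name unknown predictor(s): %s",
            paste(unknown, collapse = ", "))
    for (nm in names(true_betas))
      lp <- lp + true_betas[[nm]] * predictors[[nm]]
  }
  lp
}

# Probability a subject with linear predictor lp has the event before both
# dropout and the administrative horizon, under competing exponentials.
event_probability <- function(lp, h0, dropout, horizon) {
  le <- h0 * exp(lp)
  tot <- le + dropout
  le / tot * (1 - exp(-tot * horizon))
}

#' Calibrate the generator's baseline hazard
#'
#' Finds the constant per-month baseline hazard at which the expected number
#' of observed onsets -- under competing exponential event and dropout times
#' and administrative censoring at the horizon -- matches
#' `config$target_events`. The expectation is taken over a seeded Monte-Carlo
#' sample of covariate draws (the per-subject probability itself is closed
#' form), and the hazard is found by bisection to within 0.1% of the target.
#'
#' @param config a [generator_config()].
#' @param n_mc Monte-Carlo sample size for the covariate draw (default 4000).
#' @return the calibrated baseline hazard (per month).
#' @export
calibrate_baseline_hazard <- function(config, n_mc = 4000) {
  preds <- with_seed(derive_seed(config$seed, "calibrate"),
                     draw_predictors(config, n_mc))
  lp <- linear_predictor(preds, config$true_betas)
  expected <- function(h0)
    config$n_subjects * mean(event_probability(lp, h0, config$dropout_rate,
                                               config$horizon_months))
  target <- config$target_events
  lo <- 1e-10; hi <- 1e-4
  while (expected(hi) < target && hi < 1e6) hi <- hi * 10
  if (expected(hi) < target * 0.95)
    stopf("target_events unreachable: dropout removes subjects too fast")
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (expected(mid) < target) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-6) break
  }
  mid <- sqrt(lo * hi)
  if (abs(expected(mid) - target) > 0.05 * target)
    stopf("baseline-hazard calibration failed to reach the target")
  mid
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws baseline predictors (correlated ordinal symptom items, binary
#' flags, scale totals), event times from an exponential
#' proportional-hazards model with linear predictor
#' `sum(true_betas * x)`, independent exponential dropout, administrative
#' censoring at the horizon, and missingness injected at
#' `config$missing_fraction`. Bit-reproducible given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return a list with elements `cohort` (a [cohort_table()]) and `truth`
#'   (a `data.frame` of per-subject true linear predictor, true event time
#'   and true censoring time, with the generating betas and baseline hazard
#'   as attributes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  h0 <- config$baseline_hazard %||% calibrate_baseline_hazard(config)
  n <- config$n_subjects

  with_seed(derive_seed(config$seed, "cohort"), {
    preds <- draw_predictors(config, n)
    lp <- linear_predictor(preds, config$true_betas)
    t_event <- stats::rexp(n, rate = h0 * exp(lp))
    t_censor <- stats::rexp(n, rate = config$dropout_rate)
    time_obs <- pmin(t_event, t_censor, config$horizon_months)
    event <- as.integer(t_event <= pmin(t_censor, config$horizon_months))
    # guard against zero-length follow-up from the continuous draw
    time_obs <- pmax(time_obs, 1e-6)

    expected_events <- n * mean(event_probability(
      lp, h0, config$dropout_rate, config$horizon_months))
    refused <- FALSE
    if (expected_events < 2) {
      warnf("configuration yields expected events < 2 (%.2f)",
            expected_events)
      refused <- TRUE
    }

    if (config$missing_fraction > 0) {
      p_miss <- if (config$missingness == "mcar") {
        matrix(config$missing_fraction, n, ncol(preds))
      } else {
        # missing-at-random: odds scale with centred illness severity, with
        # the marginal rate held at missing_fraction
        sev <- preds$cgi_s - mean(preds$cgi_s)
        eta <- stats::qlogis(config$missing_fraction) + 0.8 * sev
        matrix(stats::plogis(eta), n, ncol(preds))
      }
      mask <- matrix(stats::runif(n * ncol(preds)) < p_miss, n)
      preds[mask] <- NA
    }

    cohort <- cohort_table(
      data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                 time_months = time_obs, event = event, preds,
                 check.names = FALSE),
      horizon_months = config$horizon_months)
    truth <- data.frame(subject_id = cohort$subject_id,
                        linear_predictor = lp,
                        event_time = t_event,
                        censor_time = t_censor,
                        stringsAsFactors = FALSE)
    attr(truth, "true_betas") <- config$true_betas
    attr(truth, "baseline_hazard") <- h0
    attr(cohort, "refused") <- refused
    list(cohort = cohort, truth = truth)
  })
}
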