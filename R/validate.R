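# Out-of-sample risk estimation. The central guarantee: no subject's risk
# score is ever produced by a model -- imputation or Cox -- whose training
# rows included that subject. Both validation strategies share one
# training-set pipeline: fit lasso imputation models on the training
# subjects, multiply impute training and held-out subjects with those
# models, select the Cox-lasso penalty by seeded inner cross-validation on
# the first completed training set, fit one Cox lasso per completed set,
# and average the held-out linear predictors across imputations.

#' Validation configuration
#'
#' @param m_imputations completed datasets per training set (default 10).
#' @param n_bootstrap bootstrap replications (default 1000).
#' @param n_folds folds of the inner penalty-selection CV (default 10).
#' @param seed master seed; every fold/replication/imputation draws its own
#'   substream from it.
#' @return an object of class `validation_config`.
#' @export
validation_config <- function(m_imputations = 10, n_bootstrap = 1000,
                              n_folds = 10, seed = 1L) {
  stopifnot(m_imputations >= 1, n_bootstrap >= 1, n_folds >= 3)
  if (n_bootstrap < 100)
    warnf("n_bootstrap < 100: confidence intervals will be unreliable")
  structure(list(m_imputations = as.integer(m_imputations),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "validation_config")
}

# Fit the imputation + Cox-lasso ensemble on a training cohort and score
# held-out subjects. Returns per-imputation linear predictors (original
# scale) for the test rows, so callers can both average and audit.
score_heldout <- function(train, test, m, n_folds, seed_imp_train,
                          seed_imp_test, seed_cv) {
  if (sum(train$event) < 1) return(NULL)
  imp_models <- fit_imputation_models(train)
  train_imps <- impute_multiply(train, train, imp_models, m = m,
                                seed = seed_imp_train)
  test_imps <- impute_multiply(train, test, imp_models, m = m,
                               seed = seed_imp_test)
  y <- survival::Surv(train$time_months, train$event)
  scores <- matrix(NA_real_, nrow(test), m)
  lambda <- NULL
  for (k in seq_len(m)) {
    design <- suppressMessages(standardize_design(train_imps[[k]]))
    fit <- if (is.null(lambda)) {
      path <- select_lambda(design, y, family = "cox", n_folds = n_folds,
                            seed = seed_cv)
      lambda <- path$lambda
      path$fit
    } else {
      fit_lasso(design, y, lambda, family = "cox")
    }
    scores[, k] <- predict(fit, test_imps[[k]])
  }
  list(scores = scores, lambda = lambda)
}

#' Leave-one-out cross-validated risk scores
#'
#' For each subject, the imputation models and the multiply-imputed Cox
#' lasso (one fit per completed dataset) are trained on the other `n - 1`
#' subjects; the held-out subject is imputed with the training-fitted
#' models and scored per imputation, and the per-imputation linear
#' predictors are averaged into that subject's single out-of-sample risk
#' score. At the end every subject carries exactly one score, and no model
#' that scored a subject ever saw that subject.
#'
#' @param cohort a `cohort_table` with `n >= 10` and at least 3 events.
#' @param config a [validation_config()].
#' @return an object of class `out_of_sample_risk` (strategy `"loocv"`):
#'   `scores` (data.frame subject_id, score, n_contributions) and
#'   `per_imputation` (n x m matrix of held-out linear predictors).
#' @export
loocv_risk <- function(cohort, config = validation_config()) {
  n <- nrow(cohort)
  if (n < 10) stopf("loocv_risk needs n >= 10")
  if (sum(cohort$event) < 3) stopf("loocv_risk needs >= 3 events")
  m <- config$m_imputations
  per_imp <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    res <- score_heldout(
      cohort[-i, ], cohort[i, , drop = FALSE], m = m,
      n_folds = config$n_folds,
      seed_imp_train = derive_seed(config$seed, "loocv", i, "train"),
      seed_imp_test = derive_seed(config$seed, "loocv", i, "test"),
      seed_cv = derive_seed(config$seed, "loocv", i, "cv"))
    if (is.null(res)) {
      warnf("training fold without events: subject %s left unscored",
            cohort$subject_id[i])
      next
    }
    per_imp[i, ] <- res$scores[1, ]
  }
  structure(list(
    scores = data.frame(subject_id = cohort$subject_id,
                        score = rowMeans(per_imp),
                        n_contributions = as.integer(!is.na(per_imp[, 1])),
                        stringsAsFactors = FALSE),
    per_imputation = per_imp,
    strategy = "loocv", seed = config$seed),
    class = "out_of_sample_risk")
}

# Seeded bootstrap bag: n indices drawn with replacement.
draw_bag <- function(n, seed) with_seed(seed, sample.int(n, n, replace = TRUE))

#' Bootstrap out-of-bag risk scores
#'
#' Runs `n_bootstrap` seeded replications; each draws `n` subjects with
#' replacement as the training bag, runs the imputation + Cox-lasso
#' pipeline on the bag, and scores the out-of-bag subjects (those never
#' drawn). A subject's score is the mean over the replications in which it
#' was out-of-bag; the per-replication score matrix is retained for
#' confidence-interval construction. Replications whose bag carries no
#' events are recorded but contribute no scores, and extra replications are
#' appended if any subject ends with zero out-of-bag appearances.
#'
#' @inheritParams loocv_risk
#' @return an object of class `out_of_sample_risk` (strategy
#'   `"bootstrap_oob"`): `scores` as in [loocv_risk()], and
#'   `per_replication`, an n x B matrix with `NA` where a subject was
#'   in-bag (or the replication was invalid).
#' @export
bootstrap_oob_risk <- function(cohort, config = validation_config()) {
  n <- nrow(cohort)
  if (n < 10) stopf("bootstrap_oob_risk needs n >= 10")
  if (sum(cohort$event) < 3) stopf("bootstrap_oob_risk needs >= 3 events")
  m <- config$m_imputations
  B <- config$n_bootstrap
  run_rep <- function(b) {
    bag <- draw_bag(n, derive_seed(config$seed, "boot", b, "bag"))
    oob <- setdiff(seq_len(n), unique(bag))
    col <- rep(NA_real_, n)
    if (!length(oob)) return(col)
    train <- cohort[bag, ]
    train$subject_id <- sprintf("B%04d", seq_along(bag))  # bags repeat ids
    attr(train, "manifest") <- attr(cohort, "manifest")
    res <- tryCatch(score_heldout(
      train, cohort[oob, ], m = m, n_folds = config$n_folds,
      seed_imp_train = derive_seed(config$seed, "boot", b, "train"),
      seed_imp_test = derive_seed(config$seed, "boot", b, "test"),
      seed_cv = derive_seed(config$seed, "boot", b, "cv")),
      error = function(e) NULL)
    if (is.null(res)) return(col)
    col[oob] <- rowMeans(res$scores)
    col
  }
  per_rep <- vapply(seq_len(B), run_rep, numeric(n))
  # coverage guard: every subject must be scored out-of-bag at least once
  extra <- 0
  while (any(rowSums(!is.na(per_rep)) == 0) && extra < 50) {
    extra <- extra + 1
    per_rep <- cbind(per_rep, run_rep(B + extra))
  }
  n_contrib <- rowSums(!is.na(per_rep))
  structure(list(
    scores = data.frame(subject_id = cohort$subject_id,
                        score = rowMeans(per_rep, na.rm = TRUE),
                        n_contributions = as.integer(n_contrib),
                        stringsAsFactors = FALSE),
    per_replication = per_rep,
    strategy = "bootstrap_oob", seed = config$seed),
    class = "out_of_sample_risk")
}

#' @export
print.out_of_sample_risk <- function(x, ...) {
  cat(sprintf("<out_of_sample_risk> %s: %d subjects, mean score %.3f\n",
              x$strategy, nrow(x$scores), mean(x$scores$score, na.rm = TRUE)))
  invisible(x)
}

#' Final prognostic model on the full cohort
#'
#' Fits the same imputation + Cox-lasso pipeline on the complete cohort
#' (penalty selected on the first completed dataset, one Cox lasso per
#' completed dataset) and pools the per-imputation coefficients by
#' averaging. The pooled model is the deliverable a risk calculator is read
#' off; validation of its discrimination comes exclusively from
#' [loocv_risk()] / [bootstrap_oob_risk()].
#'
#' @param cohort a `cohort_table`.
#' @param config a [validation_config()].
#' @return an object of class `final_model`: pooled standardized and
#'   original-scale coefficients, selected penalty, and the per-imputation
#'   coefficient matrix.
#' @export
fit_final_model <- function(cohort, config = validation_config()) {
  m <- config$m_imputations
  imp_models <- fit_imputation_models(cohort)
  imps <- impute_multiply(cohort, cohort, imp_models, m = m,
                          seed = derive_seed(config$seed, "final", "imp"))
  y <- survival::Surv(cohort$time_months, cohort$event)
  lambda <- NULL
  coef_std <- coef_raw <- NULL
  for (k in seq_len(m)) {
    design <- suppressMessages(standardize_design(imps[[k]]))
    fit <- if (is.null(lambda)) {
      path <- select_lambda(design, y, family = "cox",
                            n_folds = config$n_folds,
                            seed = derive_seed(config$seed, "final", "cv"))
      lambda <- path$lambda
      path$fit
    } else fit_lasso(design, y, lambda, family = "cox")
    coef_std <- rbind(coef_std, fit$coefficients[order(names(fit$coefficients))])
    coef_raw <- rbind(coef_raw, fit$coefficients_raw[order(names(fit$coefficients_raw))])
  }
  pooled_std <- colMeans(coef_std)
  pooled_raw <- colMeans(coef_raw)
  structure(list(coefficients = pooled_std, coefficients_raw = pooled_raw,
                 lambda = lambda, per_imputation_std = coef_std,
                 m = m, seed = config$seed),
            class = "final_model")
}

#' @export
print.final_model <- function(x, ...) {
  act <- sum(x$coefficients != 0)
  cat(sprintf("<final_model> lambda %.4g, %d pooled nonzero coefficients\n",
              x$lambda, act))
  invisible(x)
}

#' Compare validation strategies on simulated cohorts with known truth
#'
#' Simulates cohorts from a generator configuration, runs both
#' leave-one-out and bootstrap out-of-bag validation on each, and reports
#' the distribution of their cumulative/dynamic AUC estimates at a fixed
#' horizon against the "true" AUC, computed with the generating linear
#' predictor as the score on one large independent simulated test cohort.
#'
#' @param gen_config a [generator_config()].
#' @param replications number of simulated cohorts (desk scale).
#' @param month evaluation horizon in months; default the median observed
#'   event month of the truth cohort.
#' @param config a [validation_config()] (use a reduced `n_bootstrap` at
#'   desk scale).
#' @param n_truth size of the independent truth cohort (default 10000).
#' @param seed master seed.
#' @return a list with `results` (one row per replication and strategy) and
#'   `true_auc`.
#' @export
compare_strategies <- function(gen_config, replications = 5, month = NULL,
                               config = validation_config(n_bootstrap = 100),
                               n_truth = 10000, seed = 1L) {
  big_cfg <- gen_config
  big_cfg$n_subjects <- as.integer(n_truth)
  big_cfg$target_events <- gen_config$target_events *
    n_truth / gen_config$n_subjects
  big_cfg$missing_fraction <- 0
  big_cfg$seed <- derive_seed(seed, "truth")
  big <- generate_cohort(big_cfg)
  if (is.null(month))
    month <- ceiling(stats::median(
      big$cohort$time_months[big$cohort$event == 1]))
  true_auc <- cumulative_auc_at(big$truth$linear_predictor,
                                big$cohort$time_months, big$cohort$event,
                                month)
  rows <- list()
  for (r in seq_len(replications)) {
    cfg <- gen_config
    cfg$seed <- derive_seed(seed, "rep", r)
    sim <- generate_cohort(cfg)
    vcfg <- config
    for (strategy in c("loocv", "bootstrap_oob")) {
      vcfg$seed <- derive_seed(seed, "rep", r, strategy)
      risk <- if (strategy == "loocv") loocv_risk(sim$cohort, vcfg)
      else bootstrap_oob_risk(sim$cohort, vcfg)
      rows[[length(rows) + 1]] <- data.frame(
        replication = r, strategy = strategy,
        auc = cumulative_auc_at(risk$scores$score, sim$cohort$time_months,
                                sim$cohort$event, month),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(auc ~ strategy, results,
                              function(a) c(mean = mean(a), sd = stats::sd(a)))
  list(results = results, summary = summary, true_auc = true_auc,
       month = month, seed = seed)
}
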