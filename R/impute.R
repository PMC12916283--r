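# Lasso-based multiple imputation. Imputation models are ordinary lasso
# regressions of each incomplete predictor on all other predictors
# (gaussian for continuous/ordinal, binomial for binary), fitted strictly
# on training subjects; completed datasets differ only in
# originally-missing cells, which are drawn stochastically so that
# imputation uncertainty propagates into the validated risk scores.

# Penalty rule for imputation models: a single lasso path per column with
# the penalty chosen by BIC (in-sample deviance + log(n) * df). Cheap enough
# to refit inside every cross-validation fold and bootstrap bag, where a
# full inner CV per column would dominate the run time.
fit_imputation_column <- function(xother, yobs, family) {
  n <- length(yobs)
  if (ncol(xother) == 0 ||
      all(apply(xother, 2, function(c) stats::sd(c) < 1e-12)))
    return(if (family == "binomial")
      list(constant = TRUE, value = mean(yobs), family = family)
    else list(constant = TRUE, value = mean(yobs),
              residual_sd = stats::sd(yobs), family = family))
  # a binary column with (almost) no minority class carries no regression
  # information; impute it as a Bernoulli draw at the observed rate
  if (family == "binomial" && min(tabulate(yobs + 1, 2)) < 3)
    return(list(constant = TRUE, value = mean(yobs), family = family))
  if (family == "gaussian" && stats::sd(yobs) < 1e-12)
    return(list(constant = TRUE, value = yobs[1], residual_sd = 0,
                family = family))
  design <- suppressMessages(standardize_design(xother))
  # rare binary flags routinely leave one class small; glmnet warns each
  # time, which is expected here rather than actionable
  g <- withCallingHandlers(
    glmnet::glmnet(pad_design_matrix(design$x), yobs, family = family,
                   nlambda = 30, lambda.min.ratio = 1e-2,
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dev <- (1 - g$dev.ratio) * g$nulldev
  bic <- dev + log(n) * g$df
  fit <- new_lasso_fit(g, s = g$lambda[which.min(bic)], design = design,
                       family = family)
  out <- list(constant = FALSE, fit = fit, family = family)
  if (family == "gaussian") {
    resid <- yobs - predict(fit, xother)
    out$residual_sd <- sqrt(mean(resid^2))
  }
  out
}

#' Fit lasso imputation models on training subjects
#'
#' For every predictor with missing values in the training rows, fits a
#' lasso regression of that predictor on all other predictors (gaussian
#' family for continuous and ordinal predictors, binomial for binary ones).
#' Covariates never include the survival outcome. Missing cells among the
#' covariates are filled with training means while fitting and predicting;
#' the stored training means also serve to fill covariates at application
#' time.
#'
#' @param train a `cohort_table` (training rows only).
#' @return an object of class `imputation_model_set`.
#' @export
fit_imputation_models <- function(train) {
  manifest <- attr(train, "manifest")
  x <- predictor_matrix(train)
  col_means <- colMeans(x, na.rm = TRUE)
  entirely_missing <- names(col_means)[!is.finite(col_means)]
  if (length(entirely_missing))
    stopf("predictor(s) entirely missing in training data: %s",
          paste(entirely_missing, collapse = ", "))
  heavy <- colnames(x)[colMeans(is.na(x)) > 0.5]
  if (length(heavy))
    warnf("predictor(s) >50%% missing in training data: %s",
          paste(utils::head(heavy, 5), collapse = ", "))
  xfill <- x
  for (j in seq_len(ncol(x))) xfill[is.na(x[, j]), j] <- col_means[j]

  incomplete <- colnames(x)[colSums(is.na(x)) > 0]
  models <- lapply(incomplete, function(nm) {
    kind <- manifest$kind[match(nm, manifest$name)]
    family <- if (kind == "binary") "binomial" else "gaussian"
    obs <- !is.na(x[, nm])
    fit_imputation_column(xfill[obs, setdiff(colnames(x), nm),
                                drop = FALSE],
                          x[obs, nm], family)
  })
  names(models) <- incomplete
  # observed training values per column back the fallback draw for cells
  # that are missing at application time in a column that was complete
  # (hence modelless) in training
  observed_values <- lapply(seq_len(ncol(x)), function(j)
    x[!is.na(x[, j]), j])
  names(observed_values) <- colnames(x)
  structure(list(models = models, train_means = col_means,
                 observed_values = observed_values,
                 columns = colnames(x)),
            class = "imputation_model_set")
}

impute_once <- function(x, models) {
  xfill <- x
  for (j in seq_len(ncol(x)))
    xfill[is.na(x[, j]), j] <- models$train_means[colnames(x)[j]]
  out <- x
  for (nm in names(models$models)) {
    miss <- which(is.na(x[, nm]))
    if (!length(miss)) next
    m <- models$models[[nm]]
    xo <- xfill[miss, setdiff(colnames(x), nm), drop = FALSE]
    if (m$family == "gaussian") {
      mu <- if (m$constant) rep(m$value, length(miss)) else predict(m$fit, xo)
      out[miss, nm] <- mu + stats::rnorm(length(miss), 0, m$residual_sd)
    } else {
      p <- if (m$constant) rep(m$value, length(miss)) else
        predict(m$fit, xo, type = "response")
      out[miss, nm] <- stats::rbinom(length(miss), 1, p)
    }
  }
  # columns complete in training have no model; draw leftover missing cells
  # from the column's observed training distribution
  for (nm in setdiff(colnames(x), names(models$models))) {
    miss <- which(is.na(x[, nm]))
    if (!length(miss)) next
    pool <- models$observed_values[[nm]]
    out[miss, nm] <- pool[sample.int(length(pool), length(miss),
                                     replace = TRUE)]
  }
  out
}

#' Multiply impute missing predictor cells
#'
#' Produces `m` completed copies of `apply_to`: continuous/ordinal cells are
#' drawn as model prediction plus Normal(0, training residual SD) noise,
#' binary cells as Bernoulli draws at the predicted probability. Observed
#' cells are never touched, and the models are fitted on `train` only, so a
#' held-out subject can be imputed without ever entering a model's training
#' rows.
#'
#' @param train a `cohort_table` of training subjects.
#' @param apply_to a `cohort_table` to complete (may equal `train`).
#' @param models an [fit_imputation_models()] result fitted on `train`, or
#'   `NULL` to fit here.
#' @param m number of completed datasets (default 10).
#' @param seed integer seed; the `m` draws are independent substreams.
#' @return a list of `m` completed predictor matrices (subjects x
#'   predictors, no missing cells).
#' @export
impute_multiply <- function(train, apply_to = train, models = NULL,
                            m = 10, seed = 1L) {
  if (is.null(models)) models <- fit_imputation_models(train)
  x <- predictor_matrix(apply_to)
  lapply(seq_len(m), function(k)
    with_seed(derive_seed(seed, "impute", k), impute_once(x, models)))
}
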