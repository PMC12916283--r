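# L1-penalized Gaussian, binomial and Cox regression with a regularization
# path -- the engines behind both the imputation models and the prognostic
# model. Solutions are computed with glmnet on an explicitly standardized
# design, so coefficients are available on both the standardized scale (used
# by the relevance metric) and the original scale.

#' Standardize a design matrix
#'
#' Centers every column to mean 0 and scales to population standard
#' deviation 1 (divisor `n`). Zero-variance columns are removed with a
#' notice; their names are retained so downstream fits report them with
#' coefficient zero.
#'
#' @param x numeric matrix (no missing cells), subjects x predictors.
#' @return an object of class `standardized_design` with fields `x`
#'   (standardized matrix), `center`, `scale`, `names`, `dropped`.
#' @export
standardize_design <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("design contains missing cells; impute first")
  n <- nrow(x)
  center <- colMeans(x)
  scale <- sqrt(colMeans(x^2) - center^2)  # population SD
  keep <- scale > 1e-12
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    message(sprintf("standardize_design: dropped %d zero-variance column(s)",
                    length(dropped)))
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
              scale[keep], "/")
  structure(list(x = xs, center = center[keep], scale = scale[keep],
                 names = colnames(x)[keep], dropped = dropped, n = n),
            class = "standardized_design")
}

#' Back-transform a standardized design
#'
#' @param design a [standardize_design()] result.
#' @return the original-scale matrix for the retained columns.
#' @export
unstandardize_design <- function(design) {
  sweep(sweep(design$x, 2, design$scale, "*"), 2, design$center, "+")
}

check_outcome <- function(design, y, family) {
  switch(family,
    gaussian = stopifnot(is.numeric(y), length(y) == design$n),
    binomial = stopifnot(all(y %in% c(0, 1)), length(y) == design$n),
    cox = {
      stopifnot(inherits(y, "Surv"), nrow(y) == design$n)
      if (sum(y[, "status"]) < 1) stopf("cox fit needs at least one event")
    })
}

# glmnet requires >= 2 columns; single-predictor designs get an all-zero
# companion column that is stripped from the returned coefficients.
pad_design_matrix <- function(x) {
  if (ncol(x) >= 2) x else cbind(x, .pad. = rep(0, nrow(x)))
}

lambda_max_of <- function(design, y, family) {
  # only the top of the path is needed; keep the probe fits trivial
  g <- glmnet::glmnet(pad_design_matrix(design$x), y, family = family,
                      standardize = FALSE, nlambda = 3,
                      lambda.min.ratio = 0.9)
  g$lambda[1]
}

#' Fit a lasso model at a fixed penalty
#'
#' Minimizes `(negative log-likelihood)/n + lambda * sum(|beta_j|)` on the
#' standardized design (partial likelihood with Breslow ties for the Cox
#' family). The solution is computed by warm-started cyclic coordinate
#' descent along a short path ending at `lambda`, which is how the solver
#' reaches a tight optimum at an arbitrary single penalty.
#'
#' @param design a [standardize_design()] result.
#' @param y outcome: numeric (gaussian), 0/1 (binomial), or
#'   `survival::Surv` (cox).
#' @param lambda non-negative penalty.
#' @param family `"gaussian"`, `"binomial"` or `"cox"`.
#' @return an object of class `lasso_fit`: standardized and original-scale
#'   coefficients, intercept (gaussian/binomial), penalty, and active set.
#' @export
fit_lasso <- function(design, y, lambda,
                      family = c("gaussian", "binomial", "cox")) {
  family <- match.arg(family)
  stopifnot(inherits(design, "standardized_design"), lambda >= 0)
  check_outcome(design, y, family)
  lmax <- lambda_max_of(design, y, family)
  if (lambda >= lmax) {
    lam_seq <- lambda
  } else {
    top <- max(lmax, lambda * 1.0001)
    lam_seq <- exp(seq(log(top), log(max(lambda, top * 1e-7)), length.out = 25))
    if (lambda <= top * 1e-7) lam_seq <- c(lam_seq, lambda)
    lam_seq[length(lam_seq)] <- lambda
  }
  g <- glmnet::glmnet(pad_design_matrix(design$x), y, family = family,
                      lambda = lam_seq, standardize = FALSE, thresh = 1e-12,
                      maxit = 1e6)
  new_lasso_fit(g, s = lambda, design = design, family = family)
}

new_lasso_fit <- function(glmnet_fit, s, design, family) {
  co <- as.matrix(stats::coef(glmnet_fit, s = s, exact = FALSE))
  if (family == "cox") {
    beta_std <- co[, 1]
    intercept_std <- NULL
  } else {
    beta_std <- co[-1, 1]
    intercept_std <- co[1, 1]
  }
  beta_std <- beta_std[seq_along(design$names)]  # drop any padding column
  names(beta_std) <- design$names
  beta_raw <- beta_std / design$scale
  intercept_raw <- if (is.null(intercept_std)) NULL else
    intercept_std - sum(beta_std * design$center / design$scale)
  # zero-variance columns dropped at standardization re-enter with beta 0
  if (length(design$dropped)) {
    zeros <- stats::setNames(numeric(length(design$dropped)), design$dropped)
    beta_std <- c(beta_std, zeros)
    beta_raw <- c(beta_raw, zeros)
  }
  structure(list(family = family, lambda = s,
                 coefficients = beta_std, coefficients_raw = beta_raw,
                 intercept = intercept_std, intercept_raw = intercept_raw,
                 active = names(beta_std)[beta_std != 0],
                 center = design$center, scale = design$scale),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> family %s, lambda %.4g, %d active of %d\n",
              x$family, x$lambda, length(x$active), length(x$coefficients)))
  invisible(x)
}

#' Linear predictor of a lasso fit on new data
#'
#' @param object a `lasso_fit`.
#' @param newx original-scale matrix or data.frame with the fit's columns.
#' @param type `"link"` (default) or `"response"` (binomial probability).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.lasso_fit <- function(object, newx, type = c("link", "response"),
                              ...) {
  type <- match.arg(type)
  nms <- names(object$coefficients_raw)
  if (!is.matrix(newx)) newx <- as.matrix(as.data.frame(newx))
  newx <- newx[, nms, drop = FALSE]
  eta <- drop(newx %*% object$coefficients_raw) +
    (object$intercept_raw %||% 0)
  if (type == "response" && object$family == "binomial") stats::plogis(eta)
  else eta
}

#' Select the penalty by seeded k-fold cross-validation
#'
#' Builds a 100-point log-spaced penalty grid below the smallest all-zero
#' penalty (four decades for the gaussian and binomial families; two for the
#' Cox family, where far smaller penalties yield saturated fits when events
#' are scarce), evaluates mean cross-validated deviance (partial-likelihood
#' deviance for the Cox family) over seeded folds, and selects either the
#' deviance-minimizing penalty (`rule = "min"`, the default) or the largest
#' penalty within one standard error of that minimum (`rule = "1se"`).
#' The min rule is the prediction-oriented default used by the prognostic
#' pipeline; the 1se rule is the conservative selector appropriate when the
#' question is which predictors carry signal at all (under pure noise it
#' returns an empty or near-empty model, which the min rule does not
#' guarantee). For the Cox family the fold count is reduced with a warning
#' when there are fewer events than folds.
#'
#' @param design a [standardize_design()] result.
#' @param y outcome (see [fit_lasso()]).
#' @param family model family.
#' @param n_folds folds for the inner CV (default 10, minimum 3).
#' @param seed integer seed for the fold assignment.
#' @param rule `"min"` (default) or `"1se"`.
#' @return an object of class `lasso_path`: the penalty grid, mean CV
#'   deviance, selected penalty (`lambda`), selection rule tag, and the
#'   [fit_lasso()] refit at the selected penalty (`fit`).
#' @export
select_lambda <- function(design, y, family = c("gaussian", "binomial",
                                                "cox"),
                          n_folds = 10, seed = 1L,
                          rule = c("min", "1se")) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  stopifnot(n_folds >= 3)
  check_outcome(design, y, family)
  n <- design$n
  if (family == "cox") {
    n_events <- sum(y[, "status"])
    if (n_events < n_folds) {
      n_folds <- max(3, n_events)
      warnf("select_lambda: reduced folds to %d (few events)", n_folds)
    }
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  cv <- glmnet::cv.glmnet(pad_design_matrix(design$x), y, family = family,
                          foldid = foldid,
                          type.measure = "deviance", nlambda = 100,
                          lambda.min.ratio = if (family == "cox") 1e-2
                          else 1e-4,
                          standardize = FALSE)
  lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  structure(list(lambda_grid = cv$lambda, cv_deviance = cv$cvm,
                 lambda = lambda, rule = rule, family = family,
                 fit = fit_lasso(design, y, lambda, family)),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "<lasso_path> family %s, %d-point grid, selected lambda %.4g (%s)\n",
    x$family, length(x$lambda_grid), x$lambda, x$rule))
  invisible(x)
}

#' Relevance of each selected predictor
#'
#' Relevance of a predictor within a fitted model is the absolute value of
#' its standardized coefficient divided by the sum of the absolute values of
#' all standardized coefficients; relevances are non-negative and sum to 1
#' over the active set.
#'
#' @param fit a `lasso_fit`.
#' @return named numeric vector over the active set.
#' @export
compute_relevance <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  b <- fit$coefficients[fit$coefficients != 0]
  if (!length(b)) stopf("no predictors selected")
  abs(b) / sum(abs(b))
}

# Gradient of the per-observation-scaled negative log-(partial-)likelihood
# at the fitted coefficients, used by the KKT optimality check.
nll_gradient <- function(fit, design, y) {
  x <- design$x
  n <- nrow(x)
  beta <- fit$coefficients[design$names]
  eta <- drop(x %*% beta)
  switch(fit$family,
    gaussian = crossprod(x, (fit$intercept + eta) - y)[, 1] / n,
    binomial = crossprod(x, stats::plogis(fit$intercept + eta) - y)[, 1] / n,
    cox = {
      time <- y[, "time"]; status <- y[, "status"]
      w <- exp(eta)
      grad <- numeric(ncol(x))
      for (t in unique(time[status == 1])) {
        at_risk <- time >= t
        d <- which(status == 1 & time == t)
        xbar <- colSums(x[at_risk, , drop = FALSE] * w[at_risk]) /
          sum(w[at_risk])
        grad <- grad - (colSums(x[d, , drop = FALSE]) - length(d) * xbar)
      }
      grad / n
    })
}

#' Karush-Kuhn-Tucker optimality residual of a lasso solution
#'
#' At an exact solution the gradient of the scaled negative log-likelihood
#' satisfies `|g_j| <= lambda` for inactive coefficients and
#' `g_j = -lambda * sign(beta_j)` for active ones. Returns the largest
#' violation of those conditions.
#'
#' @param fit a `lasso_fit`.
#' @param design the `standardized_design` the fit was computed on.
#' @param y the outcome used in the fit.
#' @return the maximum KKT violation (0 means exactly optimal).
#' @export
kkt_violation <- function(fit, design, y) {
  g <- nll_gradient(fit, design, y)
  beta <- fit$coefficients[design$names]
  active <- beta != 0
  viol_inactive <- if (any(!active))
    max(0, abs(g[!active]) - fit$lambda) else 0
  viol_active <- if (any(active))
    max(abs(g[active] + fit$lambda * sign(beta[active]))) else 0
  max(viol_inactive, viol_active)
}

#' Serialize a lasso fit to JSON
#'
#' @param fit a `lasso_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lasso_fit <- function(fit, path) {
  jsonlite::write_json(
    list(family = fit$family, lambda = fit$lambda,
         coefficients = as.list(fit$coefficients[fit$coefficients != 0]),
         coefficients_raw =
           as.list(fit$coefficients_raw[fit$coefficients_raw != 0]),
         intercept = fit$intercept_raw),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
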