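# End-to-end orchestration: screen -> validate -> evaluate -> calculator,
# with every stage's output written to plain CSV/JSON artifacts and a
# provenance block sufficient to reproduce the run bit-identically.

#' Configuration of a full analysis run
#'
#' @param cohort_path CSV of an existing cohort, or `NULL` to generate a
#'   synthetic one from `generator`.
#' @param manifest predictor manifest for `cohort_path` (default
#'   [default_manifest()]).
#' @param generator a [generator_config()] used when `cohort_path` is
#'   `NULL`.
#' @param validation a [validation_config()].
#' @param strategies validation strategies to run, subset of
#'   `c("loocv", "bootstrap_oob")`.
#' @param alpha two-tailed significance level (default 0.05).
#' @param horizon_months follow-up horizon.
#' @param seed master seed; mandatory for any stochastic stage.
#' @param desk if `TRUE`, reduce to the desk-scale profile
#'   (100 bootstrap replications, 5 imputations) for smoke runs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, manifest = default_manifest(),
                       generator = generator_config(),
                       validation = validation_config(),
                       strategies = c("loocv", "bootstrap_oob"),
                       alpha = 0.05, horizon_months = 60, seed = 1L,
                       desk = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  strategies <- match.arg(strategies, c("loocv", "bootstrap_oob"),
                          several.ok = TRUE)
  if (desk) {
    validation$n_bootstrap <- 100L
    validation$m_imputations <- 5L
  }
  structure(list(cohort_path = cohort_path, manifest = manifest,
                 generator = generator, validation = validation,
                 strategies = strategies, alpha = alpha,
                 horizon_months = horizon_months, seed = as.integer(seed),
                 desk = desk),
            class = "run_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

km_curve_frame <- function(km) {
  data.frame(time = km$time, n_risk = km$n_risk, n_event = km$n_event,
             surv = km$surv, cum_risk = km$cum_risk)
}

#' Run the full prognostic-modelling analysis
#'
#' Executes, in order: cohort acquisition (load or synthesize), univariate
#' Cox screening, out-of-sample validation (leave-one-out and/or bootstrap
#' out-of-bag), time-resolved AUC evaluation, AIC risk stratification with
#' stratified Kaplan-Meier curves, the pooled full-cohort model with its
#' relevance table, and the calculator's horizon-probability mapping.
#' All artifacts are written to `out_dir`; the run is idempotent under an
#' identical configuration and seed. A stage failure writes a `FAILED`
#' marker naming the stage and rethrows.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return an object of class `run_report` (invisibly also written as
#'   artifacts under `out_dir`).
#' @export
run_full_analysis <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    report <- list()

    stage <- "cohort"
    say("[cohort] acquiring cohort")
    if (is.null(config$cohort_path)) {
      gen <- config$generator
      gen$seed <- derive_seed(config$seed, "generate")
      sim <- generate_cohort(gen)
      cohort <- sim$cohort
      utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
    } else {
      cohort <- read_cohort(config$cohort_path, config$manifest,
                            config$horizon_months)
    }
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    report$cohort <- cohort

    stage <- "screen"
    say("[screen] univariate Cox screening of %d predictors",
        nrow(attr(cohort, "manifest")))
    screening <- screen_cohort(cohort)
    utils::write.csv(screening, file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    km_all <- km_estimate(cohort$time_months, cohort$event)
    utils::write.csv(km_curve_frame(km_all),
                     file.path(out_dir, "km_overall.csv"), row.names = FALSE)
    report$screening <- screening
    report$km <- km_all

    stage <- "validate"
    vcfg <- config$validation
    vcfg$seed <- derive_seed(config$seed, "validate")
    risks <- list()
    for (strategy in config$strategies) {
      say("[validate] %s (m = %d%s)", strategy, vcfg$m_imputations,
          if (strategy == "bootstrap_oob")
            sprintf(", B = %d", vcfg$n_bootstrap) else "")
      risks[[strategy]] <- if (strategy == "loocv") loocv_risk(cohort, vcfg)
      else bootstrap_oob_risk(cohort, vcfg)
      utils::write.csv(risks[[strategy]]$scores,
                       file.path(out_dir, sprintf("risk_%s.csv", strategy)),
                       row.names = FALSE)
    }
    report$risks <- risks

    stage <- "model"
    say("[model] pooled full-cohort lasso-Cox model")
    final <- fit_final_model(cohort, vcfg)
    write_json_artifact(
      list(lambda = final$lambda, m = final$m,
           coefficients = as.list(final$coefficients[
             final$coefficients != 0]),
           coefficients_raw = as.list(final$coefficients_raw[
             final$coefficients_raw != 0])),
      file.path(out_dir, "model.json"))
    model_table <- tryCatch(relevance_table(final), error = function(e) {
      warnf("final model is empty; model_table.csv will hold no rows")
      data.frame(name = character(), beta_std = numeric(),
                 beta_raw = numeric(), relevance = numeric())
    })
    utils::write.csv(model_table, file.path(out_dir, "model_table.csv"),
                     row.names = FALSE)
    report$final_model <- final
    report$model_table <- model_table

    stage <- "evaluate"
    primary <- risks[[config$strategies[1]]]
    for (strategy in names(risks)) {
      say("[evaluate] AUC over time, %s", strategy)
      curve <- auc_curve_with_ci(
        risks[[strategy]], cohort, conf_level = 1 - config$alpha,
        seed = derive_seed(config$seed, "auc", strategy))
      utils::write.csv(curve$curve,
                       file.path(out_dir, sprintf("auc_%s.csv", strategy)),
                       row.names = FALSE)
      report$auc[[strategy]] <- curve
    }
    say("[evaluate] AIC risk stratification")
    split <- aic_threshold_split(primary, cohort$time_months, cohort$event)
    strata <- do.call(rbind, lapply(names(split$km), function(g)
      cbind(group = g, km_curve_frame(split$km[[g]]))))
    utils::write.csv(strata, file.path(out_dir, "km_strata.csv"),
                     row.names = FALSE)
    write_json_artifact(
      list(threshold = split$threshold, aic = split$aic,
           n_low = sum(split$group == "low"),
           n_high = sum(split$group == "high")),
      file.path(out_dir, "risk_split.json"))
    report$risk_split <- split

    stage <- "calculator"
    say("[calculator] %g-month probability mapping",
        calculator_model()$horizon_months)
    calc <- calculator_model()
    # the out-of-sample linear predictor is mapped to a positive risk via
    # exp() before the log-risk logistic fit (the log then recovers the
    # linear predictor except at exactly zero risk, where epsilon guards)
    calc <- tryCatch(
      fit_horizon_mapping(calc, exp(primary$scores$score),
                          cohort$time_months, cohort$event),
      error = function(e) {
        warnf("horizon mapping not fitted: %s", conditionMessage(e))
        calc
      })
    write_json_artifact(
      list(coefficients = as.list(calc$coefficients), cutoff = calc$cutoff,
           epsilon = calc$epsilon, horizon_months = calc$horizon_months,
           logistic = calc$logistic),
      file.path(out_dir, "calculator.json"))
    report$calculator <- calc

    stage <- "provenance"
    prov <- list(
      package = "bsdrisk",
      version = as.character(utils::packageVersion("bsdrisk")),
      seed = config$seed,
      strategies = config$strategies,
      alpha = config$alpha,
      desk = config$desk,
      validation = unclass(config$validation),
      generator = if (is.null(config$cohort_path))
        lapply(unclass(config$generator), function(v)
          if (is.null(v)) NULL else unname(v)) else NULL,
      generator_beta_names = if (is.null(config$cohort_path))
        names(config$generator$true_betas) else NULL,
      cohort_path = config$cohort_path)
    write_json_artifact(prov, file.path(out_dir, "provenance.json"))
    report$provenance <- prov

    class(report) <- "run_report"
    invisible(report)
  }, error = on_fail)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> n = %d, events = %d\n", nrow(x$cohort),
              sum(x$cohort$event)))
  if (nrow(x$model_table)) {
    cat("  pooled model (top relevance):\n")
    top <- utils::head(x$model_table, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-24s beta_raw %+.3f  relevance %.1f%%\n",
                  top$name[i], top$beta_raw[i], 100 * top$relevance[i]))
  } else cat("  pooled model: empty\n")
  for (strategy in names(x$auc)) {
    cv <- x$auc[[strategy]]$curve
    ok <- !is.na(cv$auc)
    if (any(ok))
      cat(sprintf("  %s AUC: peak %.2f at month %d (%d significant months)\n",
                  strategy, max(cv$auc[ok]), cv$month[ok][which.max(cv$auc[ok])],
                  sum(cv$significant, na.rm = TRUE)))
  }
  cat(sprintf("  risk split threshold: %.4g (%d high risk)\n",
              x$risk_split$threshold, sum(x$risk_split$group == "high")))
  invisible(x)
}
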