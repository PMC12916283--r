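# Time-resolved discrimination and AIC-based risk stratification.
# Discrimination is summarized month by month with the cumulative-case /
# dynamic-control AUC: at month t, cases are subjects whose onset occurred
# by t and controls are subjects still at risk at t; subjects censored
# before t without an event carry no information about status at t and are
# excluded (an IPCW-weighted variant is out of scope; the exclusion rule is
# simple and exactly verifiable against pair enumeration).

#' Cumulative/dynamic AUC at one month
#'
#' Probability that a randomly chosen case (onset by `month`) outscores a
#' randomly chosen control (still at risk at `month`), ties counting one
#' half -- the Mann-Whitney statistic over case/control pairs. Invariant to
#' strictly monotone transforms of the scores.
#'
#' @param scores per-subject risk scores (an `out_of_sample_risk` or a
#'   numeric vector aligned with `times`).
#' @param times follow-up times in months.
#' @param events 0/1 onset indicators.
#' @param month evaluation horizon (positive).
#' @return the AUC in `[0, 1]`, or `NA` if there is no case or no control
#'   at `month` (undefined-at-month marker).
#' @export
cumulative_auc_at <- function(scores, times, events, month) {
  if (inherits(scores, "out_of_sample_risk")) scores <- scores$scores$score
  stopifnot(length(scores) == length(times), month > 0)
  case <- events == 1 & times <= month
  control <- times >= month & !case
  keep <- (case | control) & !is.na(scores)
  n1 <- sum(case & keep); n0 <- sum(control & keep)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores[keep])
  (sum(r[case[keep]]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC-over-time curve with bootstrap confidence band
#'
#' Point estimate and percentile 95% confidence interval of the
#' cumulative/dynamic AUC at each month of the follow-up grid. For
#' bootstrap out-of-bag scores the band comes from the retained
#' per-replication scores (each replication's out-of-bag subjects yield one
#' AUC per month); for leave-one-out scores a seeded bootstrap over
#' subjects supplies it. Months where the interval excludes 0.5 are flagged
#' significant (two-tailed 5% level); months with fewer than 3 cumulative
#' events are annotated low-confidence.
#'
#' @param risk an `out_of_sample_risk`.
#' @param cohort the `cohort_table` the scores belong to.
#' @param months integer month grid; default 1 to the floor of the longest
#'   follow-up.
#' @param n_boot bootstrap-over-subjects resamples for the leave-one-out
#'   band (default 1000).
#' @param conf_level band level (default 0.95).
#' @param seed seed for the subject bootstrap.
#' @return an object of class `time_auc_curve`: data.frame with columns
#'   `month`, `auc`, `ci_low`, `ci_high`, `n_events`, `significant`,
#'   `low_confidence`.
#' @export
auc_curve_with_ci <- function(risk, cohort, months = NULL, n_boot = 1000,
                              conf_level = 0.95, seed = 1L) {
  stopifnot(inherits(risk, "out_of_sample_risk"))
  times <- cohort$time_months
  events <- cohort$event
  if (is.null(months)) months <- seq_len(floor(max(times)))
  alpha <- 1 - conf_level
  point <- vapply(months, function(mo)
    cumulative_auc_at(risk$scores$score, times, events, mo), numeric(1))

  if (risk$strategy == "bootstrap_oob") {
    reps <- risk$per_replication
    ci <- vapply(months, function(mo) {
      aucs <- apply(reps, 2, function(col) {
        ok <- !is.na(col)
        if (!any(ok)) return(NA_real_)
        cumulative_auc_at(col[ok], times[ok], events[ok], mo)
      })
      aucs <- aucs[!is.na(aucs)]
      if (length(aucs) < 10) return(c(NA_real_, NA_real_))
      stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    }, numeric(2))
  } else {
    n <- length(times)
    draws <- with_seed(derive_seed(seed, "auc_ci"),
                       matrix(sample.int(n, n * n_boot, replace = TRUE),
                              n, n_boot))
    ci <- vapply(months, function(mo) {
      aucs <- apply(draws, 2, function(idx)
        cumulative_auc_at(risk$scores$score[idx], times[idx], events[idx],
                          mo))
      aucs <- aucs[!is.na(aucs)]
      if (length(aucs) < 10) return(c(NA_real_, NA_real_))
      stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    }, numeric(2))
  }

  n_events_by <- vapply(months, function(mo)
    sum(events == 1 & times <= mo), numeric(1))
  out <- data.frame(month = months, auc = point,
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    n_events = as.integer(n_events_by),
                    significant = !is.na(ci[1, ]) & !is.na(point) &
                      (ci[1, ] > 0.5 | ci[2, ] < 0.5),
                    low_confidence = n_events_by < 3)
  structure(list(curve = out, strategy = risk$strategy,
                 conf_level = conf_level), class = "time_auc_curve")
}

#' @export
print.time_auc_curve <- function(x, ...) {
  defined <- x$curve[!is.na(x$curve$auc), ]
  cat(sprintf(
    "<time_auc_curve> %s: %d months, peak AUC %.3f at month %d, %d significant\n",
    x$strategy, nrow(x$curve),
    max(defined$auc), defined$month[which.max(defined$auc)],
    sum(x$curve$significant, na.rm = TRUE)))
  invisible(x)
}

#' Split the cohort into low/high risk groups by minimum AIC
#'
#' Scans the midpoints between consecutive distinct risk scores (keeping at
#' least `min_group` subjects on each side), fits a one-parameter Cox model
#' on the high/low indicator at each candidate, and returns the threshold
#' with the lowest AIC (`2k - 2 * maximized partial log-likelihood`,
#' `k = 1`; Breslow ties) together with the full AIC profile and the
#' stratified Kaplan-Meier curve of each group. Ties in the profile resolve
#' to the lowest threshold. The chosen partition depends on the scores only
#' through their ranks.
#'
#' @param scores an `out_of_sample_risk` or numeric vector.
#' @param times,events outcome vectors aligned with `scores`.
#' @param min_group smallest allowed group size (default 5).
#' @return an object of class `risk_group_split`: `threshold`, `aic`,
#'   `profile` (data.frame threshold, aic), `group` (factor low/high), and
#'   `km` (list of `km_curve` per group).
#' @export
aic_threshold_split <- function(scores, times, events, min_group = 5) {
  if (inherits(scores, "out_of_sample_risk")) scores <- scores$scores$score
  stopifnot(length(scores) == length(times), length(times) == length(events))
  if (sum(events) < 2) stopf("aic_threshold_split needs >= 2 events")
  s <- sort(unique(scores))
  if (length(s) < 2) stopf("no split possible: all scores identical")
  mids <- (s[-1] + s[-length(s)]) / 2
  sizes_hi <- vapply(mids, function(th) sum(scores > th), numeric(1))
  keep <- sizes_hi >= min_group & (length(scores) - sizes_hi) >= min_group
  if (!any(keep))
    stopf("no candidate threshold keeps %d subjects per group", min_group)
  mids <- mids[keep]
  aic <- vapply(mids, function(th) {
    hi <- as.numeric(scores > th)
    # extreme thresholds can separate the groups completely; the partial
    # likelihood still converges to a finite value, which is all AIC needs
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(times, events) ~ hi, ties = "breslow"))
    2 - 2 * fit$loglik[2]
  }, numeric(1))
  best <- which.min(aic)  # which.min takes the first (lowest) threshold
  threshold <- mids[best]
  group <- factor(ifelse(scores > threshold, "high", "low"),
                  levels = c("low", "high"))
  km <- lapply(split(seq_along(scores), group), function(idx)
    km_estimate(times[idx], events[idx]))
  structure(list(threshold = threshold, aic = aic[best],
                 profile = data.frame(threshold = mids, aic = aic),
                 group = group, km = km),
            class = "risk_group_split")
}

#' @export
print.risk_group_split <- function(x, ...) {
  cat(sprintf(
    "<risk_group_split> threshold %.4g (AIC %.2f): %d low / %d high\n",
    x$threshold, x$aic, sum(x$group == "low"), sum(x$group == "high")))
  invisible(x)
}
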