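# Kaplan-Meier estimation and univariate Cox screening. Wraps the
# `survival` package (product-limit estimator; partial likelihood with
# Breslow tie handling) behind small typed result objects.

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function; censored subjects leave
#' the risk set after their time, and events are resolved before censorings
#' tied at the same time. Cumulative risk is `1 - survival`.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @return an object of class `km_curve` with fields `time`, `surv`,
#'   `n_risk`, `n_event`, `cum_risk`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stopf("km_estimate: empty input")
  if (length(times) != length(events))
    stopf("times and events must have equal length")
  if (any(times <= 0)) stopf("times must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, cum_risk = 1 - fit$surv,
                 n = length(times), total_events = sum(events)),
            class = "km_curve")
}

#' Cumulative risk at a time point
#'
#' Reads `1 - S(t)` off a Kaplan-Meier curve using the right-continuous
#' step convention; `t` beyond the last observed time returns the last value
#' and `t` before the first event returns 0.
#'
#' @param curve a [km_estimate()] result.
#' @param t time (months), `>= 0`.
#' @return cumulative event risk in `[0, 1]`.
#' @export
cumulative_risk_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 0, curve$cum_risk[pmax(idx, 1)])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d events, last time %.1f\n",
              x$n, x$total_events, max(x$time)))
  invisible(x)
}

#' Univariate Cox regression for one predictor
#'
#' Fits a single-predictor Cox proportional-hazards model (Breslow tie
#' handling) on complete cases, returning the log hazard ratio, its Wald
#' standard error, two-tailed p-value, and 95% CI. Degenerate inputs are
#' flagged rather than thrown: a constant predictor yields a non-estimable
#' result (HR 1, infinite CI), and a monotone-separation fit (|standardized
#' beta| > 10) is flagged divergent -- the pattern behind zero-event cells
#' reported as HR 0 with p near 1.
#'
#' @param cohort a `cohort_table`.
#' @param predictor predictor column name.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `cox_fit`.
#' @export
cox_fit_univariate <- function(cohort, predictor, conf_level = 0.95) {
  if (!predictor %in% names(cohort))
    stopf("unknown predictor '%s'", predictor)
  x <- cohort[[predictor]]
  ok <- !is.na(x)
  x <- x[ok]
  times <- cohort$time_months[ok]
  events <- cohort$event[ok]
  n_events <- sum(events)
  base <- list(predictor = predictor, n = sum(ok), n_events = n_events)

  if (length(unique(x)) < 2 || n_events == 0) {
    return(structure(c(base, list(
      beta = 0, hazard_ratio = 1, se = Inf, wald_p = NA_real_,
      ci = c(0, Inf), flag = "non_estimable")), class = "cox_fit"))
  }
  # monotone-likelihood (separated) fits warn; they are detected and
  # flagged from the standardized coefficient below
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  beta_std <- beta * stats::sd(x)
  flag <- if (!is.finite(beta) || abs(beta_std) > 10) "divergent" else "ok"
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(c(base, list(
    beta = beta, hazard_ratio = exp(beta), se = se,
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    ci = exp(beta + c(-1, 1) * z * se),
    flag = flag)), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s: HR %.3g (%.3g-%.3g), p %.3g [%s]\n",
              x$predictor, x$hazard_ratio, x$ci[1], x$ci[2],
              x$wald_p, x$flag))
  invisible(x)
}

#' Univariate screening of every predictor
#'
#' Runs [cox_fit_univariate()] on each manifest predictor, producing the
#' familiar screening table (predictor, HR, 95% CI, two-tailed Wald p) used
#' to describe baseline characteristics associated with onset.
#'
#' @param cohort a `cohort_table`.
#' @return a `data.frame` with one row per predictor.
#' @export
screen_cohort <- function(cohort) {
  manifest <- attr(cohort, "manifest")
  rows <- lapply(manifest$name, function(nm) {
    f <- cox_fit_univariate(cohort, nm)
    data.frame(predictor = nm, n = f$n, n_events = f$n_events,
               hr = f$hazard_ratio, ci_low = f$ci[1], ci_high = f$ci[2],
               p_value = f$wald_p, flag = f$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
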