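# Cohort data model: one row per subject, right-censored outcome, baseline
# predictors, explicit missingness. The single interchange object for all
# downstream stages.

#' BPSS-FP item codes
#'
#' The 31 items of the Bipolar Prodrome Symptom Interview and Scale - Full
#' Prospective: 10 mania (M1-M10), 12 depression (D1-D12) and 9 general
#' (G1-G9) symptom-index items. Each item carries an ordinal severity
#' (0 = absent .. 6 = extreme) and a binary prevalence flag (symptom present
#' at the interview threshold).
#'
#' @return character vector of the 31 item codes.
#' @export
bpss_item_codes <- function() {
  c(paste0("M", 1:10), paste0("D", 1:12), paste0("G", 1:9))
}

#' Build a predictor manifest
#'
#' A manifest declares every predictor column of a cohort table and its kind
#' (`binary`, `continuous`, or `ordinal`). Ordinal severities enter models as
#' numeric covariates; the kind is retained so the imputation stage can choose
#' the right regression family (gaussian for continuous/ordinal, binomial for
#' binary).
#'
#' @param name character vector of predictor column names.
#' @param kind character vector, one of `"binary"`, `"continuous"`,
#'   `"ordinal"`, recycled against `name`.
#' @return a `data.frame` with columns `name` and `kind`.
#' @export
predictor_manifest <- function(name, kind) {
  kind <- rep_len(kind, length(name))
  bad <- setdiff(unique(kind), c("binary", "continuous", "ordinal"))
  if (length(bad))
    stopf("unknown predictor kind(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(name))
    stopf("duplicated predictor name(s) in manifest")
  data.frame(name = as.character(name), kind = kind,
             stringsAsFactors = FALSE)
}

#' Default predictor manifest for an adolescent inpatient cohort
#'
#' Covers the baseline blocks used by the prognostic analysis: demographics
#' (age, sex, race as one-hot indicators against the largest category),
#' binary diagnosis and medication-class flags, psychopathology scale totals
#' (MADRS, CGI-S, GAF current/high/low, YMRS), and the 31 BPSS-FP items, each
#' as an ordinal severity plus a binary prevalence flag.
#'
#' @return a predictor manifest `data.frame`.
#' @export
default_manifest <- function() {
  items <- bpss_item_codes()
  rbind(
    predictor_manifest("age_years", "continuous"),
    predictor_manifest("sex_male", "binary"),
    predictor_manifest(paste0("race_", c("black", "mixed", "asian_pacific",
                                         "other")), "binary"),
    predictor_manifest(c("depressive_disorders",
                         "persistent_depressive_disorder",
                         "trauma_stressor_disorders",
                         "personality_disorder_traits",
                         "anxiety_disorders",
                         "disruptive_behavior_disorders",
                         "adhd",
                         "substance_use_disorders",
                         "attenuated_psychosis_syndrome",
                         "eating_disorders"), "binary"),
    predictor_manifest(c("antipsychotics", "antidepressants",
                         "mood_stabilizers", "lithium", "anxiolytics",
                         "adhd_medications"), "binary"),
    predictor_manifest(c("madrs_total", "cgi_s", "gaf_current", "gaf_high",
                         "gaf_low", "ymrs_total"), "continuous"),
    predictor_manifest(paste0("severity_", items), "ordinal"),
    predictor_manifest(paste0("prevalence_", items), "binary")
  )
}

#' Read or write a predictor manifest file
#'
#' A manifest file is a two-column CSV (`name`, `kind`) declaring each
#' predictor and its kind; the companion of a cohort CSV.
#'
#' @param path CSV path.
#' @return [read_manifest()] returns a validated manifest `data.frame`;
#'   [write_manifest()] returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "kind") %in% names(raw)))
    stopf("manifest file needs columns 'name' and 'kind'")
  predictor_manifest(raw$name, raw$kind)
}

#' @rdname read_manifest
#' @param manifest a predictor manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Construct a cohort table
#'
#' @param data a `data.frame` with columns `subject_id`, `time_months`,
#'   `event`, plus one column per manifest predictor. Missing predictor
#'   values are `NA` and are preserved (only the imputation stage may fill
#'   them).
#' @param manifest a predictor manifest (see [predictor_manifest()]).
#' @param horizon_months maximum admissible follow-up, months.
#' @return an object of class `cohort_table` (a validated `data.frame` with
#'   the manifest attached as an attribute).
#' @export
cohort_table <- function(data, manifest = default_manifest(),
                         horizon_months = 60) {
  data <- as.data.frame(data)
  required <- c("subject_id", "time_months", "event")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stopf("cohort is missing outcome column(s): %s",
          paste(missing_cols, collapse = ", "))
  absent <- setdiff(manifest$name, names(data))
  if (length(absent))
    stopf("cohort is missing predictor column(s): %s",
          paste(utils::head(absent, 5), collapse = ", "))
  data <- data[, c(required, manifest$name)]
  for (nm in c("time_months", "event", manifest$name))
    data[[nm]] <- as.numeric(data[[nm]])
  attr(data, "manifest") <- manifest
  attr(data, "horizon_months") <- horizon_months
  class(data) <- c("cohort_table", "data.frame")
  validate_cohort(data)
  data
}

#' Validate a cohort table
#'
#' Checks outcome invariants (positive times, 0/1 events, unique subject ids,
#' follow-up within the horizon) and predictor ranges: binary predictors in
#' \{0,1\}, BPSS severities on the 0-6 ordinal scale, and the consistency rule
#' that a prevalence flag of 1 implies severity >= 1 when both are observed.
#' Range violations are hard errors naming the offending row and column.
#'
#' @param cohort a `cohort_table`.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  manifest <- attr(cohort, "manifest")
  horizon <- attr(cohort, "horizon_months") %||% 60
  if (anyDuplicated(cohort$subject_id))
    stopf("duplicated subject_id values")
  if (anyNA(cohort$time_months) || anyNA(cohort$event))
    stopf("outcome columns (time_months, event) must be fully observed")
  if (any(cohort$time_months <= 0))
    stopf("time_months must be > 0 (row %d)",
          which(cohort$time_months <= 0)[1])
  if (any(cohort$time_months > horizon + 1e-8))
    stopf("time_months exceeds the %g-month horizon (row %d)", horizon,
          which(cohort$time_months > horizon + 1e-8)[1])
  if (!all(cohort$event %in% c(0, 1)))
    stopf("event must be 0/1 (row %d)",
          which(!cohort$event %in% c(0, 1))[1])
  check_range <- function(cols, lo, hi, label) {
    for (nm in cols) {
      x <- cohort[[nm]]
      bad <- which(!is.na(x) & (x < lo | x > hi))
      if (length(bad))
        stopf("%s out of range [%g, %g]: row %d, column '%s' (value %g)",
              label, lo, hi, bad[1], nm, x[bad[1]])
    }
  }
  bin_cols <- manifest$name[manifest$kind == "binary"]
  for (nm in bin_cols) {
    x <- cohort[[nm]]
    bad <- which(!is.na(x) & !(x %in% c(0, 1)))
    if (length(bad))
      stopf("binary predictor not in {0,1}: row %d, column '%s' (value %g)",
            bad[1], nm, x[bad[1]])
  }
  sev_cols <- grep("^severity_", manifest$name, value = TRUE)
  check_range(sev_cols, 0, 6, "severity")
  # prevalence = 1 with severity rated absent is inconsistent but possible in
  # raw data entry; surface it without refusing the table
  for (code in sub("^severity_", "", sev_cols)) {
    pnm <- paste0("prevalence_", code)
    if (!pnm %in% names(cohort)) next
    s <- cohort[[sev_cols[match(code, sub("^severity_", "", sev_cols))]]]
    p <- cohort[[pnm]]
    bad <- which(!is.na(s) & !is.na(p) & p == 1 & s < 1)
    if (length(bad))
      warnf("prevalence_%s = 1 with severity 0 in row %d", code, bad[1])
  }
  invisible(cohort)
}

#' Read a cohort from CSV
#'
#' @param path CSV file (RFC-4180, UTF-8, header row); empty cells are
#'   missing values and are recorded in the missingness mask, never imputed
#'   at read time.
#' @param manifest predictor manifest declaring each predictor's kind.
#' @param horizon_months follow-up horizon, months.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, manifest = default_manifest(),
                        horizon_months = 60) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = c("", "NA"))
  cohort_table(raw, manifest = manifest, horizon_months = horizon_months)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: values, missingness and column order are
#' preserved across a write/read round trip.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Missingness mask of a cohort's predictors
#'
#' @param cohort a `cohort_table`.
#' @return logical matrix, subjects x predictors, `TRUE` where missing.
#' @export
missing_mask <- function(cohort) {
  manifest <- attr(cohort, "manifest")
  m <- is.na(as.matrix(cohort[, manifest$name, drop = FALSE]))
  rownames(m) <- cohort$subject_id
  m
}

#' Numeric predictor matrix of a cohort
#'
#' @param cohort a `cohort_table` (or a completed copy from the imputation
#'   stage).
#' @return numeric matrix, subjects x predictors, in manifest order.
#' @export
predictor_matrix <- function(cohort) {
  manifest <- attr(cohort, "manifest")
  x <- as.matrix(as.data.frame(cohort)[, manifest$name, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- cohort$subject_id
  x
}

#' @export
`[.cohort_table` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "manifest") <- attr(x, "manifest")
    attr(out, "horizon_months") <- attr(x, "horizon_months")
    class(out) <- class(x)
  }
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  manifest <- attr(x, "manifest")
  cat(sprintf("<cohort_table> %d subjects, %d events, %d predictors\n",
              nrow(x), sum(x$event), nrow(manifest)))
  cat(sprintf("  missing predictor cells: %d (%.1f%%)\n",
              sum(missing_mask(x)),
              100 * mean(missing_mask(x))))
  invisible(x)
}

#' Integrate patient and caregiver symptom ratings
#'
#' Interviews conducted separately with the patient and a caregiver are
#' merged item by item by keeping the higher rating on each side (symptoms
#' are more likely forgotten than invented): integrated severity is the
#' maximum of the observed severities and the integrated prevalence flag the
#' maximum of the observed flags. If only one informant rated an item, that
#' rating carries; if neither did, the item stays missing. The operation is
#' commutative, idempotent, and never decreases an observed rating.
#'
#' @param patient,caregiver `data.frame`s with columns `code`, `severity`
#'   (0-6 or `NA`) and `prevalence` (0/1 or `NA`), one row per BPSS item.
#'   Both sides must cover the same item set.
#' @return a `data.frame` of integrated ratings in the patient's item order.
#' @export
integrate_ratings <- function(patient, caregiver) {
  for (side in list(patient, caregiver)) {
    if (!all(c("code", "severity", "prevalence") %in% names(side)))
      stopf("ratings need columns code, severity, prevalence")
  }
  if (anyDuplicated(patient$code) || anyDuplicated(caregiver$code))
    stopf("duplicated item codes in ratings")
  if (!setequal(patient$code, caregiver$code))
    stopf("patient and caregiver ratings cover different item sets")
  idx <- match(patient$code, caregiver$code)
  pair_max <- function(a, b) {
    out <- pmax(a, b, na.rm = TRUE)
    out[is.na(a) & is.na(b)] <- NA
    out
  }
  check_sev <- function(x, side) {
    bad <- which(!is.na(x) & (x < 0 | x > 6))
    if (length(bad)) stopf("%s severity out of range 0-6 (item %s)",
                           side, patient$code[bad[1]])
  }
  check_sev(patient$severity, "patient")
  check_sev(caregiver$severity[idx], "caregiver")
  data.frame(
    code = patient$code,
    severity = pair_max(patient$severity, caregiver$severity[idx]),
    prevalence = pair_max(patient$prevalence, caregiver$prevalence[idx]),
    stringsAsFactors = FALSE
  )
}
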