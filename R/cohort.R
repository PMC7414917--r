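#' @importFrom rlang .data abort warn %||%
#' @importFrom stats qnorm qlogis plogis quantile
NULL

# Canonical cohort columns (CSV contract). Booleans are written as 0/1,
# missing values as empty cells.
COHORT_COLUMNS <- c(
  "patient_id", "gender", "onset", "age", "symptom_duration_months",
  "weight_kg", "alsfrs_baseline", "decline_rate",
  "survived_12m", "survival_months", "alsfrs_12m"
)

# The seven baseline predictors, in the fixed order used to build feature
# matrices everywhere in the package.
PREDICTORS <- c(
  "gender", "onset", "age", "symptom_duration_months",
  "weight_kg", "alsfrs_baseline", "decline_rate"
)

ALSFRS_MAX <- 40

#' Functional decline rate from baseline ALSFRS and symptom duration
#'
#' Estimates the average monthly loss of ALSFRS points between symptom onset
#' (where the score is taken to be the scale maximum of 40, i.e. no
#' impairment) and the baseline visit:
#' \deqn{rate = -\frac{40 - ALSFRS_{baseline}}{duration}}
#'
#' The rate is reported with a negative sign so that faster functional loss
#' is more negative, matching how decline rates are quoted clinically; a
#' patient at the scale maximum has rate 0.
#'
#' @param baseline_alsfrs Baseline ALSFRS total score, in `[0, 40]`.
#' @param symptom_duration Months between symptom onset and baseline; must be
#'   strictly positive.
#' @return Numeric vector of decline rates (ALSFRS points per month, <= 0).
#' @examples
#' compute_decline_rate(36, 6.5)  # -0.615, quoted as -0.6/month
#' compute_decline_rate(40, 12)   # 0: no loss since onset
#' @export
compute_decline_rate <- function(baseline_alsfrs, symptom_duration) {
  if (any(!is.finite(baseline_alsfrs)))
    abort("`baseline_alsfrs` must be finite.")
  if (any(baseline_alsfrs < 0 | baseline_alsfrs > ALSFRS_MAX))
    abort(sprintf("`baseline_alsfrs` must lie in [0, %d].", ALSFRS_MAX))
  if (any(!is.finite(symptom_duration)) || any(symptom_duration <= 0))
    abort("`symptom_duration` must be a positive number of months.")
  -(ALSFRS_MAX - baseline_alsfrs) / symptom_duration
}

validate_cohort <- function(cohort, call = rlang::caller_env()) {
  missing_cols <- setdiff(
    c("patient_id", "gender", "onset", "age", "symptom_duration_months",
      "weight_kg", "alsfrs_baseline"),
    names(cohort)
  )
  if (length(missing_cols) > 0)
    abort(paste0("Cohort is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  dup <- cohort$patient_id[duplicated(cohort$patient_id)]
  if (length(dup) > 0)
    abort(paste0("Duplicate patient_id in cohort: ",
                 paste(unique(dup), collapse = ", ")), call = call)
  bad_gender <- setdiff(unique(cohort$gender[!is.na(cohort$gender)]),
                        c("male", "female"))
  if (length(bad_gender) > 0)
    abort(paste0("`gender` must be 'male' or 'female'; found: ",
                 paste(bad_gender, collapse = ", ")), call = call)
  bad_onset <- setdiff(unique(cohort$onset[!is.na(cohort$onset)]),
                       c("spinal", "bulbar"))
  if (length(bad_onset) > 0)
    abort(paste0("`onset` must be 'spinal' or 'bulbar'; found: ",
                 paste(bad_onset, collapse = ", ")), call = call)
  ok <- is.na(cohort$alsfrs_baseline) |
    (cohort$alsfrs_baseline >= 0 & cohort$alsfrs_baseline <= ALSFRS_MAX)
  if (!all(ok))
    abort(paste0("`alsfrs_baseline` out of [0, 40] for row(s): ",
                 paste(which(!ok), collapse = ", ")), call = call)
  invisible(cohort)
}

# Derive decline_rate where absent; records with non-positive duration are
# left NA (treated as incomplete) rather than assigned an infinite rate.
derive_decline_rate <- function(cohort) {
  if (!"decline_rate" %in% names(cohort)) cohort$decline_rate <- NA_real_
  need <- is.na(cohort$decline_rate) &
    !is.na(cohort$alsfrs_baseline) &
    !is.na(cohort$symptom_duration_months) &
    cohort$symptom_duration_months > 0
  cohort$decline_rate[need] <- compute_decline_rate(
    cohort$alsfrs_baseline[need], cohort$symptom_duration_months[need]
  )
  cohort
}

#' Read a patient cohort from CSV
#'
#' Expects a UTF-8 CSV with a header row and the canonical columns
#' `patient_id, gender, onset, age, symptom_duration_months, weight_kg,
#' alsfrs_baseline` and optionally `decline_rate, survived_12m,
#' survival_months, alsfrs_12m`. Booleans are 0/1; missing values are empty
#' cells. The decline rate is derived from baseline ALSFRS and symptom
#' duration when the column is absent or empty (records with non-positive
#' duration stay `NA`).
#'
#' @param path Path to a CSV file.
#' @param source_label Label attached to the cohort (e.g. `"development"`,
#'   `"validation"`); stored as the `source_label` attribute.
#' @return A tibble, one row per patient, with a `source_label` attribute.
#' @export
read_cohort <- function(path, source_label = "cohort") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  spec <- readr::cols(
    patient_id = readr::col_character(),
    gender = readr::col_character(),
    onset = readr::col_character(),
    survived_12m = readr::col_logical(),   # accepts 0/1 and TRUE/FALSE
    .default = readr::col_double()
  )
  # readr's own warnings are redundant here: parse problems are re-raised as
  # row-level errors below, and absent optional columns are fine
  cohort <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE,
                    na = c("", "NA")))
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Unparseable value(s) in ", path, " at row(s): ",
      paste(unique(probs$row), collapse = ", "),
      " (expected ", paste(unique(probs$expected), collapse = "; "), ")"
    ))
  }
  validate_cohort(cohort)
  cohort <- derive_decline_rate(cohort)
  if ("survived_12m" %in% names(cohort)) {
    cohort$survived_12m <- as.logical(cohort$survived_12m)
  }
  attr(cohort, "source_label") <- source_label
  cohort
}

#' Write a patient cohort to CSV
#'
#' Writes the canonical columns (see [read_cohort()]) with booleans as 0/1
#' and missing values as empty cells, so that a write/read round trip
#' reproduces all fields to full precision.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (col in setdiff(COHORT_COLUMNS, names(out))) out[[col]] <- NA_real_
  out <- out[COHORT_COLUMNS]
  out$survived_12m <- as.integer(out$survived_12m)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Complete-case filter
#'
#' Retains exactly the records with all `required` fields present (non-`NA`),
#' preserving order — complete-case analysis, with no imputation. Records
#' with a non-positive symptom duration are treated as incomplete whenever
#' `decline_rate` is required, because the decline rate is undefined for
#' them.
#'
#' @param cohort A cohort tibble.
#' @param required Character vector of required fields; defaults to the seven
#'   baseline predictors plus the 1-year survival outcome.
#' @return The filtered tibble, with attributes `n_retained` and `n_dropped`.
#' @export
complete_case_filter <- function(cohort,
                                 required = c(PREDICTORS, "survived_12m")) {
  unknown <- setdiff(required, names(cohort))
  if (length(unknown) > 0)
    abort(paste0("Unknown required field(s): ",
                 paste(unknown, collapse = ", ")))
  keep <- rep(TRUE, nrow(cohort))
  for (field in required) keep <- keep & !is.na(cohort[[field]])
  if ("decline_rate" %in% required &&
      "symptom_duration_months" %in% names(cohort)) {
    keep <- keep & !is.na(cohort$symptom_duration_months) &
      cohort$symptom_duration_months > 0
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "source_label") <- attr(cohort, "source_label")
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
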