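#' Fit a min-max feature normalizer on a development cohort
#'
#' Learns per-feature `(min, max)` bounds for the continuous predictors and
#' fixes the categorical encoding (`male` -> 1, `female` -> 0; `spinal` -> 1,
#' `bulbar` -> 0). Transforms with [apply_normalizer()] map the development
#' cohort onto `[0, 1]` exactly; later cohorts reuse the development bounds,
#' with out-of-bounds values clipped, so the embedding transform always sees
#' in-domain features.
#'
#' @param cohort A cohort tibble with the seven baseline predictors complete
#'   (run [complete_case_filter()] first).
#' @return An object of class `als_normalizer`: per-feature bounds and the
#'   categorical encoding map.
#' @export
fit_normalizer <- function(cohort) {
  if (nrow(cohort) == 0) abort("Cannot fit a normalizer on an empty cohort.")
  validate_cohort(cohort)
  continuous <- setdiff(PREDICTORS, c("gender", "onset"))
  if (any(vapply(cohort[continuous], function(x) any(is.na(x)), logical(1))))
    abort("Predictors contain missing values; apply complete_case_filter() first.")
  bounds <- tibble::tibble(
    feature = continuous,
    min = unname(vapply(cohort[continuous], min, numeric(1))),
    max = unname(vapply(cohort[continuous], max, numeric(1)))
  )
  degenerate <- bounds$feature[bounds$max <= bounds$min]
  if (length(degenerate) > 0)
    abort(paste0("Degenerate (constant) feature(s): ",
                 paste(degenerate, collapse = ", ")))
  structure(
    list(
      bounds = bounds,
      encoding = list(gender = c(male = 1, female = 0),
                      onset = c(spinal = 1, bulbar = 0)),
      features = PREDICTORS
    ),
    class = "als_normalizer"
  )
}

#' Transform a cohort into a normalized feature matrix
#'
#' Encodes the categorical predictors with the normalizer's encoding map and
#' rescales each continuous predictor to `(x - min) / (max - min)` using the
#' bounds learnt at fit time. Values outside the development bounds are
#' clipped to `[0, 1]`.
#'
#' @param normalizer An `als_normalizer` from [fit_normalizer()].
#' @param cohort A cohort tibble with the seven baseline predictors complete.
#' @return A tibble of seven feature columns, all values in `[0, 1]`, rows
#'   aligned with `cohort`.
#' @export
apply_normalizer <- function(normalizer, cohort) {
  stopifnot(inherits(normalizer, "als_normalizer"))
  validate_cohort(cohort)
  out <- tibble::tibble(
    gender = unname(normalizer$encoding$gender[cohort$gender]),
    onset = unname(normalizer$encoding$onset[cohort$onset])
  )
  for (i in seq_len(nrow(normalizer$bounds))) {
    f <- normalizer$bounds$feature[i]
    lo <- normalizer$bounds$min[i]
    hi <- normalizer$bounds$max[i]
    out[[f]] <- pmin(pmax((cohort[[f]] - lo) / (hi - lo), 0), 1)
  }
  if (any(vapply(out, function(x) any(is.na(x)), logical(1))))
    abort("Cohort has missing predictor values; apply complete_case_filter() first.")
  out[normalizer$features]
}

#' @export
print.als_normalizer <- function(x, ...) {
  cat("Min-max feature normalizer (7 baseline predictors)\n")
  cat("Encoding: male=1/female=0, spinal=1/bulbar=0\n")
  print(x$bounds)
  invisible(x)
}

#' Tidy a feature normalizer
#'
#' @param x An `als_normalizer`.
#' @param ... Unused.
#' @return A tibble of per-feature min/max bounds.
#' @method tidy als_normalizer
#' @export
tidy.als_normalizer <- function(x, ...) x$bounds

#' Serialize a normalizer to JSON
#'
#' @param normalizer An `als_normalizer`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normalizer <- function(normalizer, path) {
  jsonlite::write_json(
    list(
      bounds = normalizer$bounds,
      encoding = lapply(normalizer$encoding, as.list),
      features = normalizer$features
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a normalizer from JSON
#'
#' @param path JSON file written by [write_normalizer()].
#' @return An `als_normalizer`.
#' @export
read_normalizer <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      bounds = tibble::as_tibble(raw$bounds),
      encoding = lapply(raw$encoding, unlist),
      features = raw$features
    ),
    class = "als_normalizer"
  )
}
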