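#' Evaluate a zone model on a projected validation cohort
#'
#' Assigns each validation patient to a survival zone, tabulates the
#' per-zone deceased/survived counts, and builds the aggregate accounting:
#' expected survivors from zone populations and development rates, the
#' maximal-overlap approximate confusion matrix against actual survivors,
#' and the classification metrics.
#'
#' @param model An `als_zones` fitted on development data.
#' @param projected Validation tibble with `x`, `y` in `[0, 1]` and known
#'   logical `survived_12m`.
#' @return A list of class `als_zone_evaluation`: `by_zone` (per-zone
#'   counts, observed rate, share of the cohort), `predicted` (expected
#'   survivor accounting), `confusion`, `metrics`, `overall_rate`.
#' @export
evaluate_zones <- function(model, projected) {
  stopifnot(inherits(model, "als_zones"))
  check_projected_outcomes(projected)
  assigned <- assign_zone(model, projected$x, projected$y)
  by_zone <- tibble::tibble(
    zone = assigned$zone,
    survived = projected$survived_12m
  ) |>
    dplyr::count(.data$zone, name = "n_zone") |>
    dplyr::right_join(tibble::tibble(zone = seq_len(model$k)), by = "zone") |>
    dplyr::mutate(n_zone = dplyr::coalesce(.data$n_zone, 0L))
  survivors <- vapply(seq_len(model$k), function(j)
    sum(projected$survived_12m[assigned$zone == j]), integer(1))
  by_zone <- by_zone |>
    dplyr::mutate(
      label = model$zones$label,
      survived = survivors,
      deceased = .data$n_zone - survivors,
      observed_rate = ifelse(.data$n_zone > 0,
                             survivors / .data$n_zone, NA_real_),
      model_rate = model$zones$rate,
      share = .data$n_zone / sum(.data$n_zone)
    ) |>
    dplyr::select("zone", "label", "deceased", "survived", "n_zone",
                  "share", "observed_rate", "model_rate")
  predicted <- predicted_survivor_count(by_zone$n_zone, by_zone$model_rate)
  actual <- sum(projected$survived_12m)
  confusion <- approx_confusion(predicted$predicted_survivors, actual,
                                nrow(projected))
  structure(
    list(
      by_zone = by_zone,
      predicted = predicted,
      actual_survivors = actual,
      overall_rate = actual / nrow(projected),
      confusion = confusion,
      metrics = classification_metrics(confusion)
    ),
    class = "als_zone_evaluation"
  )
}

#' @export
print.als_zone_evaluation <- function(x, ...) {
  cat("Zone-model evaluation on validation data\n")
  print(x$by_zone)
  cat(sprintf("Observed overall survival: %.0f%% (%d / %d)\n",
              100 * x$overall_rate, x$actual_survivors,
              sum(x$by_zone$n_zone)))
  cat(sprintf("Predicted survivors: %d, deaths: %d\n",
              x$predicted$predicted_survivors, x$predicted$predicted_deaths))
  cat("Approximate confusion matrix (maximal overlap):\n")
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

#' Tidy a zone evaluation
#'
#' @param x An `als_zone_evaluation`.
#' @param ... Unused.
#' @return The per-zone validation tibble.
#' @method tidy als_zone_evaluation
#' @export
tidy.als_zone_evaluation <- function(x, ...) x$by_zone

#' One-row summary of a zone evaluation
#'
#' @param x An `als_zone_evaluation`.
#' @param ... Unused.
#' @return A tibble combining the confusion-matrix entries and the metrics.
#' @method glance als_zone_evaluation
#' @export
glance.als_zone_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n = sum(x$by_zone$n_zone),
      actual_survivors = x$actual_survivors,
      predicted_survivors = x$predicted$predicted_survivors,
      overall_rate = x$overall_rate
    ),
    x$confusion, x$metrics
  )
}

#' Run the end-to-end develop/zone/validate pipeline
#'
#' Executes the full workflow: complete-case filtering of both cohorts,
#' min-max normalisation fitted on development data, 2D embedding fit,
#' equal-population zone segmentation, projection of the validation cohort
#' into the learnt space, zone assignment and evaluation. When `out_dir` is
#' given, writes the normalizer, embedding, zone model, projected
#' coordinates, evaluation report and a manifest (config hash, seed,
#' versions); partial artifacts are removed if a stage fails.
#'
#' @param dev,val Cohort tibbles (or CSV paths read with [read_cohort()]).
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @param axis Zoning axis, `"y"` or `"x"`.
#' @param k Number of zones.
#' @param confidence_level Confidence level for Wald widths.
#' @param cell_size Cell size of the diagnostic survival map.
#' @param n_neighbors,min_dist,metric Embedding hyperparameters.
#' @param seed Embedding seed.
#' @return A list of class `als_pipeline`: `normalizer`, `embedding`,
#'   `zones`, `cell_map`, `dev_projected`, `val_projected`, `evaluation`,
#'   `manifest`.
#' @export
run_pipeline <- function(dev, val, out_dir = NULL,
                         axis = "y", k = 3, confidence_level = 0.95,
                         cell_size = 0.1, n_neighbors = 15, min_dist = 0.1,
                         metric = "euclidean", seed = 42L) {
  if (is.character(dev)) dev <- read_cohort(dev, "development")
  if (is.character(val)) val <- read_cohort(val, "validation")
  written <- character(0)
  config <- list(axis = axis, k = k, confidence_level = confidence_level,
                 cell_size = cell_size, n_neighbors = n_neighbors,
                 min_dist = min_dist, metric = metric, seed = seed)
  stage <- "complete_case_filter"
  result <- tryCatch({
    dev_cc <- complete_case_filter(dev)
    val_cc <- complete_case_filter(val)
    message(sprintf("[%s] development %d -> %d, validation %d -> %d",
                    stage, nrow(dev), nrow(dev_cc), nrow(val), nrow(val_cc)))

    stage <- "fit_normalizer"
    normalizer <- fit_normalizer(dev_cc)
    xdev <- apply_normalizer(normalizer, dev_cc)
    xval <- apply_normalizer(normalizer, val_cc)

    stage <- "fit_embedding"
    embedding <- fit_embedding(xdev, n_neighbors = n_neighbors,
                               min_dist = min_dist, metric = metric,
                               seed = seed)
    dev_projected <- dplyr::bind_cols(
      embedding$embedding,
      dev_cc[c("patient_id", "survived_12m", "survival_months", "alsfrs_12m")]
    )
    message(sprintf("[%s] embedded %d development patients", stage,
                    nrow(dev_projected)))

    stage <- "fit_zones"
    zones <- fit_zones(dev_projected, axis = axis, k = k,
                       confidence_level = confidence_level)
    cell_map <- build_cell_map(dev_projected, cell_size = cell_size,
                               confidence_level = confidence_level)

    stage <- "transform_validation"
    val_projected <- dplyr::bind_cols(
      transform_cohort(embedding, xval),
      val_cc[c("patient_id", "survived_12m", "survival_months", "alsfrs_12m")]
    )
    message(sprintf("[%s] projected %d validation patients", stage,
                    nrow(val_projected)))

    stage <- "evaluate"
    evaluation <- evaluate_zones(zones, val_projected)

    manifest <- list(
      config = config,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("alsmap")),
      r_version = as.character(getRversion()),
      n_development = nrow(dev_projected),
      n_validation = nrow(val_projected)
    )

    if (!is.null(out_dir)) {
      stage <- "write_artifacts"
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wp <- function(p) { written <<- c(written, p); p }
      write_normalizer(normalizer, wp(file.path(out_dir, "normalizer.json")))
      write_embedding(embedding, wp(file.path(out_dir, "embedding")))
      write_zones(zones, wp(file.path(out_dir, "zones.json")))
      readr::write_csv(tibble::as_tibble(cell_map),
                       wp(file.path(out_dir, "cell_map.csv")))
      readr::write_csv(dev_projected,
                       wp(file.path(out_dir, "development_projected.csv")))
      readr::write_csv(val_projected,
                       wp(file.path(out_dir, "validation_projected.csv")))
      jsonlite::write_json(
        list(by_zone = evaluation$by_zone, predicted = evaluation$predicted,
             confusion = evaluation$confusion, metrics = evaluation$metrics,
             overall_rate = evaluation$overall_rate),
        wp(file.path(out_dir, "report.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      jsonlite::write_json(manifest, wp(file.path(out_dir, "manifest.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }

    list(normalizer = normalizer, embedding = embedding, zones = zones,
         cell_map = cell_map, dev_projected = dev_projected,
         val_projected = val_projected, evaluation = evaluation,
         manifest = manifest)
  }, error = function(e) {
    unlink(written, recursive = TRUE)
    abort(paste0("Pipeline failed at stage '", stage, "'"), parent = e)
  })
  structure(result, class = "als_pipeline")
}

#' Prognosis for a single new patient
#'
#' The worked single-patient path: derives the functional decline rate from
#' baseline ALSFRS and symptom duration, normalizes the seven baseline
#' predictors with the development bounds, projects the patient into the
#' learnt 2D space, and returns the survival-rate zone prognosis.
#'
#' @param pipeline An `als_pipeline` from [run_pipeline()], or any list with
#'   `normalizer`, `embedding` and `zones` components.
#' @param gender `"male"` or `"female"`.
#' @param onset `"spinal"` or `"bulbar"`.
#' @param age Years.
#' @param symptom_duration_months Months since symptom onset (> 0).
#' @param weight_kg Baseline weight in kg.
#' @param alsfrs_baseline Baseline ALSFRS score in `[0, 40]`.
#' @return A one-row tibble: decline rate, projected `x`, `y`, zone label,
#'   survival `rate` and the confidence interval `lower`/`upper`.
#' @export
predict_patient <- function(pipeline, gender, onset, age,
                            symptom_duration_months, weight_kg,
                            alsfrs_baseline) {
  fields <- list(gender = rlang::maybe_missing(gender),
                 onset = rlang::maybe_missing(onset),
                 age = rlang::maybe_missing(age),
                 symptom_duration_months =
                   rlang::maybe_missing(symptom_duration_months),
                 weight_kg = rlang::maybe_missing(weight_kg),
                 alsfrs_baseline = rlang::maybe_missing(alsfrs_baseline))
  absent <- names(fields)[vapply(fields, function(f)
    rlang::is_missing(f) || is.null(f) || (length(f) == 1 && is.na(f)),
    logical(1))]
  if (length(absent) > 0)
    abort(paste0("Missing baseline predictor(s): ",
                 paste(absent, collapse = ", ")))
  record <- tibble::tibble(
    patient_id = "new", gender = gender, onset = onset, age = age,
    symptom_duration_months = symptom_duration_months,
    weight_kg = weight_kg, alsfrs_baseline = alsfrs_baseline
  )
  validate_cohort(record)
  record <- derive_decline_rate(record)
  features <- apply_normalizer(pipeline$normalizer, record)
  coords <- transform_cohort(pipeline$embedding, features)
  prognosis <- assign_zone(pipeline$zones, coords$x, coords$y)
  dplyr::bind_cols(
    tibble::tibble(decline_rate = record$decline_rate), prognosis
  )
}
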