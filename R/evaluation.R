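# round half away from zero (round() in R rounds half to even, which would
# turn 159.5 expected survivors into 160 or 159 depending on parity)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expected survivor count from zone populations and rates
#'
#' The zone model outputs a survival probability per zone, not a per-patient
#' label, so the number of predicted survivors is approximated by applying
#' each zone's survival rate to its population and summing the per-zone
#' rounded expected counts (rounding half away from zero).
#'
#' @param zone_counts Integer vector of zone populations.
#' @param zone_rates Survival rate per zone, in `[0, 1]`, same length.
#' @return A one-row tibble: `predicted_survivors`, `predicted_deaths`, `n`.
#' @examples
#' predicted_survivor_count(c(160, 211, 275), c(0.90, 0.80, 0.58))
#' @export
predicted_survivor_count <- function(zone_counts, zone_rates) {
  if (length(zone_counts) != length(zone_rates))
    abort("`zone_counts` and `zone_rates` must have the same length.")
  if (any(zone_rates < 0 | zone_rates > 1))
    abort("`zone_rates` must lie in [0, 1].")
  if (any(zone_counts < 0)) abort("`zone_counts` must be non-negative.")
  survivors <- sum(round_half_away(zone_counts * zone_rates))
  tibble::tibble(
    predicted_survivors = survivors,
    predicted_deaths = sum(zone_counts) - survivors,
    n = sum(zone_counts)
  )
}

#' Maximal-overlap approximate confusion matrix
#'
#' When a model predicts only aggregate survivor counts (not per-patient
#' labels), predicted and actual counts are matched as far as possible:
#' `TP = min(predicted, actual)`, the excess on either side becoming FP or
#' FN (one of the two is always zero), and `TN` the remainder. This is the
#' most favourable labelling consistent with the two totals.
#'
#' @param predicted_survivors,actual_survivors,n Non-negative counts, with
#'   both survivor counts at most `n`.
#' @return An object of class `als_confusion`: a one-row tibble with
#'   `TP`, `FP`, `FN`, `TN`.
#' @examples
#' approx_confusion(473, 433, 646)
#' @export
approx_confusion <- function(predicted_survivors, actual_survivors, n) {
  if (predicted_survivors < 0 || actual_survivors < 0 || n < 0)
    abort("Counts must be non-negative.")
  if (predicted_survivors > n || actual_survivors > n)
    abort("Survivor counts cannot exceed the cohort size `n`.")
  tp <- min(predicted_survivors, actual_survivors)
  fp <- max(predicted_survivors - actual_survivors, 0)
  fn <- max(actual_survivors - predicted_survivors, 0)
  new_confusion(tp, fp, fn, n - tp - fp - fn)
}

new_confusion <- function(tp, fp, fn, tn) {
  out <- tibble::tibble(TP = as.integer(tp), FP = as.integer(fp),
                        FN = as.integer(fn), TN = as.integer(tn))
  class(out) <- c("als_confusion", class(out))
  out
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision (positive predictive value), specificity
#' (true negative rate), recall (sensitivity), balanced accuracy
#' (mean of recall and specificity), the mean of precision and recall, and
#' the F1 measure (harmonic mean of precision and recall). Ratios with a
#' zero denominator are reported as `NA` rather than 0.
#'
#' @param cm An `als_confusion` or anything with `TP`, `FP`, `FN`, `TN`
#'   fields.
#' @return A one-row tibble of metrics, all in `[0, 1]` (or `NA`).
#' @export
classification_metrics <- function(cm) {
  tp <- cm$TP; fp <- cm$FP; fn <- cm$FN; tn <- cm$TN
  n <- tp + fp + fn + tn
  if (n == 0) abort("Confusion matrix is empty.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  specificity <- ratio(tn, tn + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  tibble::tibble(
    accuracy = (tp + tn) / n,
    precision = precision,
    specificity = specificity,
    recall = recall,
    balanced_accuracy = (recall + specificity) / 2,
    mean_precision_recall = (precision + recall) / 2,
    f1 = f1
  )
}

# Exact confusion matrix from per-patient predictions.
exact_confusion <- function(predicted, actual) {
  new_confusion(
    sum(predicted & actual), sum(predicted & !actual),
    sum(!predicted & actual), sum(!predicted & !actual)
  )
}

#' Logistic-regression and random-forest baselines
#'
#' Fits the two standard supervised classifiers on development features and
#' predicts 1-year survival on the validation cohort, for comparison with the
#' zone model. Unlike the zone model, these produce per-patient labels, so
#' their confusion matrices are exact. Predictions threshold the estimated
#' survival probability at 0.5.
#'
#' @param dev,val Cohort tibbles with complete predictors and known
#'   `survived_12m`.
#' @param feature_set `"all7"` (all baseline predictors) or `"age_alsfrs"`
#'   (age and baseline ALSFRS only).
#' @param num_trees Trees in the random forest (default 100).
#' @param seed Seed for the forest.
#' @return A tibble, one row per model, with the confusion-matrix entries
#'   and all classification metrics.
#' @export
run_baselines <- function(dev, val, feature_set = c("all7", "age_alsfrs"),
                          num_trees = 100, seed = 42L) {
  feature_set <- match.arg(feature_set)
  norm <- fit_normalizer(dev)
  features <- if (feature_set == "age_alsfrs")
    c("age", "alsfrs_baseline") else PREDICTORS
  xdev <- apply_normalizer(norm, dev)[features]
  xval <- apply_normalizer(norm, val)[features]
  ydev <- dev$survived_12m
  yval <- val$survived_12m
  if (any(is.na(ydev)) || any(is.na(yval)))
    abort("Outcomes must be known in both cohorts.")
  if (length(unique(ydev)) < 2)
    abort("Development outcome has a single class; cannot train baselines.")

  lr <- stats::glm(y ~ ., data = cbind(xdev, y = ydev), family = "binomial")
  lr_pred <- stats::predict(lr, newdata = xval, type = "response") >= 0.5

  set.seed(seed)
  rf <- ranger::ranger(
    y ~ ., data = cbind(xdev, y = factor(ydev)), num.trees = num_trees,
    probability = TRUE, seed = seed, num.threads = 1
  )
  rf_pred <- stats::predict(rf, data = xval,
                            num.threads = 1)$predictions[, "TRUE"] >= 0.5

  dplyr::bind_rows(
    logistic_regression = dplyr::bind_cols(
      exact_confusion(lr_pred, yval),
      classification_metrics(exact_confusion(lr_pred, yval))),
    random_forest = dplyr::bind_cols(
      exact_confusion(rf_pred, yval),
      classification_metrics(exact_confusion(rf_pred, yval))),
    .id = "model"
  ) |>
    dplyr::mutate(feature_set = feature_set, .after = "model")
}

#' Kullback-Leibler divergence between two histogram distributions
#'
#' Diagnostic for distribution shift between development and validation
#' samples of one variable. Both samples are binned on a shared grid spanning
#' their pooled range; bin counts get Laplace (+1) smoothing so empty bins
#' never produce infinities; the divergence is
#' \eqn{\sum_i p_i \log(p_i / q_i)} in nats, with the development histogram
#' as `p` and validation as `q`. KL is asymmetric and non-negative, 0 only
#' when the smoothed histograms agree exactly.
#'
#' @param dev_values,val_values Non-empty numeric samples.
#' @param bins Number of shared bins (>= 2), default 20.
#' @return KL divergence in nats.
#' @export
kl_divergence <- function(dev_values, val_values, bins = 20) {
  if (length(dev_values) == 0 || length(val_values) == 0)
    abort("Samples must be non-empty.")
  if (bins < 2) abort("`bins` must be at least 2.")
  rng <- range(c(dev_values, val_values))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  count <- function(v) {
    idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1),
                bins)
    tabulate(idx, nbins = bins)
  }
  p <- (count(dev_values) + 1) / (length(dev_values) + bins)
  q <- (count(val_values) + 1) / (length(val_values) + bins)
  kl_discrete(p, q)
}

#' KL divergence between two discrete distributions
#'
#' @param p,q Probability vectors of equal length, each summing to 1; all
#'   entries of `q` must be positive wherever `p` is.
#' @return `sum(p * log(p / q))` in nats.
#' @export
kl_discrete <- function(p, q) {
  if (length(p) != length(q)) abort("`p` and `q` must have equal length.")
  nz <- p > 0
  if (any(q[nz] == 0)) abort("`q` must be positive wherever `p` is.")
  sum(p[nz] * log(p[nz] / q[nz]))
}
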