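test_that("expected survivors sum per-zone rounded counts, half away from zero", {
  res <- predicted_survivor_count(c(160, 211, 275), c(0.90, 0.80, 0.58))
  expect_equal(res$predicted_survivors, 144 + 169 + 160)
  expect_equal(res$predicted_deaths, 646 - 473)
  expect_equal(predicted_survivor_count(10, 1.0)$predicted_survivors, 10)
  # 3 * 0.5 = 1.5 must round away from zero, to 2
  expect_equal(predicted_survivor_count(3, 0.5)$predicted_survivors, 2)
  expect_error(predicted_survivor_count(c(10, 20), 0.5), "length")
  expect_error(predicted_survivor_count(10, 1.2), "\\[0, 1\\]")
})

test_that("maximal-overlap confusion matrix matches both branches by hand", {
  over <- approx_confusion(473, 433, 646)
  expect_equal(unlist(over[c("TP", "FP", "FN", "TN")]),
               c(TP = 433L, FP = 40L, FN = 0L, TN = 173L))
  under <- approx_confusion(400, 433, 646)
  expect_equal(unlist(under[c("TP", "FP", "FN", "TN")]),
               c(TP = 400L, FP = 0L, FN = 33L, TN = 213L))
  none <- approx_confusion(0, 0, 10)
  expect_equal(unlist(none[c("TP", "FP", "FN", "TN")]),
               c(TP = 0L, FP = 0L, FN = 0L, TN = 10L))
  expect_error(approx_confusion(-1, 3, 10), "non-negative")
  expect_error(approx_confusion(11, 3, 10), "exceed")
})

test_that("maximal overlap always conserves n and zeroes one error type", {
  set.seed(8)
  for (trial in 1:50) {
    n <- sample(1:1000, 1)
    pred <- sample(0:n, 1)
    act <- sample(0:n, 1)
    cm <- approx_confusion(pred, act, n)
    expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, n)
    expect_true(cm$FP == 0 || cm$FN == 0)
    expect_true(all(unlist(cm) >= 0))
  }
})

test_that("classification metrics match the printed validation row", {
  m <- classification_metrics(approx_confusion(473, 433, 646))
  expect_equal(m$accuracy, 606 / 646, tolerance = 1e-12)
  expect_equal(m$precision, 433 / 473, tolerance = 1e-12)
  expect_equal(round(m$precision, 3), 0.915)
  expect_equal(m$specificity, 173 / 213, tolerance = 1e-12)
  expect_equal(m$recall, 1)
  expect_equal(round(100 * m$balanced_accuracy), 91)
  expect_equal(round(100 * m$f1), 96)
  expect_equal(round(100 * m$accuracy), 94)
  # balanced accuracy is the recall/specificity mean; the precision/recall
  # mean is exposed separately
  expect_equal(m$balanced_accuracy, (m$recall + m$specificity) / 2)
  expect_equal(m$mean_precision_recall, (m$precision + m$recall) / 2)
})

test_that("metric edge cases: perfect, uniform and undefined ratios", {
  perfect <- classification_metrics(
    tibble::tibble(TP = 10L, FP = 0L, FN = 0L, TN = 10L))
  expect_true(all(unlist(perfect) == 1))
  uniform <- classification_metrics(
    tibble::tibble(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_true(all(unlist(uniform) == 0.5))
  no_pos <- classification_metrics(
    tibble::tibble(TP = 0L, FP = 0L, FN = 5L, TN = 5L))
  expect_true(is.na(no_pos$precision))
  expect_equal(no_pos$recall, 0)
})

test_that("KL divergence: closed form, asymmetry, non-negativity, errors", {
  expect_equal(kl_discrete(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(round(kl_discrete(c(0.5, 0.5), c(0.25, 0.75)), 4), 0.1438)
  expect_false(isTRUE(all.equal(kl_discrete(c(0.5, 0.5), c(0.25, 0.75)),
                                kl_discrete(c(0.25, 0.75), c(0.5, 0.5)))))
  x <- rnorm(500)
  expect_equal(kl_divergence(x, x, bins = 15), 0, tolerance = 1e-12)
  set.seed(4)
  for (trial in 1:20) {
    a <- rnorm(200, sample(0:3, 1))
    b <- rnorm(300, sample(0:3, 1))
    expect_gte(kl_divergence(a, b), 0)
  }
  expect_error(kl_divergence(numeric(0), rnorm(10)), "non-empty")
  expect_error(kl_divergence(rnorm(10), rnorm(10), bins = 1), "bins")
})

test_that("smoothed histograms keep shifted samples at positive divergence", {
  set.seed(9)
  a <- rnorm(2000, 0)
  b <- rnorm(2000, 1.5)
  expect_gt(kl_divergence(a, b), 0.2)
  expect_gt(kl_divergence(a, b), kl_divergence(a, rnorm(2000, 0.2)))
})

test_that("baselines beat the majority rule when the signal is strong", {
  strong <- c(age = -1, alsfrs_baseline = 1.5, decline_rate = 2.5,
              weight_kg = 0.3, onset_bulbar = -0.4)
  dev_spec <- cohort_preset("overall", n = 900, seed = 51,
                            outcome_coefficients = strong)
  dev_spec$target_survival <- 0.5
  val_spec <- cohort_preset("overall", n = 450, seed = 52,
                            outcome_coefficients = strong)
  val_spec$target_survival <- 0.5
  dev <- generate_cohort(dev_spec)
  val <- generate_cohort(val_spec)
  majority <- max(mean(val$survived_12m), 1 - mean(val$survived_12m))
  res <- run_baselines(dev, val, feature_set = "all7")
  expect_setequal(res$model, c("logistic_regression", "random_forest"))
  expect_true(all(res$accuracy > majority))
  expect_true(all(res$TP + res$FP + res$FN + res$TN == nrow(val)))
})

test_that("baselines on zero-signal data sit at the majority rate", {
  null_spec <- function(seed) {
    s <- cohort_preset("overall", n = 700, seed = seed,
                       outcome_coefficients = c(age = 0))
    s$target_survival <- 0.6
    s
  }
  dev <- generate_cohort(null_spec(61))
  val <- generate_cohort(null_spec(62))
  majority <- max(mean(val$survived_12m), 1 - mean(val$survived_12m))
  res <- run_baselines(dev, val, feature_set = "age_alsfrs")
  expect_true(all(abs(res$accuracy - majority) < 0.1))
})

test_that("degenerate single-class training is refused", {
  dev <- make_cohort(60, survived_12m = rep(TRUE, 60))
  val <- make_cohort(20)
  expect_error(run_baselines(dev, val), "single class")
})
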