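# alsmap

Zone-based 1-year survival prognosis for amyotrophic lateral sclerosis
(ALS) from baseline clinical features.

ALS is a progressive motor-neuron disease with a typical survival of 3–5
years from onset but considerable heterogeneity between patients, which
makes individual prognosis both important (care planning, trial
stratification) and hard. `alsmap` implements a deliberately simple,
uncertainty-aware prognosis model for clinicians and methods researchers:

1. Seven baseline predictors — gender, region of onset (spinal/bulbar),
   age, symptom duration, weight, the ALSFRS functional score (0–40, 40 =
   unimpaired), and the derived functional decline rate

   ```
   decline rate = −(40 − ALSFRS_baseline) / symptom duration   [points/month]
   ```

   are min–max normalised to [0, 1] and projected into a 2D embedding with
   UMAP (via `uwot`), fitted on a development cohort and frozen.
2. The projection, rescaled to the unit square, is segmented along one axis
   into *k* equally populated zones (default *k* = 3). Each zone carries its
   empirical 1-year survival rate *P* with a Wald binomial confidence width

   ```
   width = 2 z_α √(P(1 − P) / N),   α = 1 − confidence level
   ```

3. A new patient is normalised with the development bounds, projected with
   the learnt mapping, and receives the survival rate and interval of the
   zone their coordinates fall in.

Validation-side accounting follows the zone-probability logic: expected
survivors are the per-zone rounded products `n_zone × P_zone`, compared to
actual survivors through a maximal-overlap approximate confusion matrix
(`TP = min(predicted, actual)`), from which accuracy, precision,
specificity, recall, balanced accuracy and F1 are derived. Logistic
regression and random-forest baselines, and a Kullback–Leibler
distribution-shift diagnostic, are included for comparison.

Because the clinical-trial and registry datasets behind such models are not
redistributable, the package ships a synthetic cohort generator
(`cohort_preset()` / `generate_cohort()`) whose per-dataset predictor
moments, ranges and survival rates emulate the published summaries of four
ALS cohorts (three trial datasets and one real-world registry), with a
calibrated logistic link between risk factors and survival. The whole
pipeline is exercised end-to-end on generated data.

## Worked example

```r
library(alsmap)

dev <- generate_cohort(cohort_preset("overall",    n = 2000, seed = 11))
val <- generate_cohort(cohort_preset("real_world", n = 646,  seed = 12))

res <- run_pipeline(dev, val)
res$zones
#> Survival-rate zone model: 3 equally populated zones along the y axis
#>   development n = 2000 (1506 survivors), 95% confidence
#>   cuts: 0.7397, 0.8292
#> # A tibble: 3 × 6
#>    zone label      n survivors  rate  width
#>   <int> <chr>  <int>     <int> <dbl>  <dbl>
#> 1     1 zone_1   667       518 0.777 0.0632
#> 2     2 zone_2   667       420 0.630 0.0733
#> 3     3 zone_3   666       568 0.853 0.0538
```

Each zone holds a third of the development cohort; e.g. zone 3 patients
survived one year in 85.3% of cases, ± 2.7 percentage points at 95%
confidence (the `width` column is the full interval width). Note the
survival gradient need not be monotone along the axis: the embedding's
orientation is arbitrary and data-dependent.

```r
predict_patient(res, gender = "male", onset = "spinal", age = 57,
                symptom_duration_months = 13, weight_kg = 71,
                alsfrs_baseline = 33)
#> # A tibble: 1 × 9
#>   decline_rate     x     y  zone label   rate  width lower upper
#>          <dbl> <dbl> <dbl> <int> <chr>  <dbl>  <dbl> <dbl> <dbl>
#> 1       -0.538 0.823 0.857     3 zone_3 0.853 0.0538 0.826 0.880
```

This patient's functional decline rate is −0.54 points/month; they project
to (0.82, 0.86), fall into zone 3, and get a 1-year survival estimate of
85% (95% CI 83–88%).

```r
glance(res$evaluation)   # validation accounting on the synthetic registry
#>     n actual_survivors predicted_survivors overall_rate  TP FP FN  TN accuracy ...
#> 1 646              435                 484        0.673 435 49  0 162    0.924 ...
```

`tidy()`, `glance()` and `autoplot()` methods are provided for the zone
model, the cell map and the evaluation; `inst/scripts/alsmap.R` is a thin
command-line front end (`simulate`, `fit`, `predict`, `evaluate`).

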