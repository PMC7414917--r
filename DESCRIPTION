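Package: alsmap
Title: One-Year Survival Prognosis for ALS via Manifold Projection and
    Survival-Rate Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a 1-year survival prognosis pipeline for
    amyotrophic lateral sclerosis (ALS). Baseline clinical predictors
    (gender, region of onset, age, symptom duration, baseline weight,
    baseline ALSFRS score and the derived functional decline rate) are
    min-max normalised, projected into a 2D manifold embedding (UMAP),
    and the projection is segmented into equally populated zones along
    one axis, each carrying an empirical survival rate with a Wald
    binomial confidence width. New patients are projected into the
    learnt space and receive their zone's survival rate as a prognosis.
    Includes a synthetic patient-cohort generator with configurable
    predictor distributions and a logistic outcome model, validation-side
    accounting (expected survivor counts, a maximal-overlap approximate
    confusion matrix, classification metrics), logistic-regression and
    random-forest baselines, and distribution-shift diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
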