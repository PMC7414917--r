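# Shared fixtures and independent oracles.

# Small hand-written cohort tibble; `...` overrides columns.
make_cohort <- function(n = 6, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    gender = rep(c("male", "female"), length.out = n),
    onset = rep(c("spinal", "bulbar"), length.out = n),
    age = seq(40, 70, length.out = n),
    symptom_duration_months = seq(6, 24, length.out = n),
    weight_kg = seq(55, 90, length.out = n),
    alsfrs_baseline = seq(20, 38, length.out = n),
    survived_12m = rep(c(TRUE, TRUE, FALSE), length.out = n),
    survival_months = NA_real_,
    alsfrs_12m = NA_real_
  )
  base$decline_rate <- compute_decline_rate(base$alsfrs_baseline,
                                            base$symptom_duration_months)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# Projected cohort from explicit coordinates/outcomes.
make_projected <- function(y, survived, x = 0.5) {
  tibble::tibble(x = rep_len(x, length(y)), y = y, survived_12m = survived)
}

# Independent equal-population zoning oracle: each point's zone is the
# smallest j whose nearest-rank boundary ceiling(j*n/k) covers its rank
# (ties by input order). Enumerative, shares no code with fit_zones.
oracle_zone_membership <- function(coord, k) {
  n <- length(coord)
  r <- rank(coord, ties.method = "first")
  boundaries <- ceiling(seq_len(k) * n / k)
  vapply(r, function(ri) which(ri <= boundaries)[1], integer(1))
}

# Development cohort of 150 projected points whose three vertical zones have
# survival rates exactly 0.58 / 0.80 / 0.90 (29, 40 and 45 survivors out of
# 50), mirroring the printed zone rates from the bottom of the projection up.
make_reference_development <- function() {
  y <- (seq_len(150) - 0.5) / 150
  survived <- c(rep(c(TRUE, FALSE), c(29, 21)),
                rep(c(TRUE, FALSE), c(40, 10)),
                rep(c(TRUE, FALSE), c(45, 5)))
  make_projected(y, survived)
}

# Validation points distributed per the published real-world zone table:
# low zone 275 (133 survived), intermediate 211 (160), high 160 (140).
# Band edges sit safely inside the reference development's zone cuts
# (y = 0.330 and 0.663).
make_reference_validation <- function() {
  place <- function(n_total, n_surv, lo, hi) {
    make_projected(seq(lo, hi, length.out = n_total),
                   rep(c(TRUE, FALSE), c(n_surv, n_total - n_surv)))
  }
  dplyr::bind_rows(
    place(275, 133, 0.001, 0.32),
    place(211, 160, 0.34, 0.65),
    place(160, 140, 0.68, 0.999)
  )
}
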