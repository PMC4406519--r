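single_factor_config <- function(n, seed, curve = make_curve("linear", c(30, 0)),
                                 p_yes = 0.3, lo = 6, hi = 14) {
  cohort_config(
    n_patients = n, seed = seed,
    factor_specs = list(factor_spec("x", "uniform", lo = lo, hi = hi)),
    truth_curves = list(outcome = list(x = curve)),
    p_yes = c(outcome = p_yes)
  )
}

test_that("cohorts are empty at n = 0 and reproducible under the seed contract", {
  empty <- generate_cohort(single_factor_config(0, 1))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("patient_id", "x", "outcome") %in% names(empty)))

  a <- generate_cohort(single_factor_config(500, 7))
  b <- generate_cohort(single_factor_config(500, 7))
  expect_identical(a, b)
  c <- generate_cohort(single_factor_config(500, 8))
  expect_false(identical(a, c))
})

test_that("a constant 30% truth risk yields 30% prevalence within binomial error", {
  cohort <- generate_cohort(single_factor_config(10000, 42))
  prevalence <- mean(cohort$outcome == "yes")
  expect_lt(abs(prevalence - 0.30), 0.015) # ~3 binomial SEs at n = 10,000
})

test_that("factor marginals respect their truncation bounds and distributions", {
  cfg <- cohort_config(
    n_patients = 5000, seed = 3,
    factor_specs = default_factor_specs(),
    truth_curves = default_truth_curves(),
    p_yes = default_priors()
  )
  cohort <- generate_cohort(cfg)
  for (fs in cfg$factor_specs) {
    v <- cohort[[fs$name]]
    expect_true(all(v >= fs$lo & v <= fs$hi), label = fs$name)
  }
  # truncated-normal HbA1c: sample mean near the configured centre
  expect_lt(abs(mean(cohort$HbA1c) - 8), 0.15)
})

test_that("priors and marginals are relative frequencies with smoothing only when needed", {
  # 84 patients, 39 with the complication: the prior is exactly 39/84
  cohort <- tibble::tibble(
    patient_id = 1:84,
    HbA1c = runif(84, 6.5, 7.5),
    comp = rep(c("yes", "no"), c(39, 45))
  )
  schemes <- list(HbA1c = disc_scheme("HbA1c", c(6, 7, 8)))
  est <- estimate_priors(cohort, schemes)
  expect_equal(est$priors$p_yes, 39 / 84)
  expect_equal(sum(est$marginals$p), 1)

  # a cohort concentrated in one bin: that bin takes almost all the mass
  conc <- tibble::tibble(patient_id = 1:1000, HbA1c = rep(7.5, 1000), comp = "yes")
  est2 <- estimate_priors(conc, schemes)
  expect_gt(est2$marginals$p[est2$marginals$bin == "]7,8]"], 0.99)
  expect_true(all(est2$marginals$p > 0)) # empty bin smoothed, not zero
  expect_true(est2$priors$p_yes < 1) # all-yes prior smoothed into (0, 1)
})

test_that("estimated marginals converge to the configured bin masses", {
  cfg <- single_factor_config(50000, 11)
  cohort <- generate_cohort(cfg)
  scheme <- disc_scheme("x", seq(6, 14, by = 2))
  est <- estimate_priors(cohort, list(x = scheme))
  truth <- rep(0.25, 4) # uniform on [6, 14], equal-width bins
  se <- sqrt(truth * (1 - truth) / 50000)
  expect_true(all(abs(est$marginals$p - truth) < 3.5 * se))
})

test_that("values outside the configured bins are rejected", {
  cohort <- tibble::tibble(patient_id = 1, HbA1c = 9.5, comp = "yes")
  expect_error(
    estimate_priors(cohort, list(HbA1c = disc_scheme("HbA1c", c(6, 7, 8)))),
    "covered range"
  )
  expect_error(estimate_priors(cohort[0, ], list()), "empty")
})

test_that("binned risk tables drop sparse bins and keep representative order", {
  cfg <- single_factor_config(2000, 13, curve = make_curve("linear", c(-30, 6)))
  cohort <- generate_cohort(cfg)
  # a scheme extending beyond the sampled range leaves outer bins empty
  scheme <- disc_scheme("x", seq(2, 18, by = 1))
  tbl <- binned_risk_table(cohort, "x", "outcome", scheme, min_count = 20)
  expect_true(all(diff(tbl$factor_value) > 0))
  expect_true(all(tbl$factor_value > 6 & tbl$factor_value < 14))
  expect_error(
    binned_risk_table(cohort, "x", "outcome", scheme, min_count = 10000),
    "minimum count"
  )
})

test_that("a one-bin table is returned but flagged as unfittable", {
  cfg <- single_factor_config(500, 2, lo = 7.2, hi = 7.8)
  cohort <- generate_cohort(cfg)
  scheme <- disc_scheme("x", c(7, 8))
  expect_warning(
    tbl <- binned_risk_table(cohort, "x", "outcome", scheme),
    "one bin"
  )
  expect_equal(nrow(tbl), 1L)
})

test_that("generate-bin-refit recovers a linear truth at moderate size", {
  rec <- recover_pattern("linear", n_patients = 20000, seed = 5)
  expect_equal(rec$term, c("b0", "b1"))
  expect_lt(rec$relative_error[rec$term == "b1"], 0.1)
})

test_that("the copula knob induces the requested factor correlation", {
  specs <- list(
    factor_spec("u", "uniform", lo = 0, hi = 1),
    factor_spec("v", "uniform", lo = 0, hi = 1)
  )
  curve <- make_curve("linear", c(30, 0))
  cfg <- cohort_config(
    n_patients = 4000, seed = 9, factor_specs = specs,
    truth_curves = list(outcome = list(u = curve)),
    p_yes = c(outcome = 0.3),
    copula = matrix(c(1, 0.7, 0.7, 1), 2)
  )
  cohort <- generate_cohort(cfg)
  expect_gt(cor(cohort$u, cohort$v), 0.5)
  # independent by default
  cfg0 <- cohort_config(
    n_patients = 4000, seed = 9, factor_specs = specs,
    truth_curves = list(outcome = list(u = curve)),
    p_yes = c(outcome = 0.3)
  )
  cohort0 <- generate_cohort(cfg0)
  expect_lt(abs(cor(cohort0$u, cohort0$v)), 0.08)
})

test_that("cohorts survive a CSV round trip", {
  cohort <- generate_cohort(single_factor_config(50, 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back$x, cohort$x)
  expect_identical(back$outcome, cohort$outcome)
})
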