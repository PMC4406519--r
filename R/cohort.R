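#' Describe the marginal distribution of one risk factor
#'
#' Supported families: `"truncnorm"` (normal truncated to `[lo, hi]`,
#' sampled by inverse-CDF so draws are a deterministic function of the
#' uniform stream), `"uniform"` on `[lo, hi]`, and `"lognormal"` (log-normal
#' truncated to `[lo, hi]`).
#'
#' @param name Factor name.
#' @param dist Distribution family.
#' @param mean,sd Location/scale (`truncnorm`: on the natural scale;
#'   `lognormal`: of the underlying normal).
#' @param lo,hi Truncation bounds (also the support for `uniform`).
#' @return A `factor_spec`.
#' @export
factor_spec <- function(name, dist = c("truncnorm", "uniform", "lognormal"),
                        mean = 0, sd = 1, lo = -Inf, hi = Inf) {
  dist <- match.arg(dist)
  if (!(lo < hi)) rlang::abort("`lo` must be below `hi`.")
  if (dist == "uniform" && (!is.finite(lo) || !is.finite(hi))) {
    rlang::abort("Uniform factors need finite bounds.")
  }
  structure(
    list(name = name, dist = dist, mean = mean, sd = sd, lo = lo, hi = hi),
    class = "factor_spec"
  )
}

sample_factor <- function(spec, n) {
  u <- stats::runif(n)
  switch(spec$dist,
    uniform = spec$lo + u * (spec$hi - spec$lo),
    truncnorm = {
      plo <- stats::pnorm(spec$lo, spec$mean, spec$sd)
      phi <- stats::pnorm(spec$hi, spec$mean, spec$sd)
      stats::qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
    },
    lognormal = {
      plo <- stats::plnorm(spec$lo, spec$mean, spec$sd)
      phi <- stats::plnorm(spec$hi, spec$mean, spec$sd)
      stats::qlnorm(plo + u * (phi - plo), spec$mean, spec$sd)
    }
  )
}

#' Configure a synthetic cohort
#'
#' Defines the ground truth a simulated cohort is drawn from: per-factor
#' marginal distributions, per-complication dose-response truth curves, and
#' the rule combining per-factor risks into one outcome probability (the
#' same two-class naive-Bayes combination used for prediction, with the
#' configured prior). Factors are sampled independently, matching the
#' combiner's class-conditional independence assumption; an optional
#' Gaussian-copula correlation matrix is available for assumption-violation
#' studies and is off by default.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; fully determines the cohort.
#' @param factor_specs List of [factor_spec()] objects.
#' @param truth_curves Nested named list,
#'   `truth_curves[[complication]][[factor]]`, of `fitted_curve` objects
#'   (typically built with [make_curve()]) used as generating dose-response
#'   truths.
#' @param p_yes Named numeric vector of per-complication prior
#'   probabilities used by the combination rule.
#' @param copula Optional correlation matrix (factors x factors) for a
#'   Gaussian copula across factor marginals; `NULL` keeps factors
#'   independent.
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed, factor_specs, truth_curves,
                          p_yes, copula = NULL) {
  names(factor_specs) <- vapply(factor_specs, `[[`, character(1), "name")
  if (!is.null(copula)) {
    k <- length(factor_specs)
    if (!is.matrix(copula) || any(dim(copula) != k)) {
      rlang::abort("`copula` must be a square correlation matrix over the factors.")
    }
  }
  missing_p <- setdiff(names(truth_curves), names(p_yes))
  if (length(missing_p)) {
    rlang::abort(paste0("Missing `p_yes` for complication(s): ", toString(missing_p)))
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      factor_specs = factor_specs, truth_curves = truth_curves,
      p_yes = p_yes, copula = copula
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic patient cohort with known ground truth
#'
#' Samples factor values from the configured marginals, computes each
#' patient's true outcome probability per complication by combining the
#' truth curves with the configured prior (the [combine_posterior()]
#' formula), and draws binary outcomes from Bernoulli trials. Seeded and
#' reproducible: the same config always yields the identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A tibble with `patient_id`, one column per factor, and one
#'   `yes`/`no` column per complication.
#' @examples
#' cfg <- cohort_config(
#'   n_patients = 100, seed = 1,
#'   factor_specs = list(factor_spec("HbA1c", "uniform", lo = 6, hi = 12)),
#'   truth_curves = list(micro = list(HbA1c = make_curve("linear", c(-20, 4)))),
#'   p_yes = c(micro = 0.15)
#' )
#' generate_cohort(cfg)
#' @export
generate_cohort <- function(config) {
  n <- config$n_patients
  fs <- config$factor_specs
  with_local_seed(config$seed, {
    if (n == 0L) {
      vals <- lapply(fs, function(s) numeric())
    } else if (is.null(config$copula)) {
      vals <- lapply(fs, sample_factor, n = n)
    } else {
      z <- matrix(stats::rnorm(n * length(fs)), n) %*% chol(config$copula)
      u <- stats::pnorm(z)
      vals <- purrr::imap(fs, function(s, nm) {
        i <- match(nm, names(fs))
        switch(s$dist,
          uniform = s$lo + u[, i] * (s$hi - s$lo),
          truncnorm = {
            plo <- stats::pnorm(s$lo, s$mean, s$sd)
            phi <- stats::pnorm(s$hi, s$mean, s$sd)
            stats::qnorm(plo + u[, i] * (phi - plo), s$mean, s$sd)
          },
          lognormal = {
            plo <- stats::plnorm(s$lo, s$mean, s$sd)
            phi <- stats::plnorm(s$hi, s$mean, s$sd)
            stats::qlnorm(plo + u[, i] * (phi - plo), s$mean, s$sd)
          }
        )
      })
    }
    cohort <- tibble::as_tibble(c(list(patient_id = seq_len(n)), vals))
    for (comp in names(config$truth_curves)) {
      curves <- config$truth_curves[[comp]]
      if (n == 0L) {
        cohort[[comp]] <- character()
        next
      }
      q <- vapply(names(curves), function(f) {
        risk_percent_to_prob(
          suppressWarnings(predict(curves[[f]], cohort[[f]])),
          warn = FALSE
        )
      }, numeric(n))
      prob <- nb_combine(matrix(q, nrow = n), config$p_yes[[comp]])
      if (any(prob <= 0 | prob >= 1)) {
        rlang::abort(sprintf(
          "Combined outcome probability outside (0, 1) for complication '%s'; check truth curves and p_yes.",
          comp
        ))
      }
      cohort[[comp]] <- ifelse(stats::rbinom(n, 1, prob) == 1, "yes", "no")
    }
    cohort
  })
}

#' Estimate population priors from a cohort
#'
#' Relative frequencies of the factor bins (the `P(f_k)` marginals) and of
#' the complication classes (the `P(C)` priors). When any bin of a factor is
#' empty, Laplace add-one smoothing is applied across that factor's bins so
#' no state carries probability zero; class priors of exactly 0 or 1 are
#' likewise smoothed to keep them inside (0, 1).
#'
#' @param cohort A cohort tibble (see [generate_cohort()]); factor and
#'   complication columns are identified by the scheme names and the
#'   `yes`/`no` columns respectively.
#' @param schemes Named list of [disc_scheme()] objects, keyed by factor
#'   column name; every observed value must fall in a bin.
#' @return A list with `marginals` (tibble `factor`, `bin`, `p`) and
#'   `priors` (tibble `complication`, `p_yes`).
#' @export
estimate_priors <- function(cohort, schemes) {
  if (nrow(cohort) == 0L) rlang::abort("Cohort is empty.")
  marginals <- purrr::map_dfr(schemes, function(sch) {
    f <- sch$factor_name
    if (!f %in% names(cohort)) {
      rlang::abort(sprintf("Cohort has no column for factor '%s'.", f))
    }
    idx <- discretize_value(cohort[[f]], sch)
    counts <- tabulate(idx, nbins = length(sch$bins))
    if (any(counts == 0L)) counts <- counts + 1L
    tibble::tibble(factor = f, bin = sch$bins, p = counts / sum(counts))
  })
  comp_cols <- names(cohort)[vapply(cohort, function(col) {
    is.character(col) && all(col %in% c("yes", "no"))
  }, logical(1))]
  priors <- purrr::map_dfr(comp_cols, function(comp) {
    k <- sum(cohort[[comp]] == "yes")
    n <- nrow(cohort)
    p <- if (k == 0L || k == n) (k + 1) / (n + 2) else k / n
    tibble::tibble(complication = comp, p_yes = p)
  })
  list(marginals = marginals, priors = priors)
}

#' Empirical dose-response table from a cohort
#'
#' Bins the cohort on one factor and records, per bin, the representative
#' value and 100 times the observed outcome proportion — an empirical
#' dose-response dataset suitable for refitting, which is how
#' parameter-recovery of the curve-fitting stage is tested. Bins with fewer
#' than `min_count` patients are dropped; a single surviving bin is
#' returned but flagged as unfittable.
#'
#' @param cohort A cohort tibble.
#' @param factor,complication Column names of the factor and the outcome.
#' @param scheme A [disc_scheme()] for the factor.
#' @param min_count Minimum patients per retained bin.
#' @return A [dose_response()] dataset, one point per retained bin, sorted
#'   by representative value.
#' @export
binned_risk_table <- function(cohort, factor, complication, scheme,
                              min_count = 20L) {
  idx <- discretize_value(cohort[[factor]], scheme)
  outcome <- normalize_outcomes(cohort[[complication]])
  counts <- tabulate(idx, nbins = length(scheme$bins))
  keep <- which(counts >= min_count)
  if (!length(keep)) {
    rlang::abort(sprintf(
      "No bin reaches the minimum count of %d patients.", min_count
    ))
  }
  if (length(keep) == 1L) {
    rlang::warn("Only one bin retained; the resulting dataset cannot be fitted.")
  }
  risk <- vapply(keep, function(b) 100 * mean(outcome[idx == b]), numeric(1))
  dose_response(
    tibble::tibble(
      factor_value = scheme$representatives[keep],
      risk_percent = risk
    ),
    factor_name = factor, complication_name = complication
  )
}

#' Canonical recovery designs for the seven patterns
#'
#' For each pattern, a fixed generating truth — coefficients, factor range
#' and bin count — chosen so that every coefficient is identifiable from a
#' 50,000-patient cohort: coefficient magnitudes sit well clear of the
#' binomial sampling error of binned outcome proportions at that size (see
#' the methods vignette for the design analysis). Used by the
#' parameter-recovery tests and the acceptance script.
#'
#' @param pattern One of [curve_patterns].
#' @return A list: `curve` (the generating `fitted_curve`), `lo`, `hi`
#'   (uniform factor range) and `n_bins`.
#' @export
recovery_design <- function(pattern) {
  check_pattern(pattern)
  designs <- list(
    linear = list(coefficients = c(-30, 6), lo = 6, hi = 14, n_bins = 20L),
    logarithmic = list(coefficients = c(30, 15), lo = 1, hi = 21, n_bins = 20L),
    quadratic = list(coefficients = c(120, -26, 1.6), lo = 6, hi = 14, n_bins = 20L),
    cubic = list(coefficients = c(50, -15, 1.8, -0.05), lo = 1, hi = 21, n_bins = 25L),
    power = list(coefficients = c(10, 0.6), lo = 0.5, hi = 25, n_bins = 15L),
    s = list(coefficients = c(4.2, -8), lo = 2.5, hi = 25, n_bins = 20L),
    exponential = list(coefficients = c(6, 0.12), lo = 1, hi = 21, n_bins = 20L)
  )
  d <- designs[[pattern]]
  list(
    curve = make_curve(pattern, d$coefficients,
      factor_name = "x", complication_name = "outcome"
    ),
    lo = d$lo, hi = d$hi, n_bins = d$n_bins
  )
}

#' Generate-bin-refit parameter recovery for one pattern
#'
#' Runs the full recovery experiment: draw a cohort whose single factor is
#' uniform on the pattern's canonical range and whose outcome follows the
#' pattern's generating curve, bin it with [binned_risk_table()], refit the
#' same pattern, and report the recovered against the generating
#' coefficients.
#'
#' @param pattern One of [curve_patterns].
#' @param n_patients Cohort size.
#' @param seed Integer seed.
#' @return A tibble: `pattern`, `term`, `truth`, `estimate`,
#'   `relative_error`.
#' @export
recover_pattern <- function(pattern, n_patients = 50000L, seed = 1L) {
  design <- recovery_design(pattern)
  cfg <- cohort_config(
    n_patients = n_patients, seed = seed,
    factor_specs = list(factor_spec("x", "uniform", lo = design$lo, hi = design$hi)),
    truth_curves = list(outcome = list(x = design$curve)),
    p_yes = c(outcome = 0.5) # irrelevant for a single factor: posterior = q exactly
  )
  cohort <- generate_cohort(cfg)
  scheme <- disc_scheme(
    "x", seq(design$lo, design$hi, length.out = design$n_bins + 1L)
  )
  table <- binned_risk_table(cohort, "x", "outcome", scheme)
  fit <- fit_pattern(table, pattern)
  truth <- design$curve$coefficients
  tibble::tibble(
    pattern = pattern,
    term = names(truth),
    truth = unname(truth),
    estimate = unname(fit$coefficients),
    relative_error = abs(unname(fit$coefficients) - unname(truth)) / abs(unname(truth))
  )
}

#' Write and read cohort CSV files
#'
#' One row per patient: `patient_id`, factor columns, `yes`/`no`
#' complication columns.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv()`: the input invisibly; `read_cohort_csv()`:
#'   the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(cohort)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
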