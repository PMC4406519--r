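#' Default study configuration: factors, schemes, curves, network
#'
#' A ready-made configuration for the retinopathy/nephropathy study system:
#' four continuous factors (HbA1c %, diabetes duration in years, mean
#' arterial pressure in mmHg, albumin excretion rate in mg/day) and five
#' complications (micro- and macroalbuminuria; any, non-proliferative and
#' proliferative retinopathy). Albuminuria depends on HbA1c, duration and
#' MAP; the retinopathy nodes depend on HbA1c, duration and AER and
#' additionally on the two albuminuria nodes, whose `yes`/`no` states are
#' mapped onto representative AER values so the AER dose-response curves
#' can quantify those edges. Bin edges, representative values and the
#' truth-curve coefficients are package configuration — plausible clinical
#' ranges, not published estimates.
#'
#' @return `default_schemes()`: named list of [disc_scheme()] objects.
#' @export
default_schemes <- function() {
  list(
    HbA1c = disc_scheme("HbA1c", c(5, 6, 7, 8, 9, 10, 12, 14)),
    Duration = disc_scheme("Duration", c(0, 5, 10, 15, 20, 25)),
    MAP = disc_scheme("MAP", c(70, 80, 90, 100, 110, 130)),
    AER = disc_scheme("AER", c(0, 30, 100, 300, 1000))
  )
}

#' @rdname default_schemes
#' @return `default_factor_specs()`: list of [factor_spec()] marginals
#'   (HbA1c and MAP truncated normal, duration uniform, AER truncated
#'   log-normal).
#' @export
default_factor_specs <- function() {
  list(
    factor_spec("HbA1c", "truncnorm", mean = 8, sd = 1.5, lo = 5.2, hi = 13.8),
    factor_spec("Duration", "uniform", lo = 0.5, hi = 24.5),
    factor_spec("MAP", "truncnorm", mean = 97, sd = 10, lo = 70.5, hi = 129.5),
    factor_spec("AER", "lognormal", mean = 3.4, sd = 1.1, lo = 2, hi = 990)
  )
}

#' @rdname default_schemes
#' @return `default_truth_curves()`: nested list
#'   `curves[[complication]][[factor]]` of [make_curve()] objects, risks
#'   increasing in every factor and staying within (0, 100)% over the
#'   scheme ranges.
#' @export
default_truth_curves <- function() {
  list(
    micro = list(
      HbA1c = make_curve("linear", c(-20, 4), "HbA1c", "micro"),
      Duration = make_curve("logarithmic", c(2, 8), "Duration", "micro"),
      MAP = make_curve("linear", c(-32, 0.45), "MAP", "micro")
    ),
    macro = list(
      HbA1c = make_curve("exponential", c(0.3, 0.28), "HbA1c", "macro"),
      Duration = make_curve("linear", c(1, 0.8), "Duration", "macro"),
      MAP = make_curve("exponential", c(0.08, 0.04), "MAP", "macro")
    ),
    DR = list(
      HbA1c = make_curve("linear", c(-25, 5), "HbA1c", "DR"),
      Duration = make_curve("linear", c(2, 1.8), "Duration", "DR"),
      AER = make_curve("logarithmic", c(-5, 8), "AER", "DR")
    ),
    NPDR = list(
      HbA1c = make_curve("linear", c(-20, 4), "HbA1c", "NPDR"),
      Duration = make_curve("power", c(3, 0.8), "Duration", "NPDR"),
      AER = make_curve("logarithmic", c(-8, 7), "AER", "NPDR")
    ),
    PDR = list(
      HbA1c = make_curve("s", c(4.5, -25), "HbA1c", "PDR"),
      Duration = make_curve("quadratic", c(1, 0.1, 0.05), "Duration", "PDR"),
      AER = make_curve("power", c(0.5, 0.55), "AER", "PDR")
    )
  )
}

#' @rdname default_schemes
#' @return `default_priors()`: named vector of per-complication `p_yes`.
#' @export
default_priors <- function() {
  c(micro = 0.15, macro = 0.05, DR = 0.25, NPDR = 0.15, PDR = 0.05)
}

#' @rdname default_schemes
#' @return `default_network_spec()`: the [network_spec()] described above.
#'   Albuminuria states map onto AER representatives: `micro` yes/no to
#'   100/15 mg/day, `macro` yes/no to 500/15 mg/day.
#' @export
default_network_spec <- function() {
  alb_map <- list(
    micro = c(yes = 100, no = 15),
    macro = c(yes = 500, no = 15)
  )
  retinopathy <- function(name) {
    node_spec(name, "complication",
      parents = c("HbA1c", "Duration", "AER", "micro", "macro"),
      parent_value_map = alb_map
    )
  }
  network_spec(
    nodes = list(
      node_spec("HbA1c", "factor"),
      node_spec("Duration", "factor"),
      node_spec("MAP", "factor"),
      node_spec("AER", "factor"),
      node_spec("micro", "complication", parents = c("HbA1c", "Duration", "MAP")),
      node_spec("macro", "complication", parents = c("HbA1c", "Duration", "MAP")),
      retinopathy("DR"),
      retinopathy("NPDR"),
      retinopathy("PDR")
    ),
    schemes = default_schemes()
  )
}

#' @rdname default_schemes
#' @param complication A complication name among the defaults.
#' @return `default_edge_models()`: per-complication named model lists for
#'   [compile_network()], including the AER-scale curves standing behind
#'   the albuminuria-to-retinopathy edges.
#' @export
default_edge_models <- function() {
  curves <- default_truth_curves()
  models <- curves
  for (ret in c("DR", "NPDR", "PDR")) {
    # albuminuria parents are quantified through the AER curve of the child
    models[[ret]]$micro <- curves[[ret]]$AER
    models[[ret]]$macro <- curves[[ret]]$AER
  }
  models
}

#' @rdname default_schemes
#' @param n_patients,seed Cohort size and seed for estimating the root
#'   marginals and class priors.
#' @return `default_compiled_network()`: a [compile_network()] result with
#'   marginals and priors estimated from a fresh synthetic cohort.
#' @export
default_compiled_network <- function(n_patients = 5000L, seed = 20L) {
  cfg <- cohort_config(
    n_patients = n_patients, seed = seed,
    factor_specs = default_factor_specs(),
    truth_curves = default_truth_curves(),
    p_yes = default_priors()
  )
  cohort <- generate_cohort(cfg)
  est <- estimate_priors(cohort, default_schemes())
  compile_network(
    default_network_spec(),
    models = default_edge_models(),
    priors = est$priors,
    marginals = est$marginals
  )
}
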