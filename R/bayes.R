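#' Invert a conditional probability with population priors
#'
#' Converts a literature-derived P(complication | factor) into the
#' class-conditional P(factor | complication) needed by the naive-Bayes
#' product, via Bayes' theorem:
#' `P(f | C) = P(f) / P(C) * P(C | f)`.
#' Results above 1 signal mutually inconsistent inputs and are clipped to 1
#' with a warning.
#'
#' @param p_c_given_f P(complication | factor), in (0, 1\].
#' @param p_f Population marginal P(factor bin), in (0, 1\].
#' @param p_c Population prior P(complication), in (0, 1\].
#' @return P(factor | complication), in (0, 1\].
#' @examples
#' invert_conditional(0.5, 0.2, 0.4) # 0.25
#' @export
invert_conditional <- function(p_c_given_f, p_f, p_c) {
  args <- c(p_c_given_f = p_c_given_f, p_f = p_f, p_c = p_c)
  if (any(args <= 0) || any(args > 1)) {
    rlang::abort("All probabilities must lie in (0, 1].")
  }
  out <- p_f * p_c_given_f / p_c
  if (out > 1) {
    rlang::warn(sprintf(
      "Inverted probability %.4g exceeds 1 (inconsistent inputs); clipped to 1.", out
    ))
    out <- 1
  }
  out
}

# risk percent -> probability q = P(C = yes | f), with the documented clips
risk_percent_to_prob <- function(risk_percent, warn = TRUE) {
  lo <- 1e-4
  hi <- 100 - 1e-4
  if (warn && any(risk_percent < lo | risk_percent > hi)) {
    rlang::warn("Curve prediction outside [0, 100]%; clipped before use as a probability.")
  }
  pmin(pmax(risk_percent, lo), hi) / 100
}

clip_prob <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# two-class naive-Bayes combination of per-factor conditionals q_k =
# P(C = yes | f_k) with prior p_yes, in log space; vectorized over rows of
# the matrix q (one row per case, one column per factor)
nb_combine <- function(q_matrix, p_yes) {
  q_matrix <- clip_prob(q_matrix)
  n <- ncol(q_matrix)
  log_yes <- (1 - n) * log(p_yes) + rowSums(log(q_matrix))
  log_no <- (1 - n) * log(1 - p_yes) + rowSums(log1p(-q_matrix))
  1 / (1 + exp(log_no - log_yes))
}

#' Combine per-factor dose-response curves into one posterior
#'
#' Integrates the one-factor models for a complication into an n-factor
#' posterior under the naive-Bayes assumption of class-conditional
#' independence. Each curve's prediction at the observed factor value,
#' divided by 100, is read as `q_k = P(C = yes | f_k)`; the two class scores
#'
#' `s_yes = p_yes^(1-n) * prod(q_k)` and
#' `s_no = (1 - p_yes)^(1-n) * prod(1 - q_k)`
#'
#' are evaluated in log space and normalized to `s_yes / (s_yes + s_no)`.
#' This equals the classical Bayes chain
#' `P(C) * prod(P(f_k | C))` after two-class normalization: the factor
#' marginals `P(f_k)` introduced by [invert_conditional()] are common to
#' both classes and cancel, so they need not be supplied. With a single
#' observation the posterior is exactly `q_1`; with none it is the prior.
#'
#' @param complication Name of the complication (used for error messages and
#'   to label the result).
#' @param observations Observed factor values: a named numeric vector, or a
#'   data frame with columns `factor` and `value`.
#' @param models Named list of `fitted_curve` objects, keyed by factor name.
#' @param p_yes Prior probability of the complication, in (0, 1).
#' @return A single posterior probability in (0, 1).
#' @examples
#' models <- list(
#'   HbA1c = make_curve("linear", c(-20, 4)),
#'   Duration = make_curve("logarithmic", c(2, 8))
#' )
#' combine_posterior("microalbuminuria", c(HbA1c = 7.8, Duration = 8),
#'   models,
#'   p_yes = 0.15
#' )
#' @export
combine_posterior <- function(complication, observations, models, p_yes) {
  if (!is.numeric(p_yes) || length(p_yes) != 1L || p_yes <= 0 || p_yes >= 1) {
    rlang::abort("`p_yes` must be a single probability in (0, 1).")
  }
  if (is.data.frame(observations)) {
    observations <- stats::setNames(observations$value, observations$factor)
  }
  if (length(observations) == 0L) {
    return(p_yes)
  }
  if (is.null(names(observations)) || any(names(observations) == "")) {
    rlang::abort("`observations` must be named by factor.")
  }
  unknown <- setdiff(names(observations), names(models))
  if (length(unknown)) {
    rlang::abort(sprintf(
      "No 1-1 model for factor(s) %s of complication '%s'.",
      toString(unknown), complication
    ))
  }
  q <- vapply(
    names(observations),
    function(f) {
      risk_percent_to_prob(
        suppressWarnings(predict(models[[f]], observations[[f]]))
      )
    },
    numeric(1)
  )
  nb_combine(matrix(q, nrow = 1), p_yes)
}
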