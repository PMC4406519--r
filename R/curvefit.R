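#' The seven regression patterns
#'
#' Candidate shapes for a one-factor, one-complication dose-response curve:
#'
#' * `linear`: y = b0 + b1 x
#' * `logarithmic`: y = b0 + b1 ln x
#' * `quadratic`: y = b0 + b1 x + b2 x^2
#' * `cubic`: y = b0 + b1 x + b2 x^2 + b3 x^3
#' * `power`: y = b0 x^b1, fitted as ln y = ln b0 + b1 ln x
#' * `s`: y = exp(b0 + b1 / x), fitted as ln y = b0 + b1 / x
#' * `exponential`: y = b0 exp(b1 x), fitted as ln y = ln b0 + b1 x
#'
#' The last three are linearized: ordinary least squares is run on the
#' log-transformed response and all diagnostics are reported on that fitting
#' scale, so their standard errors of the estimate are not commensurable
#' with the polynomial patterns'.
#'
#' @format Character vector of the seven pattern names, in canonical order.
#' @export
curve_patterns <- c(
  "linear", "logarithmic", "quadratic", "cubic", "power", "s", "exponential"
)

pattern_arity <- c(
  linear = 2L, logarithmic = 2L, quadratic = 3L, cubic = 4L,
  power = 2L, s = 2L, exponential = 2L
)

pattern_log_response <- c(
  linear = FALSE, logarithmic = FALSE, quadratic = FALSE, cubic = FALSE,
  power = TRUE, s = TRUE, exponential = TRUE
)

pattern_needs_positive_x <- c(
  linear = FALSE, logarithmic = TRUE, quadratic = FALSE, cubic = FALSE,
  power = TRUE, s = TRUE, exponential = FALSE
)

check_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L ||
    !pattern %in% curve_patterns) {
    rlang::abort(paste0(
      "`pattern` must be one of: ", toString(curve_patterns)
    ))
  }
  pattern
}

# design matrix on the fitting scale (first column is the intercept)
pattern_design <- function(pattern, x) {
  switch(pattern,
    linear = cbind(1, x),
    logarithmic = cbind(1, log(x)),
    quadratic = cbind(1, x, x^2),
    cubic = cbind(1, x, x^2, x^3),
    power = cbind(1, log(x)),
    s = cbind(1, 1 / x),
    exponential = cbind(1, x)
  )
}

# map OLS coefficients on the fitting scale to the reported parameterization
pattern_report_coefs <- function(pattern, beta) {
  out <- switch(pattern,
    power = c(exp(beta[1]), beta[-1]),
    exponential = c(exp(beta[1]), beta[-1]),
    beta
  )
  names(out) <- paste0("b", seq_along(out) - 1L)
  out
}

# inverse of pattern_report_coefs
pattern_fitting_coefs <- function(pattern, coefficients) {
  switch(pattern,
    power = c(log(coefficients[1]), coefficients[-1]),
    exponential = c(log(coefficients[1]), coefficients[-1]),
    coefficients
  )
}

#' Construct a curve object directly from known coefficients
#'
#' Builds a `fitted_curve` without fitting — used for generating synthetic
#' cohorts from a known truth and for hand-set conditionals in toy networks.
#' The object predicts but carries no diagnostics.
#'
#' @param pattern One of [curve_patterns].
#' @param coefficients Numeric vector `b0, b1, ...` in the pattern's reported
#'   parameterization (see [curve_patterns]); length must match the pattern's
#'   arity.
#' @param factor_name,complication_name Optional labels.
#' @return A `fitted_curve`.
#' @examples
#' predict(make_curve("power", c(2, 1)), 5) # 10
#' @export
make_curve <- function(pattern, coefficients, factor_name = "factor",
                       complication_name = "complication") {
  check_pattern(pattern)
  if (length(coefficients) != pattern_arity[[pattern]]) {
    rlang::abort(sprintf(
      "Pattern '%s' takes %d coefficients, got %d.",
      pattern, pattern_arity[[pattern]], length(coefficients)
    ))
  }
  if (pattern %in% c("power", "exponential") && coefficients[1] <= 0) {
    rlang::abort("b0 must be positive for power/exponential curves.")
  }
  coefficients <- stats::setNames(
    as.numeric(coefficients), paste0("b", seq_along(coefficients) - 1L)
  )
  structure(
    list(
      pattern = pattern, coefficients = coefficients,
      n_points = NA_integer_, stats = NULL,
      factor_name = factor_name, complication_name = complication_name,
      domain = c(-Inf, Inf),
      log_scale = unname(pattern_log_response[pattern]),
      residuals = NULL, fitted = NULL
    ),
    class = "fitted_curve"
  )
}

#' Fit one regression pattern to a dose-response dataset
#'
#' Ordinary least squares on the pattern's (possibly linearized) design; see
#' [curve_patterns] for the seven shapes. The diagnostic block
#' ([compute_fit_stats()]) is evaluated on the fitting scale — the log scale
#' for the power, S and exponential patterns — with residuals ordered by
#' ascending factor value for the Durbin-Watson statistic.
#'
#' @param dataset A [dose_response()] dataset (or any data frame with
#'   `factor_value` and `risk_percent` columns), at least arity + 1 points.
#' @param pattern One of [curve_patterns].
#' @return A `fitted_curve`: pattern, named coefficients `b0...bk`,
#'   `n_points`, a `stats` diagnostic block, the training domain, and the
#'   fitting-scale residuals in ascending factor order. Methods: `predict()`,
#'   [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot], `print()`.
#' @examples
#' fit <- fit_pattern(hba1c_npdr(), "linear")
#' glance(fit)
#' @export
fit_pattern <- function(dataset, pattern) {
  check_pattern(pattern)
  d <- dose_response(
    dataset,
    factor_name = attr(dataset, "factor_name") %||% "factor",
    complication_name = attr(dataset, "complication_name") %||% "complication"
  )
  x <- d$factor_value
  y <- d$risk_percent
  arity <- pattern_arity[[pattern]]
  if (length(x) < arity + 1L) {
    rlang::abort(sprintf(
      "Pattern '%s' needs at least %d points, got %d.",
      pattern, arity + 1L, length(x)
    ))
  }
  if (pattern_needs_positive_x[[pattern]] && any(x <= 0)) {
    bad <- which(x <= 0)[1]
    rlang::abort(sprintf(
      "Pattern '%s' requires strictly positive factor values; point %d has factor_value = %g.",
      pattern, bad, x[bad]
    ))
  }
  if (pattern_log_response[[pattern]] && any(y <= 0)) {
    bad <- which(y <= 0)[1]
    rlang::abort(sprintf(
      "Pattern '%s' requires strictly positive risks; point %d has risk_percent = %g.",
      pattern, bad, y[bad]
    ))
  }
  X <- pattern_design(pattern, x)
  yt <- if (pattern_log_response[[pattern]]) log(y) else y
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    rlang::abort(sprintf("Rank-deficient design for pattern '%s'.", pattern))
  }
  beta <- qr.coef(qr_x, yt)
  fitted <- drop(X %*% beta)
  if (any(!is.finite(fitted))) {
    rlang::abort(sprintf("Pattern '%s' produced non-finite fitted values.", pattern))
  }
  stats_block <- compute_fit_stats(yt, fitted, k_predictors = arity - 1L)
  curve <- make_curve(
    pattern, pattern_report_coefs(pattern, beta),
    factor_name = attr(d, "factor_name"),
    complication_name = attr(d, "complication_name")
  )
  curve$n_points <- length(x)
  curve$stats <- stats_block
  curve$domain <- range(x)
  curve$residuals <- yt - fitted
  curve$fitted <- fitted
  curve
}

#' Regression diagnostic block
#'
#' Computes the full set of fit statistics from observed and predicted
#' responses on the fitting scale:
#' R^2 = SS_M / SS_T; F = MS_M / MS_R = (R^2 / k) / ((1 - R^2) / (n - k - 1))
#' with its p-value from the F(k, n - k - 1) distribution; Wherry's adjusted
#' R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1); Stein's cross-validation adjusted
#' R^2 = 1 - \[((n-1)/(n-k-1)) ((n-2)/(n-k-2)) ((n+1)/n)\] (1 - R^2); the
#' standard error of the estimate sqrt(SS_R / (n - k - 1)); and the
#' Durbin-Watson statistic of the residuals in the supplied order.
#'
#' @param observed,predicted Equal-length numeric vectors on the fitting
#'   scale, ordered ascending by factor value (the order the Durbin-Watson
#'   statistic is defined over).
#' @param k_predictors Number of predictors k (1 for the two-coefficient
#'   patterns, 2 for quadratic, 3 for cubic).
#' @return A `fit_stats` list: `r_squared`, `wherry_adj`, `stein_adj`, `see`,
#'   `f_ratio`, `p_value`, `durbin_watson`, `n`, `k_predictors`. For an exact
#'   fit the F-ratio is `Inf`, the p-value 0 and the Durbin-Watson statistic
#'   `NA` (it is undefined on all-zero residuals).
#' @examples
#' compute_fit_stats(c(1, 2, 4, 3, 6), c(1.2, 2.2, 3.2, 4.2, 5.2), 1)
#' @export
compute_fit_stats <- function(observed, predicted, k_predictors) {
  if (length(observed) != length(predicted)) {
    rlang::abort("`observed` and `predicted` must have equal length.")
  }
  n <- length(observed)
  k <- as.integer(k_predictors)
  if (n <= k + 2L) {
    rlang::abort(sprintf("Need n > k + 2 (n = %d, k = %d).", n, k))
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) {
    rlang::abort("Constant response: total sum of squares is zero.")
  }
  ssr <- sum((observed - predicted)^2)
  r2 <- 1 - ssr / sst
  exact <- ssr <= .Machine$double.eps * sst * 100
  f <- if (exact) Inf else (r2 / k) / ((1 - r2) / (n - k - 1))
  structure(
    list(
      r_squared = r2,
      wherry_adj = 1 - (1 - r2) * (n - 1) / (n - k - 1),
      stein_adj = 1 - ((n - 1) / (n - k - 1)) * ((n - 2) / (n - k - 2)) *
        ((n + 1) / n) * (1 - r2),
      see = sqrt(ssr / (n - k - 1)),
      f_ratio = f,
      p_value = stats::pf(f, k, n - k - 1, lower.tail = FALSE),
      durbin_watson = if (exact) NA_real_ else durbin_watson(observed - predicted),
      n = n, k_predictors = k
    ),
    class = "fit_stats"
  )
}

#' Durbin-Watson statistic
#'
#' Serial-correlation diagnostic of an ordered residual sequence,
#' `sum(diff(e)^2) / sum(e^2)`, bounded in \[0, 4\]; values near 2 indicate
#' independent errors and the conventional acceptance band is 1.5-2.5.
#' Residuals must be supplied in the dataset's row order (ascending factor
#' value for dose-response fits).
#'
#' @param residuals Ordered numeric residuals, length >= 2, not all zero.
#' @return The statistic, in \[0, 4\].
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2L) rlang::abort("Need at least 2 residuals.")
  denom <- sum(residuals^2)
  if (denom == 0) rlang::abort("Durbin-Watson is undefined for all-zero residuals.")
  sum(diff(residuals)^2) / denom
}

#' Fit all applicable patterns and select the best
#'
#' `fit_all()` fits each of the seven patterns whose preconditions the data
#' meet, skipping the rest with a warning (e.g. log-based patterns on
#' non-positive factor values). `select_best()` returns the fit with the
#' highest Wherry adjusted R-squared — compared across fitting scales, as
#' the source model-comparison tables do. Raw R-squared cannot arbitrate
#' between nested polynomials (a cubic never scores below the linear fit it
#' contains), and the adjustment reproduces the published winners where raw
#' R-squared would not. Ties break by fewer coefficients, then by pattern
#' order in [curve_patterns].
#'
#' @param dataset A [dose_response()] dataset.
#' @return `fit_all()`: a named list of `fitted_curve` objects.
#' @examples
#' best <- select_best(fit_all(hba1c_npdr()))
#' best$pattern # "linear"
#' @export
fit_all <- function(dataset) {
  fits <- list()
  for (p in curve_patterns) {
    fit <- tryCatch(fit_pattern(dataset, p), error = function(e) {
      rlang::warn(sprintf("Skipping pattern '%s': %s", p, conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[p]] <- fit
  }
  fits
}

#' @rdname fit_all
#' @param fits A non-empty list of `fitted_curve` objects.
#' @return `select_best()`: the winning `fitted_curve`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0L) rlang::abort("No fits to select from.")
  adj <- vapply(fits, function(f) f$stats$wherry_adj, numeric(1))
  arity <- vapply(fits, function(f) length(f$coefficients), integer(1))
  order_in_enum <- match(vapply(fits, `[[`, character(1), "pattern"), curve_patterns)
  fits[[order(-adj, arity, order_in_enum)[1]]]
}

#' Tabulate fits in the model-comparison layout
#'
#' One row per fit with the diagnostic columns of the published comparison
#' tables: dataset, pattern, R-squared, Durbin-Watson, Wherry's and Stein's
#' adjusted R-squared, F-ratio and significance.
#'
#' @param fits A list of `fitted_curve` objects (e.g. from [fit_all()]).
#' @return A tibble, one row per fit.
#' @export
fit_summary <- function(fits) {
  if (inherits(fits, "fitted_curve")) fits <- list(fits)
  purrr::map_dfr(fits, function(f) {
    s <- f$stats
    tibble::tibble(
      dataset = paste0(f$factor_name, "-", f$complication_name),
      pattern = f$pattern,
      r_squared = s$r_squared,
      durbin_watson = s$durbin_watson,
      wherry_adj = s$wherry_adj,
      stein_adj = s$stein_adj,
      f_ratio = s$f_ratio,
      p_value = s$p_value
    )
  })
}

#' Predict risk percent from a fitted curve
#'
#' Evaluates the pattern's closed form on the response (risk-percent) scale,
#' exponentiating the linearized patterns. Values outside the training
#' domain are allowed with a warning; values outside the pattern's
#' mathematical domain (non-positive where a log or reciprocal is taken) are
#' rejected.
#'
#' @param object A `fitted_curve`.
#' @param newdata Numeric factor values, or a data frame with a
#'   `factor_value` column.
#' @param ... Unused.
#' @return Predicted risk percentages.
#' @examples
#' predict(make_curve("linear", c(2, 3)), 4) # 14
#' @export
predict.fitted_curve <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$factor_value else newdata
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort("`newdata` must be finite numeric factor values.")
  }
  if (pattern_needs_positive_x[[object$pattern]] && any(x <= 0)) {
    rlang::abort(sprintf(
      "Pattern '%s' is undefined at non-positive factor values.", object$pattern
    ))
  }
  if (all(is.finite(object$domain)) &&
    any(x < object$domain[1] | x > object$domain[2])) {
    rlang::warn(sprintf(
      "Extrapolating beyond the training domain [%g, %g].",
      object$domain[1], object$domain[2]
    ))
  }
  beta <- pattern_fitting_coefs(object$pattern, object$coefficients)
  eta <- drop(pattern_design(object$pattern, x) %*% beta)
  if (object$log_scale) exp(eta) else eta
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat(sprintf(
    "<fitted_curve> %s-%s, pattern '%s'\n  coefficients: %s\n",
    x$factor_name, x$complication_name, x$pattern,
    paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients), collapse = ", ")
  ))
  if (!is.null(x$stats)) {
    cat(sprintf(
      "  R2 = %.3f, Wherry = %.3f, Stein = %.3f, F = %.3g, DW = %.3f (n = %d)\n",
      x$stats$r_squared, x$stats$wherry_adj, x$stats$stein_adj,
      x$stats$f_ratio, x$stats$durbin_watson, x$stats$n
    ))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style accessors for fitted curves
#'
#' `tidy()` returns one row per coefficient; `glance()` returns the one-row
#' diagnostic block.
#'
#' @param x,... A `fitted_curve`; further arguments ignored.
#' @return A tibble.
#' @method tidy fitted_curve
#' @export
tidy.fitted_curve <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname tidy.fitted_curve
#' @method glance fitted_curve
#' @export
glance.fitted_curve <- function(x, ...) {
  if (is.null(x$stats)) {
    return(tibble::tibble(pattern = x$pattern))
  }
  dplyr::bind_cols(
    tibble::tibble(pattern = x$pattern),
    tibble::as_tibble(unclass(x$stats))
  )
}

#' Plot a fitted dose-response curve over its training data
#'
#' @param object A `fitted_curve` with stored training domain.
#' @param dataset Optionally, the [dose_response()] dataset to overlay.
#' @param n_grid Number of grid points for the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fitted_curve
#' @export
autoplot.fitted_curve <- function(object, dataset = NULL, n_grid = 200, ...) {
  lo <- object$domain[1]
  hi <- object$domain[2]
  if (!all(is.finite(c(lo, hi)))) rlang::abort("Curve has no training domain to plot over.")
  grid <- tibble::tibble(factor_value = seq(lo, hi, length.out = n_grid))
  grid$risk_percent <- predict(object, grid$factor_value)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$factor_value, y = .data$risk_percent)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = object$factor_name, y = "Risk (%)",
      title = sprintf(
        "%s-%s: %s pattern", object$factor_name,
        object$complication_name, object$pattern
      )
    )
  if (!is.null(dataset)) {
    p <- p + ggplot2::geom_point(data = tibble::as_tibble(dataset))
  }
  p
}

#' Serialize a fitted curve to JSON and back
#'
#' The JSON carries the pattern, coefficients, diagnostic block and dataset
#' provenance; `curve_from_json()` restores an equivalent `fitted_curve`.
#'
#' @param curve A `fitted_curve`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `curve_to_json()`: the path (or JSON string) invisibly;
#'   `curve_from_json()`: a `fitted_curve`.
#' @export
curve_to_json <- function(curve, path = NULL) {
  payload <- list(
    pattern = curve$pattern,
    coefficients = as.list(curve$coefficients),
    n_points = curve$n_points,
    stats = if (!is.null(curve$stats)) unclass(curve$stats),
    factor_name = curve$factor_name,
    complication_name = curve$complication_name,
    domain = curve$domain
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) {
    return(invisible(as.character(json)))
  }
  writeLines(json, path)
  invisible(path)
}

#' @rdname curve_to_json
#' @param json A path to a JSON file or a JSON string.
#' @export
curve_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json)
  curve <- make_curve(
    payload$pattern, unlist(payload$coefficients),
    factor_name = payload$factor_name,
    complication_name = payload$complication_name
  )
  curve$n_points <- payload$n_points
  if (!is.null(payload$stats)) {
    curve$stats <- structure(as.list(payload$stats), class = "fit_stats")
  }
  if (!is.null(payload$domain)) curve$domain <- as.numeric(payload$domain)
  curve
}
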