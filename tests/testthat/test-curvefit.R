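# closed-form generators for each pattern, used for recovery checks
pattern_truth <- list(
  linear = list(coef = c(2, 3), f = function(x) 2 + 3 * x),
  logarithmic = list(coef = c(1, 4), f = function(x) 1 + 4 * log(x)),
  quadratic = list(coef = c(10, -2, 0.5), f = function(x) 10 - 2 * x + 0.5 * x^2),
  cubic = list(coef = c(2, 1, -0.3, 0.02), f = function(x) 2 + x - 0.3 * x^2 + 0.02 * x^3),
  power = list(coef = c(2, 1.3), f = function(x) 2 * x^1.3),
  s = list(coef = c(1, 2), f = function(x) exp(1 + 2 / x)),
  exponential = list(coef = c(0.5, 0.4), f = function(x) 0.5 * exp(0.4 * x))
)

test_that("each pattern recovers its own generating coefficients exactly", {
  x <- seq(1, 8, length.out = 8)
  for (p in curve_patterns) {
    truth <- pattern_truth[[p]]
    d <- dose_response(data.frame(factor_value = x, risk_percent = truth$f(x)))
    fit <- fit_pattern(d, p)
    expect_equal(unname(fit$coefficients), truth$coef,
      tolerance = 1e-8, label = paste0(p, " coefficients")
    )
    expect_gt(fit$stats$r_squared, 1 - 1e-10)
    expect_equal(fit$stats$see, 0, tolerance = 1e-6)
    expect_equal(fit$stats$wherry_adj, 1, tolerance = 1e-9)
    expect_equal(fit$stats$stein_adj, 1, tolerance = 1e-9)
  }
})

test_that("four points on y = exp(1 + 2/x) identify the S pattern parameters", {
  x <- c(1, 2, 4, 8)
  d <- dose_response(data.frame(factor_value = x, risk_percent = exp(1 + 2 / x)))
  fit <- fit_pattern(d, "s")
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
})

test_that("polynomial fits agree with an independent normal-equations solution", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:10, 1)
    x <- sort(runif(n, 1, 10))
    y <- runif(n, 5, 50)
    d <- dose_response(data.frame(factor_value = x, risk_percent = y))
    for (p in c("linear", "quadratic", "cubic")) {
      fit <- fit_pattern(d, p)
      X <- switch(p,
        linear = cbind(1, x),
        quadratic = cbind(1, x, x^2),
        cubic = cbind(1, x, x^2, x^3)
      )
      beta <- drop(solve(crossprod(X), crossprod(X, y)))
      expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-7)
    }
  }
})

test_that("the diagnostic block matches hand-evaluated formulas at R2 = 0.5, n = 20, k = 2", {
  obs <- as.numeric(1:20)
  sst <- sum((obs - mean(obs))^2)
  resid <- rep(c(1, -1), 10) * sqrt(sst / 2 / 20) # SSR = SST/2 exactly
  s <- compute_fit_stats(obs, obs - resid, k_predictors = 2)
  expect_equal(s$r_squared, 0.5, tolerance = 1e-12)
  expect_equal(s$wherry_adj, 1 - 0.5 * 19 / 17, tolerance = 1e-12)
  expect_equal(s$stein_adj, 1 - (19 / 17) * (18 / 16) * (21 / 20) * 0.5, tolerance = 1e-12)
  expect_equal(s$f_ratio, (0.5 / 2) / (0.5 / 17), tolerance = 1e-12)
  expect_equal(s$p_value, pf(8.5, 2, 17, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(s$see, sqrt((sst / 2) / 17), tolerance = 1e-12)
})

test_that("diagnostics reject degenerate inputs", {
  expect_error(compute_fit_stats(rep(3, 10), rep(3, 10), 1), "Constant response")
  expect_error(compute_fit_stats(1:10, 1:9, 1), "equal length")
  expect_error(compute_fit_stats(1:4, c(1, 2, 3, 5), 2), "n > k \\+ 2")
})

test_that("Durbin-Watson matches its definition and symmetry properties", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  expect_error(durbin_watson(rep(0, 5)), "all-zero")
  expect_error(durbin_watson(1), "at least 2")
  for (seed in 1:20) {
    set.seed(seed)
    e <- rnorm(sample(5:30, 1))
    dw <- durbin_watson(e)
    expect_gte(dw, 0)
    expect_lte(dw, 4)
    expect_equal(durbin_watson(rev(e)), dw)
  }
})

test_that("Durbin-Watson agrees with the lmtest implementation on a real fit", {
  skip_if_not_installed("lmtest")
  set.seed(7)
  x <- sort(runif(25, 1, 10))
  y <- 3 + 2 * x + rnorm(25)
  fit <- lm(y ~ x)
  expect_equal(
    durbin_watson(residuals(fit)),
    unname(lmtest::dwtest(fit)$statistic),
    tolerance = 1e-10
  )
})

test_that("fit_all skips infeasible patterns with a warning and keeps the rest", {
  d <- dose_response(data.frame(
    factor_value = c(-2, -1, 0, 1, 2, 3),
    risk_percent = c(5, 7, 9, 11, 13, 15)
  ))
  fits <- suppressWarnings(fit_all(d))
  expect_false(any(c("logarithmic", "power", "s") %in% names(fits)))
  expect_true(all(c("linear", "quadratic", "cubic", "exponential") %in% names(fits)))
  expect_warning(fit_all(d), "logarithmic")
})

test_that("select_best maximizes adjusted R2 with the documented tie-breaks", {
  fits <- suppressWarnings(fit_all(hba1c_npdr()))
  best <- select_best(fits)
  expect_identical(best$pattern, "linear")
  adj <- vapply(fits, function(f) f$stats$wherry_adj, numeric(1))
  expect_true(all(best$stats$wherry_adj >= adj))

  tie_a <- make_curve("quadratic", c(1, 2, 3))
  tie_a$stats <- list(wherry_adj = 0.8)
  tie_b <- make_curve("exponential", c(1, 0.5))
  tie_b$stats <- list(wherry_adj = 0.8)
  expect_identical(select_best(list(tie_a, tie_b))$pattern, "exponential")
  expect_identical(select_best(list(tie_b))$pattern, "exponential")
  expect_error(select_best(list()), "No fits")
})

test_that("prediction evaluates the closed forms on the response scale", {
  expect_equal(predict(make_curve("linear", c(2, 3)), 4), 14)
  expect_equal(predict(make_curve("power", c(2, 1)), 5), 10)
  expect_equal(predict(make_curve("exponential", c(2, 0.5)), 2), 2 * exp(1))
  expect_equal(predict(make_curve("s", c(1, 2)), 4), exp(1.5))
  best <- fit_pattern(hba1c_npdr(), "linear")
  b <- unname(best$coefficients)
  expect_equal(predict(best, 9.5), b[1] + b[2] * 9.5)
  expect_error(predict(make_curve("power", c(2, 1)), -1), "non-positive")
  expect_warning(predict(best, 20), "Extrapolating")
})

test_that("fitting preconditions name the offending point", {
  d <- dose_response(data.frame(factor_value = c(0, 1, 2, 3), risk_percent = c(1, 2, 3, 4)))
  expect_error(fit_pattern(d, "logarithmic"), "point 1")
  dz <- dose_response(data.frame(factor_value = 1:4, risk_percent = c(1, 0, 3, 4)))
  expect_error(fit_pattern(dz, "exponential"), "point 2")
  const <- dose_response(data.frame(factor_value = rep(2, 5), risk_percent = 1:5))
  expect_error(fit_pattern(const, "linear"), "Rank-deficient")
  expect_error(fit_pattern(hba1c_npdr()[1:3, ], "cubic"), "at least 5")
})

test_that("tidy, glance and the summary table expose the diagnostic block", {
  fit <- fit_pattern(hba1c_npdr(), "linear")
  td <- tidy(fit)
  expect_equal(td$term, c("b0", "b1"))
  gl <- glance(fit)
  expect_equal(gl$r_squared, fit$stats$r_squared)
  expect_equal(gl$n, 16L)
  summary <- fit_summary(suppressWarnings(fit_all(hba1c_npdr())))
  expect_equal(nrow(summary), 7L)
  expect_true(all(c("dataset", "pattern", "r_squared", "durbin_watson") %in% names(summary)))
  expect_identical(unique(summary$dataset), "HbA1c-NPDR")
})

test_that("fitted curves survive a JSON round trip", {
  fit <- fit_pattern(hba1c_npdr(), "quadratic")
  path <- withr::local_tempfile(fileext = ".json")
  curve_to_json(fit, path)
  back <- curve_from_json(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$stats$r_squared, fit$stats$r_squared)
  expect_equal(predict(back, 9), predict(fit, 9))
})

test_that("autoplot returns a ggplot of curve over data", {
  fit <- fit_pattern(hba1c_npdr(), "linear")
  p <- autoplot(fit, dataset = hba1c_npdr())
  expect_s3_class(p, "ggplot")
})
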