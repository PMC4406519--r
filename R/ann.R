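#' Configuration for the neural-network baseline
#'
#' @param hidden_units Number of units in the single hidden layer.
#' @param learning_rate Gradient-descent step size on the standardized scale.
#' @param epochs Number of full-batch passes.
#' @param seed Integer seed; fully determines the weight initialization and
#'   hence the trained model.
#' @return An `ann_config` list.
#' @export
ann_config <- function(hidden_units = 4L, learning_rate = 0.05,
                       epochs = 5000L, seed = 1L) {
  stopifnot(
    hidden_units >= 1L, learning_rate > 0, epochs >= 1L,
    is.finite(seed)
  )
  structure(
    list(
      hidden_units = as.integer(hidden_units),
      learning_rate = learning_rate,
      epochs = as.integer(epochs),
      seed = as.integer(seed)
    ),
    class = "ann_config"
  )
}

#' Train the feed-forward neural-network baseline
#'
#' A minimal single-hidden-layer regressor — tanh hidden activation, linear
#' output, full-batch gradient descent on mean squared error — serving as
#' the comparison arm to the regression patterns. Inputs and the response
#' are standardized internally; the reported training R-squared is on the
#' raw risk-percent scale. Training is deterministic for a fixed seed.
#'
#' @param dataset A [dose_response()] dataset with at least 4 points.
#' @param config An [ann_config()].
#' @return An `ann_model` with weight matrices, scaling constants, the
#'   config and `training_r_squared`. Methods: `predict()`, `glance()`.
#' @examples
#' d <- dose_response(data.frame(
#'   factor_value = seq(1, 10, length.out = 20),
#'   risk_percent = 2 + 3 * seq(1, 10, length.out = 20)
#' ))
#' m <- train_ann(d, ann_config(epochs = 2000, seed = 42))
#' m$training_r_squared > 0.99
#' @export
train_ann <- function(dataset, config = ann_config()) {
  d <- dose_response(
    dataset,
    factor_name = attr(dataset, "factor_name") %||% "factor",
    complication_name = attr(dataset, "complication_name") %||% "complication"
  )
  if (nrow(d) < 4L) rlang::abort("Need at least 4 points to train.")
  x <- d$factor_value
  y <- d$risk_percent
  mx <- mean(x)
  sx <- stats::sd(x)
  my <- mean(y)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) rlang::abort("Degenerate dataset: constant factor or risk.")
  xs <- (x - mx) / sx
  ys <- (y - my) / sy
  h <- config$hidden_units
  w <- with_local_seed(config$seed, list(
    w1 = matrix(stats::runif(h, -0.5, 0.5), nrow = 1),
    b1 = stats::runif(h, -0.5, 0.5),
    w2 = matrix(stats::runif(h, -0.5, 0.5), ncol = 1),
    b2 = stats::runif(1, -0.5, 0.5)
  ))
  n <- length(xs)
  lr <- config$learning_rate
  for (epoch in seq_len(config$epochs)) {
    a1 <- tanh(outer(xs, drop(w$w1)) + matrix(w$b1, n, h, byrow = TRUE))
    yhat <- drop(a1 %*% w$w2) + w$b2
    err <- yhat - ys
    if (!all(is.finite(err))) {
      rlang::abort("Training diverged (non-finite loss); reduce `learning_rate`.")
    }
    # full-batch gradients of MSE = mean(err^2)
    g_out <- 2 * err / n
    g_w2 <- crossprod(a1, g_out)
    g_b2 <- sum(g_out)
    g_hidden <- (g_out %*% t(w$w2)) * (1 - a1^2)
    g_w1 <- matrix(crossprod(xs, g_hidden), nrow = 1)
    g_b1 <- colSums(g_hidden)
    w$w1 <- w$w1 - lr * g_w1
    w$b1 <- w$b1 - lr * g_b1
    w$w2 <- w$w2 - lr * g_w2
    w$b2 <- w$b2 - lr * g_b2
  }
  model <- structure(
    list(
      weights = w,
      scaling = list(mx = mx, sx = sx, my = my, sy = sy),
      config = config,
      factor_name = attr(d, "factor_name"),
      complication_name = attr(d, "complication_name"),
      domain = range(x),
      training_r_squared = NA_real_
    ),
    class = "ann_model"
  )
  yhat_raw <- predict(model, x)
  model$training_r_squared <- 1 - sum((y - yhat_raw)^2) / sum((y - mean(y))^2)
  model
}

#' Predict risk percent from a trained neural-network baseline
#'
#' @param object An `ann_model`.
#' @param newdata Numeric factor values, or a data frame with a
#'   `factor_value` column.
#' @param ... Unused.
#' @return Predicted risk percentages on the raw scale.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$factor_value else newdata
  if (!is.numeric(x) || any(!is.finite(x))) {
    rlang::abort("`newdata` must be finite numeric factor values.")
  }
  s <- object$scaling
  w <- object$weights
  xs <- (x - s$mx) / s$sx
  h <- length(w$b1)
  a1 <- tanh(outer(xs, drop(w$w1)) + matrix(w$b1, length(xs), h, byrow = TRUE))
  drop(a1 %*% w$w2 + w$b2) * s$sy + s$my
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf(
    "<ann_model> %s-%s: %d hidden units, %d epochs, training R2 = %.3f\n",
    x$factor_name, x$complication_name, x$config$hidden_units,
    x$config$epochs, x$training_r_squared
  ))
  invisible(x)
}

#' @rdname tidy.fitted_curve
#' @method glance ann_model
#' @export
glance.ann_model <- function(x, ...) {
  tibble::tibble(
    r_squared = x$training_r_squared,
    hidden_units = x$config$hidden_units,
    epochs = x$config$epochs,
    learning_rate = x$config$learning_rate,
    seed = x$config$seed
  )
}

#' Serialize an `ann_model` to JSON and back
#'
#' @param model An `ann_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `ann_to_json()`: the path (or JSON string) invisibly;
#'   `ann_from_json()`: an `ann_model`.
#' @export
ann_to_json <- function(model, path = NULL) {
  payload <- list(
    weights = list(
      w1 = as.numeric(model$weights$w1), b1 = model$weights$b1,
      w2 = as.numeric(model$weights$w2), b2 = model$weights$b2
    ),
    scaling = model$scaling,
    config = unclass(model$config),
    factor_name = model$factor_name,
    complication_name = model$complication_name,
    domain = model$domain,
    training_r_squared = model$training_r_squared
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) {
    return(invisible(as.character(json)))
  }
  writeLines(json, path)
  invisible(path)
}

#' @rdname ann_to_json
#' @param json A path to a JSON file or a JSON string.
#' @export
ann_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  h <- length(p$weights$b1)
  structure(
    list(
      weights = list(
        w1 = matrix(p$weights$w1, nrow = 1), b1 = p$weights$b1,
        w2 = matrix(p$weights$w2, ncol = 1), b2 = p$weights$b2
      ),
      scaling = p$scaling,
      config = do.call(ann_config, p$config),
      factor_name = p$factor_name,
      complication_name = p$complication_name,
      domain = as.numeric(p$domain),
      training_r_squared = p$training_r_squared
    ),
    class = "ann_model"
  )
}
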