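#' Confusion counts at a probability cut-off
#'
#' Predicted probabilities at or above `cutoff_percent / 100` are classified
#' `yes` and tallied against the true outcomes.
#'
#' @param predicted Predicted probabilities in \[0, 1\].
#' @param outcomes True outcomes: `"yes"`/`"no"` (or a logical vector).
#' @param cutoff_percent Cut-off on the percent scale, in \[0, 100\].
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_at_cutoff(c(0.65, 0.55), c("yes", "yes"), 60) # tp 1, fn 1
#' @export
confusion_at_cutoff <- function(predicted, outcomes, cutoff_percent) {
  outcomes <- normalize_outcomes(outcomes)
  if (length(predicted) != length(outcomes)) {
    rlang::abort("`predicted` and `outcomes` must have equal length.")
  }
  if (cutoff_percent < 0 || cutoff_percent > 100) {
    rlang::abort("`cutoff_percent` must lie in [0, 100].")
  }
  called_yes <- predicted >= cutoff_percent / 100
  tibble::tibble(
    tp = sum(called_yes & outcomes),
    fp = sum(called_yes & !outcomes),
    tn = sum(!called_yes & !outcomes),
    fn = sum(!called_yes & outcomes)
  )
}

normalize_outcomes <- function(outcomes) {
  if (is.logical(outcomes)) {
    return(outcomes)
  }
  outcomes <- as.character(outcomes)
  bad <- setdiff(unique(outcomes), c("yes", "no"))
  if (length(bad)) {
    rlang::abort(paste0("Outcomes must be 'yes'/'no'; found: ", toString(bad)))
  }
  outcomes == "yes"
}

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP); precision
#' (positive predictive value) = TP / (TP + FP); accuracy = (TP + TN) /
#' total. Ratios with a zero denominator are undefined and reported as `NA`,
#' not zero.
#'
#' @param counts A one-row tibble (or named list) with `tp`, `fp`, `tn`,
#'   `fn`, as from [confusion_at_cutoff()].
#' @return A one-row tibble with `sensitivity`, `specificity`, `precision`,
#'   `accuracy`.
#' @examples
#' # an all-negative classifier on 10 positive / 90 negative samples
#' classification_metrics(list(tp = 0, fn = 10, tn = 90, fp = 0))
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  tn <- counts$tn
  fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) rlang::abort("All confusion counts are zero.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    accuracy = (tp + tn) / total
  )
}

#' Sweep classification metrics over probability cut-offs
#'
#' One metric row per cut-off, in input order. The default grid
#' (60, 70, 80, 90, 100 percent) follows the validation design for
#' translating a continuous complication probability into presence/absence;
#' at cut-off 100 only a probability of exactly 1 classifies positive.
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Cut-offs on the percent scale.
#' @return A `cutoff_sweep` tibble: `cutoff_percent`, the four counts and
#'   the four metrics per row. `autoplot()` draws metric-vs-cutoff lines.
#' @examples
#' sweep_cutoffs(c(0.9, 0.7, 0.2), c("yes", "no", "no"))
#' @export
sweep_cutoffs <- function(predicted, outcomes, cutoffs = c(60, 70, 80, 90, 100)) {
  if (length(cutoffs) == 0L) rlang::abort("Need at least one cut-off.")
  rows <- purrr::map_dfr(cutoffs, function(co) {
    counts <- confusion_at_cutoff(predicted, outcomes, co)
    dplyr::bind_cols(
      tibble::tibble(cutoff_percent = co), counts,
      classification_metrics(counts)
    )
  })
  structure(rows, class = c("cutoff_sweep", class(tibble::tibble())))
}

#' @rdname sweep_cutoffs
#' @param object A `cutoff_sweep`.
#' @param ... Unused.
#' @method autoplot cutoff_sweep
#' @export
autoplot.cutoff_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("cutoff_percent", "sensitivity", "specificity", "precision", "accuracy")],
    cols = -"cutoff_percent", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$cutoff_percent, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cut-off (%)", y = "Metric value", colour = NULL)
}
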