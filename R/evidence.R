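#' Dose-response datasets
#'
#' A dose-response dataset is an ordered table of `(factor_value,
#' risk_percent)` pairs describing how the risk of one complication changes
#' with one predisposing factor (e.g. risk of non-proliferative retinopathy
#' against HbA1c). Rows are kept sorted ascending by factor value; risk is
#' expressed in percent and may legitimately exceed 100 when sources report
#' rates per 100 patient-years (a warning is raised, the value is kept).
#'
#' @param points A data frame with numeric columns `factor_value` and
#'   `risk_percent`.
#' @param factor_name,complication_name Names of the factor and the
#'   complication the dataset relates.
#' @return A tibble of class `dose_response` with attributes `factor_name`
#'   and `complication_name`.
#' @examples
#' dose_response(
#'   data.frame(factor_value = c(8, 9, 10), risk_percent = c(3, 8, 15)),
#'   "HbA1c", "NPDR"
#' )
#' @export
dose_response <- function(points, factor_name = "factor",
                          complication_name = "complication") {
  points <- tibble::as_tibble(points)
  if (!all(c("factor_value", "risk_percent") %in% names(points))) {
    rlang::abort("`points` must have columns `factor_value` and `risk_percent`.")
  }
  points <- points[c("factor_value", "risk_percent")]
  if (!all(vapply(points, is.numeric, logical(1)))) {
    rlang::abort("`factor_value` and `risk_percent` must be numeric.")
  }
  if (any(!is.finite(points$factor_value)) || any(!is.finite(points$risk_percent))) {
    rlang::abort("Dose-response points must be finite.")
  }
  if (any(points$risk_percent < 0)) {
    rlang::abort("Risk percentages must be non-negative.")
  }
  if (any(points$risk_percent > 100)) {
    rlang::warn("Some risk values exceed 100%; kept as-is (rates per 100 patient-years can exceed 100).")
  }
  points <- dplyr::arrange(points, .data$factor_value)
  structure(points,
    class = c("dose_response", class(tibble::tibble())),
    factor_name = factor_name, complication_name = complication_name
  )
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "<dose_response> %s -> %s (%d points)\n",
    attr(x, "factor_name"), attr(x, "complication_name"), nrow(x)
  ))
  NextMethod()
}

#' Validate a table of literature "from-to" evidence records
#'
#' Each record encodes one published relationship cell: when the factor moves
#' from `factor_from` to `factor_to`, the complication risk moves from
#' `risk_from` to `risk_to` percent. `relation` is one of `"cause"`,
#' `"prevents"` or `"same"`; records of the "prevents" type are stored
#' unchanged — a risk that decreases with the factor is the fitted curve's
#' business, not a data transform.
#'
#' @param records A data frame with columns `factor`, `complication`,
#'   `relation`, `factor_from`, `factor_to`, `risk_from`, `risk_to`, `source`.
#' @return The validated records as a tibble.
#' @export
from_to_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c(
    "factor", "complication", "relation",
    "factor_from", "factor_to", "risk_from", "risk_to", "source"
  )
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    rlang::abort(paste0("Missing record columns: ", toString(missing)))
  }
  if (nrow(records) == 0L) rlang::abort("No evidence records supplied.")
  bad_rel <- setdiff(unique(records$relation), c("cause", "prevents", "same"))
  if (length(bad_rel)) {
    rlang::abort(paste0("Unknown relation type(s): ", toString(bad_rel)))
  }
  if (any(records$risk_from < 0) || any(records$risk_to < 0)) {
    rlang::abort("Risk percentages must be non-negative.")
  }
  if (any(records$factor_from == records$factor_to)) {
    rlang::abort("`factor_from` and `factor_to` must differ within a record.")
  }
  records[needed]
}

#' Flatten from-to records into a two-dimensional dose-response dataset
#'
#' Every record contributes its two endpoints, `(factor_from, risk_from)` and
#' `(factor_to, risk_to)`, as separate points; no interpolation is performed
#' between them. Duplicate factor values arising from distinct sources are
#' all retained, unweighted. The result is sorted ascending by factor value,
#' so the operation is invariant to the order of the input records.
#'
#' @param records A from-to record table (see [from_to_records()]); all rows
#'   must share one factor/complication pair.
#' @return A [dose_response()] dataset.
#' @examples
#' recs <- data.frame(
#'   factor = "HbA1c", complication = "retinopathy progression",
#'   relation = "cause",
#'   factor_from = c(11, 8), factor_to = c(9.9, 7.2),
#'   risk_from = c(10.78, 2.43), risk_to = c(4.21, 1.48),
#'   source = "DCCT"
#' )
#' records_to_points(recs)
#' @export
records_to_points <- function(records) {
  records <- from_to_records(records)
  pairs <- unique(records[c("factor", "complication")])
  if (nrow(pairs) > 1L) {
    rlang::abort(paste0(
      "Records mix factor/complication pairs: ",
      toString(paste0(pairs$factor, "->", pairs$complication))
    ))
  }
  points <- tidyr::pivot_longer(
    records,
    cols = c("factor_from", "factor_to"),
    names_to = "end", values_to = "factor_value"
  )
  points$risk_percent <- ifelse(points$end == "factor_from",
    points$risk_from, points$risk_to
  )
  dose_response(
    points[c("factor_value", "risk_percent")],
    factor_name = pairs$factor, complication_name = pairs$complication
  )
}

#' Mean arterial pressure
#'
#' Summarizes a blood-pressure reading as a single scalar,
#' `MAP = DP + (SP - DP) / 3`, used as the blood-pressure risk factor.
#'
#' @param systolic,diastolic Pressures in mmHg; vectorized, `systolic >=
#'   diastolic > 0` elementwise.
#' @return MAP in mmHg.
#' @examples
#' mean_arterial_pressure(120, 90) # 100
#' @export
mean_arterial_pressure <- function(systolic, diastolic) {
  if (any(diastolic <= 0)) rlang::abort("Pressures must be positive.")
  if (any(systolic < diastolic)) {
    rlang::abort("Systolic pressure must be >= diastolic pressure.")
  }
  diastolic + (systolic - diastolic) / 3
}

#' Rescale relative risk changes against an anchored absolute risk
#'
#' Many sources report only multiplicative changes in risk. Given the
#' absolute risk percent of the first (anchor) point, the absolute risks of
#' the remaining points are the anchor times each change factor.
#'
#' @param anchor_risk Absolute risk percent of the anchor point; must be
#'   positive.
#' @param relative_factors Multiplicative change factors versus the anchor
#'   (first element 1 by convention).
#' @return Risk percentages, in order.
#' @examples
#' scale_by_anchor(10, c(1, 0.5, 2)) # 10 5 20
#' @export
scale_by_anchor <- function(anchor_risk, relative_factors) {
  if (!is.numeric(anchor_risk) || length(anchor_risk) != 1L || anchor_risk <= 0) {
    rlang::abort("`anchor_risk` must be a single positive risk percent.")
  }
  anchor_risk * relative_factors
}

#' Read and write the flat-file formats for evidence and datasets
#'
#' Evidence CSVs use the header
#' `factor,complication,relation,factor_from,factor_to,risk_from,risk_to,source`;
#' dataset CSVs use `factor_value,risk_percent`.
#'
#' @param path File path.
#' @param factor_name,complication_name Dataset labels (dataset CSVs carry no
#'   metadata columns).
#' @return `read_evidence_csv()` a validated record tibble;
#'   `read_dose_response_csv()` a [dose_response()] dataset;
#'   `write_dose_response_csv()` the input, invisibly.
#' @export
read_evidence_csv <- function(path) {
  from_to_records(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_evidence_csv
#' @export
read_dose_response_csv <- function(path, factor_name = "factor",
                                   complication_name = "complication") {
  # base parser: correctly-rounded doubles, so written datasets re-read
  # bit-identically
  dose_response(
    utils::read.csv(path),
    factor_name = factor_name, complication_name = complication_name
  )
}

#' @rdname read_evidence_csv
#' @param dataset A [dose_response()] dataset.
#' @export
write_dose_response_csv <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(dataset)[c("factor_value", "risk_percent")], path)
  invisible(dataset)
}

#' The packaged HbA1c vs NPDR dataset
#'
#' Sixteen literature-derived points relating HbA1c level (percent) to the
#' risk of non-proliferative diabetic retinopathy; the worked example used
#' throughout the package and its tests.
#'
#' @return A [dose_response()] dataset with 16 points.
#' @examples
#' hba1c_npdr()
#' @export
hba1c_npdr <- function() {
  read_dose_response_csv(
    system.file("extdata", "hba1c_npdr.csv", package = "diabrisk", mustWork = TRUE),
    factor_name = "HbA1c", complication_name = "NPDR"
  )
}
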