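#' Fit dose-response datasets from files
#'
#' Reads each dataset CSV (`factor_value,risk_percent`), fits either all
#' seven regression patterns and selects the best, or the neural-network
#' baseline, writes one model JSON per dataset plus a model-comparison
#' summary CSV, and records a run manifest.
#'
#' @param dataset_paths Character vector of dataset CSV paths; dataset names
#'   are taken from the file names.
#' @param method `"regression"` or `"ann"`.
#' @param out_dir Output directory (created if needed). Existing outputs are
#'   not overwritten unless `overwrite = TRUE`.
#' @param seed Seed for the ANN baseline.
#' @param config An [ann_config()] used when `method = "ann"` (its seed is
#'   replaced by `seed`).
#' @param overwrite Allow overwriting existing outputs.
#' @return The summary tibble (Table-layout: dataset, pattern/R2/DW/adjusted
#'   R2s/F/p for regression; dataset/R2 for the ANN), invisibly.
#' @export
run_fit <- function(dataset_paths, method = c("regression", "ann"),
                    out_dir, seed = 1L, config = ann_config(),
                    overwrite = FALSE) {
  method <- match.arg(method)
  if (length(dataset_paths) == 0L) rlang::abort("No dataset files supplied.")
  missing_files <- dataset_paths[!file.exists(dataset_paths)]
  if (length(missing_files)) {
    rlang::abort(paste0("Dataset file(s) not found: ", toString(missing_files)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- purrr::map_dfr(dataset_paths, function(path) {
    name <- tools::file_path_sans_ext(basename(path))
    d <- read_dose_response_csv(path, factor_name = name)
    model_path <- file.path(out_dir, paste0(name, "_model.json"))
    if (file.exists(model_path) && !overwrite) {
      rlang::abort(paste0(model_path, " exists; pass overwrite = TRUE."))
    }
    if (method == "regression") {
      best <- select_best(fit_all(d))
      curve_to_json(best, model_path)
      row <- fit_summary(best)
      row$dataset <- name
      row
    } else {
      config$seed <- as.integer(seed)
      model <- train_ann(d, config)
      ann_to_json(model, model_path)
      tibble::tibble(dataset = name, pattern = "ann", r_squared = model$training_r_squared)
    }
  })
  readr::write_csv(summary, file.path(out_dir, "fit_summary.csv"))
  write_manifest(out_dir, list(
    command = "fit", method = method, seed = seed,
    inputs = dataset_paths
  ))
  invisible(summary)
}

#' Simulate a cohort to CSV
#'
#' Generates a synthetic cohort under the default study configuration (or a
#' supplied [cohort_config()]) and writes it as a cohort CSV.
#'
#' @param out_path Output CSV path.
#' @param n_patients,seed Size and seed when using the default
#'   configuration.
#' @param config Optional full [cohort_config()] overriding the defaults.
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(out_path, n_patients = 1000L, seed = 1L,
                         config = NULL) {
  if (is.null(config)) {
    config <- cohort_config(
      n_patients = n_patients, seed = seed,
      factor_specs = default_factor_specs(),
      truth_curves = default_truth_curves(),
      p_yes = default_priors()
    )
  }
  cohort <- generate_cohort(config)
  write_cohort_csv(cohort, out_path)
  write_manifest(dirname(out_path), list(
    command = "simulate", seed = config$seed, n_patients = config$n_patients
  ))
  invisible(cohort)
}

#' Compile the default network against a cohort and save it
#'
#' Estimates root marginals and class priors from the cohort file, compiles
#' the default network spec with the default edge models, and writes the
#' compiled network JSON.
#'
#' @param cohort_path Cohort CSV (as written by [run_simulate()]).
#' @param out_path Output JSON path.
#' @return The `compiled_network`, invisibly.
#' @export
run_build_network <- function(cohort_path, out_path) {
  cohort <- read_cohort_csv(cohort_path)
  est <- estimate_priors(cohort, default_schemes())
  network <- compile_network(
    default_network_spec(),
    models = default_edge_models(),
    priors = est$priors, marginals = est$marginals
  )
  network_to_json(network, out_path)
  write_manifest(dirname(out_path), list(
    command = "build-network", inputs = cohort_path
  ))
  invisible(network)
}

#' Score patients with a compiled network
#'
#' Reads a compiled network JSON and a patient CSV whose columns include
#' some or all of the network's factors, and writes one row per patient
#' with the inferred probability of every complication. Missing factor
#' columns or `NA` cells are marginalized over the root distributions and
#' flagged in a `missing_factors` column.
#'
#' @param network_path Compiled network JSON (see [network_to_json()]).
#' @param patient_path Patient CSV; unknown factor columns (other than
#'   `patient_id` and outcome columns) are rejected.
#' @param out_path Output CSV path.
#' @return The predictions tibble, invisibly.
#' @export
run_predict <- function(network_path, patient_path, out_path) {
  network <- network_from_json(network_path)
  patients <- readr::read_csv(patient_path, show_col_types = FALSE)
  kinds <- vapply(network$spec$nodes, `[[`, character(1), "kind")
  factors <- names(network$spec$nodes)[kinds == "factor"]
  comps <- names(network$spec$nodes)[kinds == "complication"]
  extra <- setdiff(names(patients), c("patient_id", factors, comps))
  if (length(extra)) {
    rlang::abort(paste0(
      "Unknown factor column(s): ", toString(extra),
      ". Known factors: ", toString(factors)
    ))
  }
  observed_cols <- intersect(factors, names(patients))
  preds <- purrr::map_dfr(seq_len(nrow(patients)), function(i) {
    obs <- unlist(patients[i, observed_cols, drop = FALSE])
    obs <- obs[!is.na(obs)]
    res <- infer(network, obs)
    wide <- tidyr::pivot_wider(
      res,
      names_from = "complication", values_from = "probability"
    )
    dplyr::bind_cols(
      tibble::tibble(
        patient_id = if ("patient_id" %in% names(patients)) {
          patients$patient_id[i]
        } else {
          i
        },
        missing_factors = paste(setdiff(factors, names(obs)), collapse = ";")
      ),
      wide
    )
  })
  readr::write_csv(preds, out_path)
  write_manifest(dirname(out_path), list(
    command = "predict", inputs = c(network_path, patient_path)
  ))
  invisible(preds)
}

#' Evaluate predictions against observed outcomes
#'
#' Joins a predictions CSV (from [run_predict()]) with a cohort CSV holding
#' the true outcomes and sweeps the classification metrics over the
#' cut-offs, producing the published metrics layout (complication, cut-off,
#' sensitivity, specificity, precision).
#'
#' @param predictions_path Predictions CSV.
#' @param cohort_path Cohort CSV with `yes`/`no` outcome columns.
#' @param out_path Output CSV path.
#' @param cutoffs Cut-offs on the percent scale.
#' @return The metrics tibble, invisibly.
#' @export
run_evaluate <- function(predictions_path, cohort_path, out_path,
                         cutoffs = c(60, 70, 80, 90, 100)) {
  preds <- readr::read_csv(predictions_path, show_col_types = FALSE)
  cohort <- read_cohort_csv(cohort_path)
  merged <- dplyr::inner_join(preds, cohort,
    by = "patient_id", suffix = c("_pred", "_true")
  )
  comps <- intersect(
    setdiff(names(preds), c("patient_id", "missing_factors")),
    names(cohort)
  )
  if (!length(comps)) rlang::abort("No shared complication columns to evaluate.")
  metrics <- purrr::map_dfr(comps, function(comp) {
    sweep <- sweep_cutoffs(
      merged[[paste0(comp, "_pred")]],
      merged[[paste0(comp, "_true")]],
      cutoffs
    )
    dplyr::bind_cols(tibble::tibble(complication = comp), tibble::as_tibble(sweep))
  })
  readr::write_csv(metrics, out_path)
  write_manifest(dirname(out_path), list(
    command = "evaluate", inputs = c(predictions_path, cohort_path)
  ))
  invisible(metrics)
}

# every run records what produced its outputs
write_manifest <- function(dir, fields) {
  manifest <- c(
    list(
      package = "diabrisk",
      version = as.character(utils::packageVersion("diabrisk")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    fields
  )
  writeLines(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
    file.path(dir, "manifest.json")
  )
  invisible(manifest)
}
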