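#' Read a labeled dataset from CSV
#'
#' Reads a header CSV with numeric feature columns and one designated label
#' column. Fails loudly, with row/column context, on a missing label
#' column, non-numeric feature columns, or missing values.
#'
#' @param path Path to a CSV file with a header row.
#' @param label Name of the label column (default `"label"`).
#' @param label_kind `"auto"` (categorical if the column is non-numeric),
#'   `"categorical"` (coerce to factor) or `"continuous"`.
#'
#' @return A tibble with numeric features and the label column (factor if
#'   categorical).
#' @export
read_labeled_csv <- function(path, label = "label",
                             label_kind = c("auto", "categorical", "continuous")) {
  label_kind <- match.arg(label_kind)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!label %in% names(data)) {
    dvm_abort(sprintf("label column \"%s\" not found in %s (columns: %s)",
                      label, path, paste(utils::head(names(data), 8),
                                         collapse = ", ")),
              "dvmetric_error_parse")
  }
  feats <- setdiff(names(data), label)
  bad <- feats[!vapply(data[feats], is.numeric, logical(1))]
  if (length(bad)) {
    dvm_abort(sprintf("non-numeric feature column(s) in %s: %s", path,
                      paste(bad, collapse = ", ")),
              "dvmetric_error_parse")
  }
  na_cells <- which(is.na(data), arr.ind = TRUE)
  if (nrow(na_cells)) {
    dvm_abort(sprintf("missing values in %s, e.g. row %d column \"%s\"",
                      path, na_cells[1, 1], names(data)[na_cells[1, 2]]),
              "dvmetric_error_parse")
  }
  y <- data[[label]]
  if (label_kind == "categorical" ||
      (label_kind == "auto" && is_discrete_vector(y))) {
    data[[label]] <- factor(y)
  }
  data
}

#' Write a labeled dataset to CSV with a JSON config sidecar
#'
#' Writes the tibble to `path` and, when the dataset carries a generator
#' configuration (attribute `"config"`, as set by the `simulate_*`
#' generators), a `<path>.json` sidecar with the full configuration and
#' seed.
#'
#' @param data A labeled dataset tibble.
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_labeled_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  config <- attr(data, "config")
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write analysis results to JSON (and tidy CSV)
#'
#' Serializes a result object under a path prefix: `<prefix>.json` always;
#' additionally `<prefix>.csv` with one row per cell and replicate for a
#' `dvm_surface`, and a two-column (`step_feature`, `dvm`) CSV for a
#' `dvm_selection`.
#'
#' @param x A `dvm_result`, `dvm_surface`, or `dvm_selection`.
#' @param prefix Output path prefix (no extension).
#'
#' @return The paths written, invisibly.
#' @export
write_results <- function(x, prefix) {
  json_path <- paste0(prefix, ".json")
  paths <- json_path
  if (inherits(x, "dvm_result")) {
    jsonlite::write_json(dvm_result_payload(x), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (inherits(x, "dvm_surface")) {
    jsonlite::write_json(
      list(cells = x$cells, replicates = x$replicates,
           model_id = x$model_id, lambda = x$lambda, seed = x$seed),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    csv_path <- paste0(prefix, ".csv")
    readr::write_csv(x$replicates, csv_path, progress = FALSE)
    paths <- c(paths, csv_path)
  } else if (inherits(x, "dvm_selection")) {
    jsonlite::write_json(
      list(steps = x$steps, best_subset = x$best_subset,
           best_dvm = x$best_dvm, r = x$r, model_id = x$model_id,
           lambda = x$lambda),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    csv_path <- paste0(prefix, ".csv")
    readr::write_csv(
      tibble::tibble(step_feature = x$steps$feature, dvm = x$steps$dvm),
      csv_path, progress = FALSE)
    paths <- c(paths, csv_path)
  } else {
    dvm_abort("write_results() supports dvm_result, dvm_surface, dvm_selection",
              "dvmetric_error_config")
  }
  invisible(paths)
}
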