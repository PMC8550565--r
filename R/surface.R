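#' Held-out accuracy of a supervised model over the fidelity splits
#'
#' Companion metric to the DVM: the fraction of correct held-out
#' predictions, averaged over the same `M` seeded splits the fidelity uses
#' (identical `cfg` implies identical split indices, so DVM and accuracy
#' are paired).
#'
#' @inheritParams fidelity_supervised
#'
#' @return A `dvm_accuracy` object: `accuracy`, `per_split`, `ci95`,
#'   `splits`.
#' @export
evaluate_accuracy <- function(data, model, label = "label",
                              cfg = fidelity_config()) {
  model <- as_dvm_model(model)
  if (model$mode != "supervised") {
    dvm_abort("accuracy is a supervised metric; the model is unsupervised",
              "dvmetric_error_unsupported_metric")
  }
  parts <- split_features_label(data, label)
  if (!is.factor(parts$y)) {
    dvm_abort("accuracy requires a categorical label",
              "dvmetric_error_unsupported_metric")
  }
  X <- parts$X
  y <- parts$y
  check_split_preconditions(y, nrow(X), cfg)
  splits <- dvm_splits(nrow(X), cfg, labels = y, mode = "supervised")
  per_split <- vapply(splits, function(sp) {
    fitted <- fit_model(model, X[sp$train, , drop = FALSE], y[sp$train], sp$seed)
    t_hat <- apply_model(model, fitted, X[sp$test, , drop = FALSE])
    mean(as.character(t_hat) == as.character(y[sp$test]))
  }, numeric(1))
  structure(
    list(accuracy = mean(per_split), per_split = per_split,
         ci95 = t_ci95(per_split), splits = splits, config = cfg),
    class = "dvm_accuracy"
  )
}

#' @export
print.dvm_accuracy <- function(x, ...) {
  cat(sprintf("<dvm_accuracy> %.4f [95%% CI %.4f, %.4f] over %d splits\n",
              x$accuracy, x$ci95[["low"]], x$ci95[["high"]],
              length(x$per_split)))
  invisible(x)
}

#' DVM / accuracy surface over a sample-size by feature-count grid
#'
#' For every grid cell `(n, p)` and replicate, subsamples the dataset to `n`
#' rows (seeded) and `p` features (seeded, without replacement), computes
#' the DVM and -- for classification tasks -- the paired held-out accuracy,
#' and aggregates over replicates. The complexity regularizer of every cell
#' is normalized against the largest grid point, so the penalty is 1 there
#' and smaller elsewhere. A failing cell (e.g. degenerate clustering at tiny
#' `n`) is recorded with its error message and skipped, not fatal.
#'
#' When a cell asks for the full dataset (`n == nrow(data)` and `p` equal to
#' all features) the data pass through unshuffled, so a 1 x 1 full-size grid
#' reproduces a direct [compute_dvm()] call with the cell's seed.
#'
#' @inheritParams compute_dvm
#' @param n_values,p_values Increasing vectors of sample sizes / feature
#'   counts; must not exceed the dimensions of `data`.
#' @param replicates Number of replicate subsamples per cell (default 3).
#' @param seed Integer seed; per-cell seeds are derived from it.
#' @param verbose Emit per-cell progress via `message()` (stderr).
#'
#' @return A `dvm_surface` object with `replicates` (one row per cell and
#'   replicate) and `cells` (per-cell means with 95% t-intervals over
#'   replicates).
#' @export
dvm_surface <- function(data, model, label = "label", n_values, p_values,
                        replicates = 3, lambda = 0.01,
                        cfg = fidelity_config(), seed = 1L, verbose = FALSE) {
  model <- as_dvm_model(model)
  has_label <- !is.null(label) && label %in% names(data)
  feats <- if (has_label) setdiff(names(data), label) else names(data)
  n_all <- nrow(data)
  p_all <- length(feats)
  n_values <- sort(unique(as.integer(n_values)))
  p_values <- sort(unique(as.integer(p_values)))
  if (max(n_values) > n_all || max(p_values) > p_all) {
    dvm_abort(sprintf("grid exceeds data dimensions (%d x %d)", n_all, p_all),
              "dvmetric_error_bounds")
  }
  grid <- expand.grid(p = p_values, n = n_values)[c("n", "p")]
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    for (g in seq_len(nrow(grid))) {
      ni <- grid$n[g]
      pi <- grid$p[g]
      cell_seed <- derive_seed(seed, rep_i * 100000L + g)
      sub <- with_seed(cell_seed, {
        ridx <- if (ni < n_all) sort(sample.int(n_all, ni)) else seq_len(n_all)
        fidx <- if (pi < p_all) sort(sample.int(p_all, pi)) else seq_len(p_all)
        cols <- feats[fidx]
        if (has_label) cols <- c(cols, label)
        data[ridx, cols]
      })
      cfg_cell <- cfg
      cfg_cell$seed <- cell_seed
      res <- tryCatch(
        compute_dvm(sub, model, label = if (has_label) label else NULL,
                    lambda = lambda, cfg = cfg_cell,
                    reference = c(max(n_values), max(p_values))),
        error = function(e) e
      )
      ok <- inherits(res, "dvm_result")
      if (verbose) {
        message(sprintf("[dvm_surface] rep %d cell n=%d p=%d: %s",
                        rep_i, ni, pi,
                        if (ok) sprintf("dvm=%.4f", res$dvm) else "FAILED"))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = ni, p = pi, replicate = rep_i, seed = cell_seed,
        dvm = if (ok) res$dvm else NA_real_,
        fidelity = if (ok) res$fidelity else NA_real_,
        ci_low = if (ok) res$ci95[["low"]] else NA_real_,
        ci_high = if (ok) res$ci95[["high"]] else NA_real_,
        accuracy = if (ok) res$accuracy else NA_real_,
        regularizer = if (ok) res$regularizer else NA_real_,
        error = if (ok) NA_character_ else conditionMessage(res)
      )
    }
  }
  reps <- dplyr::bind_rows(rows)
  cells <- reps |>
    dplyr::group_by(.data$n, .data$p) |>
    dplyr::summarise(
      dvm_mean = mean(.data$dvm, na.rm = TRUE),
      dvm_ci_low = t_ci95(stats::na.omit(.data$dvm))[["low"]],
      dvm_ci_high = t_ci95(stats::na.omit(.data$dvm))[["high"]],
      accuracy_mean = mean(.data$accuracy, na.rm = TRUE),
      n_ok = sum(is.na(.data$error)),
      n_failed = sum(!is.na(.data$error)),
      .groups = "drop"
    )
  structure(
    list(replicates = reps, cells = cells, n_values = n_values,
         p_values = p_values, model_id = model$id, lambda = lambda,
         seed = seed, config = cfg),
    class = "dvm_surface"
  )
}

#' @export
print.dvm_surface <- function(x, ...) {
  cat(sprintf("<dvm_surface> %s: %d x %d grid, %d replicate rows\n",
              x$model_id, length(x$n_values), length(x$p_values),
              nrow(x$replicates)))
  print(as.data.frame(x$cells), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.dvm_surface <- function(x, ...) x$replicates

#' @export
glance.dvm_surface <- function(x, ...) x$cells

#' @export
autoplot.dvm_surface <- function(object, metric = c("dvm", "accuracy"), ...) {
  metric <- match.arg(metric)
  cells <- object$cells
  cells$y <- if (metric == "dvm") cells$dvm_mean else cells$accuracy_mean
  pl <- ggplot2::ggplot(cells,
                        ggplot2::aes(x = .data$n, y = .data$y,
                                     colour = factor(.data$p),
                                     group = factor(.data$p)))
  if (metric == "dvm") {
    pl <- pl + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$dvm_ci_low, ymax = .data$dvm_ci_high,
                   fill = factor(.data$p)),
      alpha = 0.15, colour = NA)
  }
  pl +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size", y = metric, colour = "features",
                  fill = "features",
                  title = sprintf("%s %s surface", object$model_id, metric)) +
    ggplot2::theme_minimal()
}
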