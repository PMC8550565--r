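#' Compute the Data Value Metric of a dataset for an inference method
#'
#' The Data Value Metric (DVM) scores how much useful information a dataset
#' carries for a specific supervised or unsupervised task:
#' \deqn{\mathrm{DVM} = F - \lambda R,}
#' where `F` is the split-averaged information-bottleneck fidelity (see
#' [fidelity_supervised()] / [fidelity_unsupervised()]) and `R` is the
#' normalized Big-O training-complexity regularizer of the chosen model
#' (see [normalized_regularizer()]). Values near 1 indicate a
#' high-information dataset for the task; values near (or below) 0 indicate
#' that the data carry little extractable signal relative to the
#' computational price of the method.
#'
#' @param data Data frame of numeric features plus (for supervised models) a
#'   label column.
#' @param model A `dvm_model` or registry id string; its `mode` selects the
#'   supervised or unsupervised fidelity procedure.
#' @param label Label column name (default `"label"`).
#' @param lambda Penalty coefficient (>= 0) on the complexity regularizer.
#'   Default 0.01: the regularizer acts as a tie-breaker between similarly
#'   informative configurations.
#' @param cfg A [fidelity_config].
#' @param reference Optional `c(n, p)` reference problem size anchoring the
#'   regularizer at 1; defaults to the dimensions of `data`, so the
#'   regularizer of the full dataset is exactly 1.
#' @param denominator Optional externally fixed normalizing MI passed to the
#'   fidelity procedure (see [fidelity_supervised()]).
#'
#' @return A `dvm_result` with fields `dvm`, `fidelity`,
#'   `per_split_fidelities`, `ci95`, `regularizer`, `lambda`,
#'   `denominator`, `accuracy` (mean held-out accuracy when the task is
#'   classification), `per_split_accuracy`, `model_id`, `n`, `p`, `config`.
#'   `dvm = fidelity - lambda * regularizer` holds exactly.
#' @examples
#' d <- simulate_cluster_square(n = 200, d = 5, seed = 1)
#' r <- compute_dvm(d, dvm_model("decision_tree"), cfg = fidelity_config(seed = 1))
#' r$dvm
#' @export
compute_dvm <- function(data, model, label = "label", lambda = 0.01,
                        cfg = fidelity_config(), reference = NULL,
                        denominator = NULL) {
  model <- as_dvm_model(model)
  if (lambda < 0) dvm_abort("`lambda` must be >= 0", "dvmetric_error_config")
  fid <- if (model$mode == "supervised") {
    fidelity_supervised(data, model, label, cfg, denominator = denominator)
  } else {
    fidelity_unsupervised(data, model, label, cfg, denominator = denominator)
  }
  p <- ncol(data) - as.integer(!is.null(label) && label %in% names(data))
  n <- nrow(data)
  if (is.null(reference)) reference <- c(n, p)
  reg <- normalized_regularizer(model, n, p, reference[1], reference[2])
  acc <- fid$per_split_accuracy
  structure(
    list(dvm = fid$fidelity - lambda * reg,
         fidelity = fid$fidelity,
         per_split_fidelities = fid$per_split_fidelities,
         ci95 = fid$ci95,
         regularizer = reg, lambda = lambda,
         denominator = fid$denominator,
         accuracy = if (all(is.na(acc))) NA_real_ else mean(acc),
         per_split_accuracy = acc,
         splits = fid$splits,
         model_id = model$id, mode = model$mode,
         n = n, p = p, reference = reference,
         config = fid$config, seed = fid$config$seed),
    class = "dvm_result"
  )
}

#' @rdname compute_dvm
#' @export
dvm <- compute_dvm

#' @export
print.dvm_result <- function(x, ...) {
  cat(sprintf("<dvm_result> %s (%s), n = %d, p = %d\n",
              x$model_id, x$mode, x$n, x$p))
  cat(sprintf("  DVM      : %.4f  (fidelity %.4f - lambda %.3g x regularizer %.4f)\n",
              x$dvm, x$fidelity, x$lambda, x$regularizer))
  cat(sprintf("  fidelity : %.4f  [95%% CI %.4f, %.4f] over %d splits\n",
              x$fidelity, x$ci95[["low"]], x$ci95[["high"]],
              length(x$per_split_fidelities)))
  if (!is.na(x$accuracy)) {
    cat(sprintf("  accuracy : %.4f  (mean held-out, same splits)\n", x$accuracy))
  }
  invisible(x)
}

#' @export
tidy.dvm_result <- function(x, ...) {
  tibble::tibble(
    split = seq_along(x$per_split_fidelities),
    fidelity = x$per_split_fidelities,
    accuracy = x$per_split_accuracy
  )
}

#' @export
glance.dvm_result <- function(x, ...) {
  tibble::tibble(
    dvm = x$dvm, fidelity = x$fidelity,
    ci_low = x$ci95[["low"]], ci_high = x$ci95[["high"]],
    regularizer = x$regularizer, lambda = x$lambda,
    accuracy = x$accuracy, denominator = x$denominator,
    model_id = x$model_id, mode = x$mode, n = x$n, p = x$p,
    n_splits = length(x$per_split_fidelities), seed = x$seed
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.dvm_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$split, y = .data$fidelity)) +
    ggplot2::geom_hline(yintercept = object$fidelity, linetype = 2,
                        colour = "grey40") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci95[["low"]], ymax = object$ci95[["high"]],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "split", y = "per-split fidelity",
                  title = sprintf("%s: DVM = %.3f", object$model_id, object$dvm)) +
    ggplot2::theme_minimal()
}

dvm_result_payload <- function(x) {
  list(
    fidelity = x$fidelity,
    per_split_fidelities = x$per_split_fidelities,
    ci95 = c(x$ci95[["low"]], x$ci95[["high"]]),
    regularizer = x$regularizer,
    lambda = x$lambda,
    dvm = x$dvm,
    accuracy = x$accuracy,
    config = list(
      beta = x$config$beta, n_splits = x$config$n_splits,
      train_fraction = x$config$train_fraction,
      split_fractions = x$config$split_fractions,
      estimator = x$config$estimator, mi_floor = x$config$mi_floor,
      model_id = x$model_id, mode = x$mode, n = x$n, p = x$p
    ),
    seed = x$seed
  )
}
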