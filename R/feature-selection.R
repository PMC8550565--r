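#' Greedy forward feature selection by DVM gain
#'
#' Starting from the empty set, repeats `r` times: score every not-yet
#' selected feature by the DVM of the current subset plus that feature, and
#' add the best one (argmax; ties broken toward the lowest feature index).
#' Within a step all candidates are evaluated with the same derived split
#' seed, so candidate comparisons are paired. The full `r`-step trace is
#' returned together with the subset at the maximum DVM over the trace: the
#' curve is not expected to be monotone (the complexity regularizer and the
#' extra-input penalty both grow with the subset), and its local maximum is
#' the natural stopping point.
#'
#' The DVM of the empty feature set is taken as 0 (no representation, no
#' information). Candidates whose evaluation fails (e.g. no measurable
#' signal) score `NA` and are never selected.
#'
#' The fidelity denominator \eqn{I(X; Y)} is estimated once on the full
#' initial feature set and held fixed across all subset evaluations: the
#' initial set defines the task's total information, and each subset is
#' scored by how much of it the model recovers. (Re-normalizing per subset
#' would let any single feature "explain" all of its own information,
#' saturating the score and defeating the selection.)
#'
#' @param data Data frame: numeric features plus a label column.
#' @param model A `dvm_model` used to score subsets.
#' @param r Number of selection steps (`1 <= r <= p`).
#' @param label Label column name.
#' @param lambda Complexity penalty passed to [compute_dvm()].
#' @param cfg A [fidelity_config]; per-step split seeds are derived from
#'   `cfg$seed`.
#'
#' @return A `dvm_selection` object: `steps` (tibble with `step`, `feature`,
#'   `dvm`, `seed`), `best_subset`, `best_dvm`, `best_step`, `r`.
#' @examples
#' d <- simulate_cluster_square(n = 200, d = 6, seed = 1)
#' tr <- select_features(d, dvm_model("decision_tree"), r = 3,
#'                       cfg = fidelity_config(n_splits = 3, seed = 1))
#' tr$best_subset
#' @export
select_features <- function(data, model, r, label = "label", lambda = 0.01,
                            cfg = fidelity_config()) {
  model <- as_dvm_model(model)
  parts <- split_features_label(data, label)
  feats <- setdiff(names(data), label)
  p <- length(feats)
  n <- nrow(data)
  if (r < 1 || r > p) {
    dvm_abort(sprintf("`r` must satisfy 1 <= r <= p (r = %d, p = %d)", r, p),
              "dvmetric_error_parameter")
  }
  den_full <- cfg_mi(cfg, parts$X, parts$y)
  if (den_full <= cfg$mi_floor) {
    dvm_abort(sprintf(
      "estimated I(X;Y) = %.3g nats on the full feature set is at or below the floor %.3g",
      den_full, cfg$mi_floor), "dvmetric_error_degenerate_signal")
  }
  selected <- character(0)
  steps <- vector("list", r)
  for (step in seq_len(r)) {
    step_cfg <- cfg
    step_cfg$seed <- derive_seed(cfg$seed, step)
    candidates <- setdiff(feats, selected)
    scores <- vapply(candidates, function(cand) {
      sub <- data[c(selected, cand, label)]
      tryCatch(
        compute_dvm(sub, model, label = label, lambda = lambda,
                    cfg = step_cfg, reference = c(n, p),
                    denominator = den_full)$dvm,
        dvmetric_error = function(e) NA_real_
      )
    }, numeric(1))
    if (all(is.na(scores))) {
      dvm_abort(sprintf("all candidate evaluations failed at step %d", step),
                "dvmetric_error_degenerate_signal")
    }
    best <- which.max(scores) # first (= lowest feature index) among ties
    selected <- c(selected, candidates[best])
    steps[[step]] <- tibble::tibble(step = step, feature = candidates[best],
                                    dvm = scores[[best]], seed = step_cfg$seed)
  }
  steps <- dplyr::bind_rows(steps)
  best_step <- which.max(steps$dvm)
  structure(
    list(steps = steps,
         best_subset = steps$feature[seq_len(best_step)],
         best_dvm = steps$dvm[best_step],
         best_step = best_step,
         r = r, model_id = model$id, lambda = lambda, config = cfg),
    class = "dvm_selection"
  )
}

#' @export
print.dvm_selection <- function(x, ...) {
  cat(sprintf("<dvm_selection> %d steps (%s), peak DVM = %.4f at step %d\n",
              x$r, x$model_id, x$best_dvm, x$best_step))
  cat("  best subset:", paste(x$best_subset, collapse = ", "), "\n")
  print(as.data.frame(x$steps[c("step", "feature", "dvm")]), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.dvm_selection <- function(x, ...) x$steps

#' @export
glance.dvm_selection <- function(x, ...) {
  tibble::tibble(best_dvm = x$best_dvm, best_step = x$best_step,
                 n_selected = length(x$best_subset), r = x$r,
                 model_id = x$model_id, lambda = x$lambda)
}

#' @export
autoplot.dvm_selection <- function(object, ...) {
  df <- object$steps
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$dvm)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = df[object$best_step, ], colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$feature) +
    ggplot2::labs(x = "selected feature", y = "DVM after adding",
                  title = sprintf("forward selection: peak DVM = %.3f",
                                  object$best_dvm)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
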