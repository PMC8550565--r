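#' Configuration for DVM fidelity estimation
#'
#' Bundles the settings of the split-and-estimate procedure behind the DVM
#' fidelity term: the information-bottleneck weight `beta`, the number of
#' repeated random splits `M`, the split geometry, the MI estimator, and the
#' seed that makes the whole computation reproducible.
#'
#' @param beta Weight (>= 0) on the conditional compression penalty
#'   \eqn{I(X; T | Y)} in the fidelity numerator. Default 0.1, keeping the
#'   label-information term dominant.
#' @param n_splits Number of repeated random splits `M` (>= 2 so a
#'   confidence interval exists). Default 10.
#' @param train_fraction Training fraction for supervised splits
#'   (default 0.7). Splits are stratified by class for categorical labels.
#' @param split_fractions Length-3 fractions (summing to 1) of the three-way
#'   split used by the unsupervised procedure: two training parts and one
#'   held-out validation part. Default `c(0.4, 0.4, 0.2)`.
#' @param estimator MI estimator id used inside the fidelity term:
#'   `"auto"` (default: plug-in for categorical pairs, KSG for
#'   low-dimensional continuous pairs, hash ensemble for mixed or
#'   high-dimensional pairs; see [estimate_mi()]), `"plugin"`, `"knn"`, or
#'   `"hash"`.
#' @param k Neighbour count for the knn estimator (default 5).
#' @param hash A [hash_config] for the hash estimator.
#' @param mi_floor Positive floor (in nats) on the full-data normalizing MI
#'   \eqn{I(X; Y)}; below it the data carry no measurable task signal and
#'   the fidelity ratio is refused rather than divided toward infinity.
#'   Default `1e-3`.
#' @param seed Integer seed; per-split seeds are derived from it.
#'
#' @return A `fidelity_config` list.
#' @export
fidelity_config <- function(beta = 0.1, n_splits = 10, train_fraction = 0.7,
                            split_fractions = c(0.4, 0.4, 0.2),
                            estimator = "auto", k = 5, hash = hash_config(),
                            mi_floor = 1e-3, seed = 1L) {
  if (beta < 0) dvm_abort("`beta` must be >= 0", "dvmetric_error_config")
  if (n_splits < 2) {
    dvm_abort("`n_splits` must be >= 2 for a confidence interval",
              "dvmetric_error_config")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    dvm_abort("`train_fraction` must be in (0, 1)", "dvmetric_error_config")
  }
  if (length(split_fractions) != 3 || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-8) {
    dvm_abort("`split_fractions` must be 3 positive fractions summing to 1",
              "dvmetric_error_config")
  }
  if (!estimator %in% c("auto", "plugin", "knn", "hash")) {
    dvm_abort(sprintf("unknown estimator id \"%s\"", estimator),
              "dvmetric_error_config")
  }
  structure(
    list(beta = beta, n_splits = as.integer(n_splits),
         train_fraction = train_fraction, split_fractions = split_fractions,
         estimator = estimator, k = k, hash = hash,
         mi_floor = mi_floor, seed = as.integer(seed)),
    class = "fidelity_config"
  )
}

cfg_mi <- function(cfg, x, y) {
  estimate_mi(x, y, estimator = cfg$estimator, k = cfg$k, config = cfg$hash)$value
}

cfg_cmi <- function(cfg, x, y, z) {
  mi_conditional(x, y, z, estimator = cfg$estimator, k = cfg$k,
                 config = cfg$hash)$value
}

#' Seeded random splits used by the fidelity procedures
#'
#' Exposed so that companion metrics (held-out accuracy) and paired
#' comparisons (feature-selection candidates) can be computed on identical
#' splits. Supervised splits are stratified by class when `labels` is a
#' factor; unsupervised splits are three-way per `split_fractions`.
#'
#' @param n Number of samples.
#' @param cfg A [fidelity_config].
#' @param labels Optional label vector (stratifies categorical splits).
#' @param mode `"supervised"` (train/test) or `"unsupervised"` (three-way).
#'
#' @return A list of `n_splits` splits; each is a list of index vectors
#'   (`train`/`test`, or `train1`/`train2`/`test`) plus the derived `seed`.
#' @export
dvm_splits <- function(n, cfg, labels = NULL, mode = "supervised") {
  lapply(seq_len(cfg$n_splits), function(i) {
    s <- derive_seed(cfg$seed, i)
    with_seed(s, {
      if (mode == "supervised") {
        if (is.factor(labels)) {
          train <- unlist(lapply(split(seq_len(n), labels), function(idx) {
            sample(idx, max(1L, round(cfg$train_fraction * length(idx))))
          }), use.names = FALSE)
        } else {
          train <- sample.int(n, max(1L, round(cfg$train_fraction * n)))
        }
        train <- sort(train)
        list(train = train, test = setdiff(seq_len(n), train), seed = s)
      } else {
        f <- cfg$split_fractions
        perm <- sample.int(n)
        n1 <- max(1L, floor(f[1] * n))
        n2 <- max(1L, floor(f[2] * n))
        if (n1 + n2 >= n) {
          dvm_abort("dataset too small for a three-way split",
                    "dvmetric_error_parameter")
        }
        list(train1 = sort(perm[seq_len(n1)]),
             train2 = sort(perm[n1 + seq_len(n2)]),
             test = sort(perm[(n1 + n2 + 1):n]), seed = s)
      }
    })
  })
}

# Extract (X, y) from a data frame given the label column name.
split_features_label <- function(data, label, require_label = TRUE) {
  data <- as.data.frame(data)
  y <- NULL
  if (!is.null(label)) {
    if (!label %in% names(data)) {
      if (require_label) {
        dvm_abort(sprintf("label column \"%s\" not found in data", label),
                  "dvmetric_error_parse")
      }
    } else {
      y <- data[[label]]
      data <- data[setdiff(names(data), label)]
      if (is_discrete_vector(y)) y <- factor(y)
    }
  }
  bad <- names(data)[!vapply(data, is.numeric, logical(1))]
  if (length(bad)) {
    dvm_abort(sprintf("non-numeric feature column(s): %s",
                      paste(bad, collapse = ", ")),
              "dvmetric_error_parse")
  }
  X <- as.matrix(data)
  if (anyNA(X) || (!is.null(y) && anyNA(y))) {
    dvm_abort("data contain missing values", "dvmetric_error_parse")
  }
  if (nrow(X) < 2 || ncol(X) < 1) {
    dvm_abort("need at least 2 samples and 1 feature", "dvmetric_error_parameter")
  }
  list(X = X, y = y)
}

check_split_preconditions <- function(y, n, cfg) {
  test_frac <- 1 - cfg$train_fraction
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) < 2) {
      dvm_abort("labels contain a single class", "dvmetric_error_degenerate_label")
    }
    min_test <- min(round(test_frac * table(droplevels(y))))
    if (min_test < 2) {
      dvm_abort("too few samples per class: each split's test set needs >= 2 per class",
                "dvmetric_error_parameter")
    }
  } else {
    if (round(test_frac * n) < 20) {
      dvm_abort("continuous-label splits need >= 20 held-out samples",
                "dvmetric_error_parameter")
    }
  }
}

new_dvm_fidelity <- function(per_split, denominator, acc, splits, cfg, mode) {
  ci <- t_ci95(per_split)
  structure(
    list(fidelity = mean(per_split), per_split_fidelities = per_split,
         ci95 = ci, denominator = denominator,
         per_split_accuracy = acc, splits = splits,
         config = cfg, mode = mode),
    class = "dvm_fidelity"
  )
}

#' Supervised DVM fidelity
#'
#' Estimates the fidelity term of the Data Value Metric for a supervised
#' task over `M` seeded random train/test splits. For split `i`, the model
#' is fit on the training part and applied to the held-out part, yielding a
#' representation \eqn{\tilde T_i} (predicted labels by default), and
#' \deqn{F_i = \frac{I(\tilde T_i; \tilde Y_i) - \beta\, I(\tilde X_i; \tilde T_i \mid \tilde Y_i)}
#'                  {I(X; Y)},}
#' where the normalizing \eqn{I(X; Y)} is estimated once on the full
#' dataset. The reported fidelity is the mean of the per-split values with a
#' Student-t 95% confidence interval.
#'
#' @param data Data frame: numeric feature columns plus one label column.
#' @param model A supervised `dvm_model` (see [dvm_model()]).
#' @param label Name of the label column (default `"label"`).
#' @param cfg A [fidelity_config].
#' @param denominator Optional externally fixed normalizing MI (in nats).
#'   Used by [select_features()], where the task's total information is
#'   defined by the full initial feature set and must not be re-estimated
#'   per candidate subset. Default `NULL`: estimate \eqn{I(X;Y)} from
#'   `data`.
#'
#' @return A `dvm_fidelity` object: `fidelity`, `per_split_fidelities`,
#'   `ci95`, `denominator`, `per_split_accuracy` (categorical labels only),
#'   and the splits used.
#' @export
fidelity_supervised <- function(data, model, label = "label",
                                cfg = fidelity_config(), denominator = NULL) {
  model <- as_dvm_model(model)
  if (model$mode != "supervised") {
    dvm_abort("model is not supervised", "dvmetric_error_config")
  }
  parts <- split_features_label(data, label)
  X <- parts$X
  y <- parts$y
  if (is.null(y)) {
    dvm_abort(sprintf("label column \"%s\" not found in data", label),
              "dvmetric_error_parse")
  }
  n <- nrow(X)
  check_split_preconditions(y, n, cfg)
  denom <- denominator %||% cfg_mi(cfg, X, y)
  if (denom <= cfg$mi_floor) {
    dvm_abort(sprintf(
      "estimated I(X;Y) = %.3g nats is at or below the floor %.3g: no measurable task signal",
      denom, cfg$mi_floor), "dvmetric_error_degenerate_signal")
  }
  splits <- dvm_splits(n, cfg, labels = if (is.factor(y)) y else NULL,
                       mode = "supervised")
  per_split <- numeric(length(splits))
  acc <- rep(NA_real_, length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    fitted <- fit_model(model, X[sp$train, , drop = FALSE], y[sp$train], sp$seed)
    t_hat <- apply_model(model, fitted, X[sp$test, , drop = FALSE])
    y_test <- y[sp$test]
    num <- cfg_mi(cfg, t_hat, y_test)
    pen <- if (cfg$beta > 0) {
      cfg_cmi(cfg, X[sp$test, , drop = FALSE], t_hat, y_test)
    } else 0
    per_split[i] <- (num - cfg$beta * pen) / denom
    if (is.factor(y) && is.null(dim(t_hat))) {
      acc[i] <- mean(as.character(t_hat) == as.character(y_test))
    }
  }
  new_dvm_fidelity(per_split, denom, acc, splits, cfg, "supervised")
}

#' Unsupervised DVM fidelity (clustering stability)
#'
#' Estimates the fidelity term for a clustering task over `M` seeded
#' three-way splits \eqn{(X', X'', \tilde X)}. The model is fit separately
#' on \eqn{X'} and on \eqn{X''}; both fitted models are applied to the
#' common held-out part \eqn{\tilde X}, giving two paired labelings
#' \eqn{\hat Y_i} and \eqn{\tilde T_i} of the same points. Their mutual
#' information, which is invariant to cluster relabeling, measures the
#' stability of the clustering:
#' \deqn{F_i = \frac{I(\tilde T_i; \hat Y_i) - \beta\, I(\tilde X_i; \tilde T_i \mid \hat Y_i)}
#'                  {I(X; \hat Y)},}
#' with \eqn{\hat Y} the labels obtained by fitting and applying the model
#' on the full dataset.
#'
#' @param data Data frame of numeric features (a label column, if present,
#'   is dropped).
#' @param model An unsupervised `dvm_model`.
#' @param label Name of a label column to drop, if present (default
#'   `"label"`).
#' @inheritParams fidelity_supervised
#'
#' @return A `dvm_fidelity` object (accuracy slots are `NA`).
#' @export
fidelity_unsupervised <- function(data, model, label = "label",
                                  cfg = fidelity_config(), denominator = NULL) {
  model <- as_dvm_model(model)
  if (model$mode != "unsupervised") {
    dvm_abort("model is not unsupervised", "dvmetric_error_config")
  }
  parts <- split_features_label(data, label, require_label = FALSE)
  X <- parts$X
  n <- nrow(X)
  check_clusters <- function(lab, part) {
    if (length(unique(as.character(lab))) < 2) {
      dvm_abort(sprintf("clustering returned a single cluster on %s", part),
                "dvmetric_error_degenerate_clustering")
    }
    lab
  }
  full_fit <- fit_model(model, X, NULL, cfg$seed)
  y_full <- check_clusters(apply_model(model, full_fit, X), "the full dataset")
  denom <- denominator %||% cfg_mi(cfg, X, y_full)
  if (denom <= cfg$mi_floor) {
    dvm_abort(sprintf(
      "estimated I(X;Yhat) = %.3g nats is at or below the floor %.3g",
      denom, cfg$mi_floor), "dvmetric_error_degenerate_signal")
  }
  splits <- dvm_splits(n, cfg, mode = "unsupervised")
  per_split <- numeric(length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    f1 <- fit_model(model, X[sp$train1, , drop = FALSE], NULL, sp$seed)
    f2 <- fit_model(model, X[sp$train2, , drop = FALSE], NULL,
                    derive_seed(sp$seed, 1L))
    Xt <- X[sp$test, , drop = FALSE]
    y_hat <- check_clusters(apply_model(model, f1, Xt), "a training part")
    t_hat <- check_clusters(apply_model(model, f2, Xt), "a training part")
    num <- cfg_mi(cfg, t_hat, y_hat)
    pen <- if (cfg$beta > 0) cfg_cmi(cfg, Xt, t_hat, y_hat) else 0
    per_split[i] <- (num - cfg$beta * pen) / denom
  }
  new_dvm_fidelity(per_split, denom, rep(NA_real_, length(splits)), splits,
                   cfg, "unsupervised")
}

#' Information-bottleneck score of a representation
#'
#' Computes \eqn{I(T; Y) - \beta I(X; T)}: how informative the
#' representation `t` is about the label `y`, penalized by how much of the
#' input `x` it retains. Unlike the DVM fidelity this is unnormalized and
#' has no fixed range.
#'
#' @param x Input samples.
#' @param t Representation samples (aligned with `x`).
#' @param y Label samples (aligned with `x`).
#' @param beta Penalty weight (>= 0).
#' @inheritParams estimate_mi
#'
#' @return A single number (may be negative).
#' @export
ib_score <- function(x, t, y, beta = 0.1, estimator = "plugin", k = 5,
                     config = hash_config()) {
  estimate_mi(t, y, estimator, k, config)$value -
    beta * estimate_mi(x, t, estimator, k, config)$value
}

#' Single-shot DVM fidelity of a representation
#'
#' Evaluates \eqn{(I(T;Y) - \beta I(X;T|Y)) / I(X;Y)} on one aligned sample
#' triple, without any splitting. With the exact plug-in estimator and a
#' representation that is a deterministic function of `x`, the value never
#' exceeds 1 (data-processing bound), with equality exactly when
#' \eqn{I(X;Y|T) = 0} and \eqn{I(X;T|Y) = 0}.
#'
#' @inheritParams ib_score
#' @param mi_floor Positive floor on the normalizing \eqn{I(X;Y)}.
#'
#' @return A single number.
#' @export
ib_fidelity <- function(x, t, y, beta = 0.1, estimator = "plugin", k = 5,
                        config = hash_config(), mi_floor = 1e-3) {
  denom <- estimate_mi(x, y, estimator, k, config)$value
  if (denom <= mi_floor) {
    dvm_abort(sprintf("I(X;Y) = %.3g is at or below the floor %.3g",
                      denom, mi_floor),
              "dvmetric_error_degenerate_signal")
  }
  num <- estimate_mi(t, y, estimator, k, config)$value
  pen <- if (beta > 0) {
    mi_conditional(x, t, y, estimator, k, config)$value
  } else 0
  (num - beta * pen) / denom
}
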