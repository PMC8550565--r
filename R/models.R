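# Inference-model registry: every model is a fit/apply pair plus symbolic
# Big-O training and prediction costs in (n, p, hyperparameters). The costs
# use unit constants, so training_complexity(random_forest, 100, 10) with 10
# trees is exactly 100^2 * 10 * 10.

as_feature_frame <- function(X) {
  df <- as.data.frame(X)
  if (is.null(colnames(X))) {
    names(df) <- paste0("V", seq_len(ncol(df)))
  }
  df
}

nearest_rows <- function(X, centers) {
  # index of the nearest row of `centers` for each row of X (squared Euclid)
  cross <- X %*% t(centers)
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}

# Affinity propagation (Frey-Dueck message passing) on the negative squared
# Euclidean similarity; preference = median off-diagonal similarity.
ap_cluster <- function(X, damping = 0.9, maxit = 200, preference = NULL) {
  n <- nrow(X)
  S <- -as.matrix(stats::dist(X))^2
  if (is.null(preference)) preference <- stats::median(S[upper.tri(S)])
  diag(S) <- preference
  R <- A <- matrix(0, n, n)
  for (it in seq_len(maxit)) {
    AS <- A + S
    idx <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), idx)]
    AS[cbind(seq_len(n), idx)] <- -Inf
    m2 <- apply(AS, 1, max)
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] - m2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    cs <- colSums(Rp)
    Anew <- pmin(matrix(rep(diag(R) + cs - pmax(diag(R), 0), each = n), n, n) - Rp, 0)
    diag(Anew) <- cs - pmax(diag(R), 0)
    A <- damping * A + (1 - damping) * Anew
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0) ex <- which.max(diag(R) + diag(A))
  lab <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  lab[ex] <- seq_along(ex)
  list(exemplars = X[ex, , drop = FALSE], labels = lab)
}

model_registry <- function() {
  list(
    linear_regression = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        if (is.factor(y)) {
          dvm_abort("linear_regression requires a continuous label",
                    "dvmetric_error_parameter")
        }
        fit <- stats::lm.fit(cbind(1, X), y)
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        list(coef = cf)
      },
      apply = function(fitted, X) drop(cbind(1, X) %*% fitted$coef),
      training_cost = function(n, p, hp) p^2 * n + p^3,
      prediction_cost = function(n, p, hp) p
    ),
    decision_tree = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        df <- as_feature_frame(X)
        df$.y <- y
        ctl <- rpart::rpart.control(minsplit = hp$minsplit %||% 20,
                                    cp = hp$cp %||% 0.01, xval = 0)
        rpart::rpart(.y ~ ., data = df, control = ctl)
      },
      apply = function(fitted, X) {
        if (fitted$method == "class") {
          predict(fitted, as_feature_frame(X), type = "class")
        } else {
          predict(fitted, as_feature_frame(X), type = "vector")
        }
      },
      training_cost = function(n, p, hp) n^2 * p,
      prediction_cost = function(n, p, hp) p
    ),
    random_forest = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        ranger::ranger(x = as_feature_frame(X), y = y,
                       num.trees = hp$k_trees %||% 100,
                       seed = seed %||% 1L, num.threads = 1)
      },
      apply = function(fitted, X) {
        predict(fitted, data = as_feature_frame(X), num.threads = 1)$predictions
      },
      training_cost = function(n, p, hp) n^2 * p * (hp$k_trees %||% 100),
      prediction_cost = function(n, p, hp) p * (hp$k_trees %||% 100)
    ),
    gradient_boosting = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        nrounds <- hp$k_trees %||% 100
        lv <- if (is.factor(y)) levels(y) else NULL
        params <- list(
          max_depth = hp$max_depth %||% 3, eta = hp$eta %||% 0.3,
          nthread = 1, seed = seed %||% 1L
        )
        if (is.null(lv)) {
          params$objective <- "reg:squarederror"
          label <- y
        } else {
          params$objective <- "multi:softmax"
          params$num_class <- length(lv)
          label <- as.integer(y) - 1L
        }
        dtrain <- xgboost::xgb.DMatrix(X, label = label, nthread = 1)
        bst <- xgboost::xgb.train(params, dtrain, nrounds = nrounds)
        list(bst = bst, levels = lv)
      },
      apply = function(fitted, X) {
        pred <- predict(fitted$bst, xgboost::xgb.DMatrix(X, nthread = 1))
        if (!is.null(fitted$levels)) {
          factor(fitted$levels[pred + 1L], levels = fitted$levels)
        } else {
          pred
        }
      },
      training_cost = function(n, p, hp) n * p * (hp$k_trees %||% 100),
      prediction_cost = function(n, p, hp) p * (hp$k_trees %||% 100)
    ),
    svm = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        e1071::svm(x = X, y = y, kernel = hp$kernel %||% "radial",
                   scale = hp$scale %||% FALSE)
      },
      apply = function(fitted, X) unname(predict(fitted, X)),
      training_cost = function(n, p, hp) n^2 * p + n^3,
      prediction_cost = function(n, p, hp) {
        if (is.null(hp$m_sv)) {
          dvm_abort("svm prediction cost needs hyperparameter `m_sv`",
                    "dvmetric_error_missing_cost")
        }
        hp$m_sv * p
      }
    ),
    k_nearest_neighbors = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        if (!is.factor(y)) {
          dvm_abort("k_nearest_neighbors supports categorical labels only",
                    "dvmetric_error_parameter")
        }
        list(X = X, y = y, k = hp$k %||% 5)
      },
      apply = function(fitted, X) {
        class::knn(train = fitted$X, test = X, cl = fitted$y, k = fitted$k)
      },
      training_cost = NULL, # complexity of training "varies"
      prediction_cost = function(n, p, hp) n * p
    ),
    naive_bayes = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        if (!is.factor(y)) {
          dvm_abort("naive_bayes supports categorical labels only",
                    "dvmetric_error_parameter")
        }
        e1071::naiveBayes(x = as_feature_frame(X), y = y)
      },
      apply = function(fitted, X) predict(fitted, as_feature_frame(X)),
      training_cost = function(n, p, hp) n * p,
      prediction_cost = function(n, p, hp) p
    ),
    neural_network = list(
      mode = "supervised",
      fit = function(X, y, hp, seed) {
        dvm_abort("no built-in fit for neural_network; supply a custom model",
                  "dvmetric_error_config")
      },
      apply = function(fitted, X) NULL,
      training_cost = NULL, # "varies"
      prediction_cost = NULL
    ),
    k_means = list(
      mode = "unsupervised",
      fit = function(X, y, hp, seed) {
        with_seed(seed %||% 1L, {
          km <- stats::kmeans(X, centers = hp$k %||% 5,
                              nstart = hp$nstart %||% 5, iter.max = 50)
          list(centers = km$centers)
        })
      },
      apply = function(fitted, X) {
        factor(nearest_rows(X, fitted$centers))
      },
      # cost per sweep; iteration count treated as a constant
      training_cost = function(n, p, hp) n * p * (hp$k %||% 5),
      prediction_cost = function(n, p, hp) p * (hp$k %||% 5)
    ),
    agglomerative = list(
      mode = "unsupervised",
      fit = function(X, y, hp, seed) {
        hc <- stats::hclust(stats::dist(X), method = hp$linkage %||% "ward.D2")
        cl <- stats::cutree(hc, k = hp$k %||% 5)
        centers <- rowsum(X, cl) / as.vector(table(cl))
        list(centers = centers)
      },
      apply = function(fitted, X) factor(nearest_rows(X, fitted$centers)),
      training_cost = function(n, p, hp) n^2 * p,
      prediction_cost = function(n, p, hp) p * (hp$k %||% 5)
    ),
    affinity_propagation = list(
      mode = "unsupervised",
      fit = function(X, y, hp, seed) {
        res <- ap_cluster(X, damping = hp$damping %||% 0.9,
                          maxit = hp$maxit %||% 200,
                          preference = hp$preference)
        list(exemplars = res$exemplars)
      },
      apply = function(fitted, X) factor(nearest_rows(X, fitted$exemplars)),
      training_cost = function(n, p, hp) n^2 * p,
      prediction_cost = function(n, p, hp) p
    )
  )
}

#' Construct an inference model from the built-in registry
#'
#' Returns a model specification usable by [compute_dvm()],
#' [fidelity_supervised()], [fidelity_unsupervised()], [select_features()]
#' and [dvm_surface()]. Each registry entry couples a fit/apply pair (the
#' encoder-decoder of the task: fit on a training subset, apply to held-out
#' samples yielding a low-dimensional representation, by default the
#' predicted labels) with symbolic Big-O training and prediction costs.
#'
#' Available ids: `linear_regression`, `decision_tree`, `random_forest`,
#' `gradient_boosting`, `svm`, `k_nearest_neighbors`, `naive_bayes`
#' (supervised); `k_means`, `agglomerative`, `affinity_propagation`
#' (unsupervised). `neural_network` exists in the complexity registry only.
#' Training complexities of `k_nearest_neighbors` and `neural_network`
#' "vary" and require either a user cost function (hyperparameter `cost`)
#' or, for kNN, opt-in to its documented `n * p` prediction cost via
#' `use_default_cost = TRUE`.
#'
#' @param id Registry identifier (see above).
#' @param ... Hyperparameters passed to the fit function and the cost
#'   formulas, e.g. `k_trees` (tree ensembles, default 100), `k` (number of
#'   clusters / neighbours, default 5), `minsplit`, `cp` (decision tree),
#'   `kernel` (svm), `cost` (user complexity function of `(n, p, hp)`).
#'
#' @return A `dvm_model` object.
#' @examples
#' dvm_model("random_forest", k_trees = 50)
#' @export
dvm_model <- function(id, ...) {
  reg <- model_registry()
  if (!id %in% names(reg)) {
    dvm_abort(sprintf("unknown model id \"%s\" (see ?dvm_model)", id),
              "dvmetric_error_config")
  }
  entry <- reg[[id]]
  structure(
    list(id = id, mode = entry$mode, hyperparams = list(...),
         fit = entry$fit, apply = entry$apply,
         training_cost = entry$training_cost,
         prediction_cost = entry$prediction_cost),
    class = "dvm_model"
  )
}

#' Construct a user-defined inference model
#'
#' Escape hatch for models outside the registry (including feature-layer
#' representations: `apply` may return an n x d numeric matrix instead of
#' predicted labels).
#'
#' @param fit `function(X, y, hp, seed)` returning a fitted object (`y` is
#'   `NULL` in unsupervised mode).
#' @param apply `function(fitted, X)` returning per-sample predictions (a
#'   vector) or a representation matrix aligned with the rows of `X`.
#' @param mode `"supervised"` or `"unsupervised"`.
#' @param training_cost Optional `function(n, p, hp)` giving the abstract
#'   training operation count.
#' @param prediction_cost Optional `function(n, p, hp)`.
#' @param id Identifier used in reports.
#' @param ... Hyperparameters.
#'
#' @return A `dvm_model` object.
#' @export
dvm_model_custom <- function(fit, apply, mode = c("supervised", "unsupervised"),
                             training_cost = NULL, prediction_cost = NULL,
                             id = "custom", ...) {
  mode <- match.arg(mode)
  structure(
    list(id = id, mode = mode, hyperparams = list(...),
         fit = fit, apply = apply,
         training_cost = training_cost, prediction_cost = prediction_cost),
    class = "dvm_model"
  )
}

#' @export
print.dvm_model <- function(x, ...) {
  cat(sprintf("<dvm_model> %s (%s)\n", x$id, x$mode))
  if (length(x$hyperparams)) {
    cat("  hyperparams:",
        paste(names(x$hyperparams), unlist(lapply(x$hyperparams, format)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

as_dvm_model <- function(model) {
  if (inherits(model, "dvm_model")) return(model)
  if (is.character(model) && length(model) == 1) return(dvm_model(model))
  dvm_abort("`model` must be a dvm_model or a registry id string",
            "dvmetric_error_config")
}

#' Abstract training cost of a model at a given problem size
#'
#' Evaluates the model's symbolic Big-O training-complexity formula with unit
#' constants at sample size `n` and feature count `p`. Models whose training
#' complexity "varies" (k-nearest neighbours, neural networks) require either
#' a user-supplied `cost` hyperparameter or, for kNN, the documented opt-in
#' `use_default_cost = TRUE` which falls back to its `n * p` prediction cost.
#'
#' @param model A `dvm_model` or registry id string.
#' @param n,p Positive integers: training sample size and feature count.
#'
#' @return A positive number (abstract operation count).
#' @examples
#' training_complexity(dvm_model("random_forest", k_trees = 10), 100, 10)
#' @export
training_complexity <- function(model, n, p) {
  model <- as_dvm_model(model)
  if (n < 1 || p < 1) {
    dvm_abort("`n` and `p` must be positive", "dvmetric_error_parameter")
  }
  hp <- model$hyperparams
  if (is.function(hp$cost)) {
    return(hp$cost(n, p, hp))
  }
  if (is.null(model$training_cost)) {
    if (model$id == "k_nearest_neighbors" && isTRUE(hp$use_default_cost)) {
      return(n * p)
    }
    dvm_abort(
      sprintf("training complexity of \"%s\" varies; supply a `cost` hyperparameter",
              model$id),
      "dvmetric_error_missing_cost"
    )
  }
  model$training_cost(n, p, hp)
}

#' Normalized complexity regularizer
#'
#' Maps the abstract training cost at `(n, p)` into `[0, 1]` by
#' `log(1 + cost(n, p)) / log(1 + cost(reference_n, reference_p))`. Equals 1
#' at the reference point and is monotone nondecreasing in `n` and `p`. The
#' reference point anchors the penalty to the largest problem size under
#' study (e.g. the full dataset, or the largest grid cell of a surface run).
#'
#' @inheritParams training_complexity
#' @param reference_n,reference_p Reference problem size; must dominate
#'   `(n, p)` componentwise.
#'
#' @return A number in `[0, 1]`.
#' @export
normalized_regularizer <- function(model, n, p, reference_n, reference_p) {
  if (reference_n < n || reference_p < p) {
    dvm_abort("reference size must dominate the evaluated (n, p) componentwise",
              "dvmetric_error_config")
  }
  log1p(training_complexity(model, n, p)) /
    log1p(training_complexity(model, reference_n, reference_p))
}

fit_model <- function(model, X, y, seed) {
  model$fit(X, y, model$hyperparams, seed)
}

apply_model <- function(model, fitted, X) {
  model$apply(fitted, X)
}
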