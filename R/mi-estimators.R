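#' Mutual information estimate
#'
#' Container returned by the MI estimators. Holds the (clipped, nonnegative)
#' estimate together with the estimator identity, its settings, the sample
#' size used, and the logarithm base, so that values from different
#' estimators are never silently mixed across bases.
#'
#' @param value Nonnegative mutual information value.
#' @param estimator Estimator identifier (`"plugin"`, `"knn"`, `"hash"`).
#' @param params Named list of estimator settings used.
#' @param n_used Number of paired samples the estimate was computed from.
#' @param base Logarithm base, `"nats"` or `"bits"`.
#'
#' @return An object of class `mi_estimate`.
#' @export
mi_estimate <- function(value, estimator, params = list(), n_used = NA_integer_,
                        base = "nats") {
  structure(
    list(value = value, estimator = estimator, params = params,
         n_used = as.integer(n_used), base = base),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("<mi_estimate> %.6g %s (%s estimator, n = %d)\n",
              x$value, x$base, x$estimator, x$n_used))
  invisible(x)
}

#' @export
as.double.mi_estimate <- function(x, ...) x$value

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mi_estimate <- function(x, ...) {
  tibble::tibble(value = x$value, base = x$base, estimator = x$estimator,
                 n_used = x$n_used)
}

log_base_factor <- function(base) {
  base <- match.arg(base, c("nats", "bits"))
  if (base == "bits") 1 / log(2) else 1
}

plugin_mi_from_keys <- function(kx, ky) {
  tab <- table(kx, ky)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  ratio <- p / outer(px, py)
  nz <- p > 0
  max(0, sum(p[nz] * log(ratio[nz])))
}

#' Plug-in mutual information for discrete samples
#'
#' Computes the empirical mutual information
#' \eqn{\sum_{x,y} \hat p(x,y) \log(\hat p(x,y) / (\hat p(x)\hat p(y)))}
#' directly from the joint frequency table of the paired samples. Exact and
#' deterministic; the estimator of choice for categorical data such as class
#' labels or cluster assignments. Multi-column inputs are collapsed to one
#' categorical symbol per row.
#'
#' @param x,y Paired samples: vectors, factors, or data frames / matrices
#'   (one row per sample). Values are treated as categorical symbols.
#' @param base Logarithm base for the result, `"nats"` (default) or `"bits"`.
#'
#' @return An [mi_estimate]. The value is nonnegative and symmetric in
#'   `x` and `y`.
#' @examples
#' x <- c(0, 0, 1, 1)
#' mi_plugin(x, x, base = "bits") # H(fair coin) = 1 bit
#' @export
mi_plugin <- function(x, y, base = "nats") {
  bx <- as_sample_blocks(x, "x")
  by <- as_sample_blocks(y, "y")
  check_paired(bx$n, by$n)
  val <- plugin_mi_from_keys(blocks_key(bx), blocks_key(by)) * log_base_factor(base)
  mi_estimate(val, "plugin", list(), bx$n, base)
}

#' k-nearest-neighbour (KSG) mutual information for continuous samples
#'
#' Kraskov-Stoegbauer-Grassberger estimator (type 1): for each point the
#' Chebyshev distance to its k-th neighbour in the joint space sets a local
#' scale, and neighbour counts within that scale in each marginal enter a
#' digamma formula. Invariant (up to sampling noise) under strictly monotone
#' marginal transforms. Negative raw estimates are clipped to zero.
#'
#' Exact ties between points would make the k-th neighbour ill-defined, so a
#' deterministic, seed-derived jitter of relative magnitude 1e-10 is added to
#' every coordinate before distance computations.
#'
#' @param x,y Paired continuous samples: numeric vectors or matrices.
#' @param k Number of neighbours (default 5); must satisfy `k < n`.
#' @param seed Integer seed for the tie-breaking jitter (default 1).
#' @inheritParams mi_plugin
#'
#' @return An [mi_estimate].
#' @export
mi_knn <- function(x, y, k = 5, seed = 1L, base = "nats") {
  bx <- as_sample_blocks(x, "x")
  by <- as_sample_blocks(y, "y")
  if (!is.null(bx$disc) || !is.null(by$disc)) {
    dvm_abort("mi_knn() requires continuous (numeric) samples",
              "dvmetric_error_input")
  }
  check_paired(bx$n, by$n)
  n <- bx$n
  if (!all(is.finite(bx$cont)) || !all(is.finite(by$cont))) {
    dvm_abort("mi_knn() inputs contain non-finite values", "dvmetric_error_input")
  }
  if (k >= n || k < 1) {
    dvm_abort(sprintf("`k` must satisfy 1 <= k < n (k = %d, n = %d)", k, n),
              "dvmetric_error_parameter")
  }
  jitter_mat <- function(m) {
    scale <- pmax(apply(m, 2, stats::sd), .Machine$double.eps)
    m + matrix(stats::rnorm(length(m)), nrow(m)) * rep(scale * 1e-10, each = nrow(m))
  }
  with_seed(seed, {
    xm <- jitter_mat(bx$cont)
    ym <- jitter_mat(by$cont)
    cnt <- ksg_neighbor_counts(xm, ym, as.integer(k))
    raw <- digamma(k) + digamma(n) -
      mean(digamma(cnt$nx + 1) + digamma(cnt$ny + 1))
    mi_estimate(max(0, raw) * log_base_factor(base), "knn",
                list(k = k, seed = seed), n, base)
  })
}

#' Configuration for the hash-ensemble mutual information estimator
#'
#' The estimator quantizes continuous coordinates at several binning
#' resolutions (after a seeded random projection when the input is
#' high-dimensional), computes a plug-in MI on each quantized table, and
#' combines the per-resolution estimates. Categorical coordinates pass
#' through unchanged, so on fully discrete data the estimator coincides with
#' [mi_plugin] exactly.
#'
#' @param resolutions Strictly increasing integer vector (length >= 2) of
#'   bins per (projected) coordinate. Default `c(8, 16, 32)`.
#' @param projection_dim Continuous blocks with more than this many columns
#'   are first mapped through a seeded Gaussian random projection to this
#'   dimension. Default 5.
#' @param weighting Either `"uniform"` or a numeric vector of combination
#'   weights (one per resolution) summing to 1.
#' @param seed Integer seed controlling the projection (default 1).
#'
#' @return A `hash_config` list.
#' @export
hash_config <- function(resolutions = c(8, 16, 32), projection_dim = 5,
                        weighting = "uniform", seed = 1L) {
  if (length(resolutions) < 2) {
    dvm_abort("`resolutions` must contain at least 2 binning resolutions",
              "dvmetric_error_config")
  }
  if (any(diff(resolutions) <= 0)) {
    dvm_abort("`resolutions` must be strictly increasing", "dvmetric_error_config")
  }
  if (is.numeric(weighting)) {
    if (length(weighting) != length(resolutions) ||
        abs(sum(weighting) - 1) > 1e-8) {
      dvm_abort("numeric `weighting` must have one weight per resolution and sum to 1",
                "dvmetric_error_config")
    }
  } else if (!identical(weighting, "uniform")) {
    dvm_abort("`weighting` must be \"uniform\" or a numeric weight vector",
              "dvmetric_error_config")
  }
  if (projection_dim < 1) {
    dvm_abort("`projection_dim` must be a positive integer", "dvmetric_error_config")
  }
  structure(list(resolutions = as.integer(resolutions),
                 projection_dim = as.integer(projection_dim),
                 weighting = weighting, seed = as.integer(seed)),
            class = "hash_config")
}

# Equal-frequency binning of a numeric vector into at most `b` bins.
quantize_column <- function(v, b) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = b + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) {
    return(rep.int(1L, length(v)))
  }
  findInterval(v, br[-c(1, length(br))]) + 1L
}

# Project (if needed) and quantize the continuous block of a sample at
# resolution b; returns a character key per row combining all coordinates.
hash_keys <- function(blocks, b, projection_dim, proj_seed) {
  parts <- list()
  if (!is.null(blocks$cont)) {
    m <- blocks$cont
    if (ncol(m) > projection_dim) {
      proj <- with_seed(proj_seed, {
        matrix(stats::rnorm(ncol(m) * projection_dim), ncol(m), projection_dim) /
          sqrt(ncol(m))
      })
      m <- m %*% proj
    }
    parts <- c(parts, lapply(seq_len(ncol(m)),
                             function(j) quantize_column(m[, j], b)))
  }
  if (!is.null(blocks$disc)) {
    parts <- c(parts, lapply(seq_len(ncol(blocks$disc)),
                             function(j) blocks$disc[, j]))
  }
  do.call(paste, c(parts, sep = "\r"))
}

#' Hash-ensemble mutual information estimator
#'
#' Near-linear-time MI estimator for mixed or high-dimensional data in the
#' spirit of ensemble hash/binning estimators: continuous coordinates are
#' (optionally randomly projected and) quantized at each configured
#' resolution, plug-in MI is computed on the quantized contingency table,
#' and the per-resolution estimates are combined by the configured weights.
#' Reproducible given the config seed; clipped at zero; identical to
#' [mi_plugin] on fully discrete inputs.
#'
#' @param x,y Paired samples of any kind (numeric, categorical, or mixed;
#'   vectors or data frames / matrices).
#' @param config A [hash_config].
#' @inheritParams mi_plugin
#'
#' @return An [mi_estimate].
#' @export
mi_hash <- function(x, y, config = hash_config(), base = "nats") {
  if (!inherits(config, "hash_config")) {
    config <- do.call(hash_config, config)
  }
  bx <- as_sample_blocks(x, "x")
  by <- as_sample_blocks(y, "y")
  check_paired(bx$n, by$n)
  if ((!is.null(bx$cont) && !all(is.finite(bx$cont))) ||
      (!is.null(by$cont) && !all(is.finite(by$cont)))) {
    dvm_abort("mi_hash() inputs contain non-finite values", "dvmetric_error_input")
  }
  seeds <- c(x = derive_seed(config$seed, 1L), y = derive_seed(config$seed, 2L))
  per_res <- vapply(config$resolutions, function(b) {
    kx <- hash_keys(bx, b, config$projection_dim, seeds[["x"]])
    ky <- hash_keys(by, b, config$projection_dim, seeds[["y"]])
    plugin_mi_from_keys(kx, ky)
  }, numeric(1))
  w <- if (is.numeric(config$weighting)) {
    config$weighting
  } else {
    rep(1 / length(per_res), length(per_res))
  }
  # identical per-resolution values (e.g. fully discrete input, where
  # quantization is the identity) combine without rounding
  combined <- if (diff(range(per_res)) == 0) per_res[1] else sum(w * per_res)
  val <- max(0, combined) * log_base_factor(base)
  mi_estimate(val, "hash",
              list(resolutions = config$resolutions,
                   projection_dim = config$projection_dim,
                   weighting = config$weighting, seed = config$seed,
                   per_resolution = per_res),
              bx$n, base)
}

# Data-driven estimator choice: exact plug-in whenever both sides are
# categorical; KSG for purely continuous pairs of low dimension (where it is
# near-unbiased); the hash ensemble for mixed or high-dimensional pairs.
# The KSG dimension cutoff matches the hash projection target.
resolve_estimator <- function(bx, by, knn_dim_max = 3) {
  all_disc <- is.null(bx$cont) && is.null(by$cont)
  if (all_disc) return("plugin")
  all_cont <- is.null(bx$disc) && is.null(by$disc)
  if (all_cont && ncol(bx$cont) <= knn_dim_max && ncol(by$cont) <= knn_dim_max) {
    return("knn")
  }
  "hash"
}

#' Estimate mutual information with a named estimator
#'
#' Front door used throughout the package: dispatches to [mi_plugin],
#' [mi_knn] or [mi_hash] by identifier. The `"auto"` policy picks the
#' estimator suited to the data type of the pair: exact plug-in when both
#' sides are categorical, KSG when both sides are continuous with at most 3
#' coordinates each (where the neighbour estimator is near-unbiased), and
#' the hash ensemble for mixed or high-dimensional pairs.
#'
#' @inheritParams mi_plugin
#' @param estimator One of `"auto"`, `"plugin"`, `"knn"`, `"hash"`.
#' @param k Neighbour count for the knn estimator.
#' @param config [hash_config] for the hash estimator.
#'
#' @return An [mi_estimate].
#' @export
estimate_mi <- function(x, y, estimator = "auto", k = 5,
                        config = hash_config(), base = "nats") {
  if (identical(estimator, "auto")) {
    estimator <- resolve_estimator(as_sample_blocks(x, "x"),
                                   as_sample_blocks(y, "y"))
  }
  switch(estimator,
    plugin = mi_plugin(x, y, base = base),
    knn = mi_knn(x, y, k = k, base = base),
    hash = mi_hash(x, y, config = config, base = base),
    dvm_abort(sprintf("unknown estimator id \"%s\"", estimator),
              "dvmetric_error_config")
  )
}

#' Conditional mutual information via the chain rule
#'
#' Computes \eqn{I(X; Y \mid Z) = I(X; (Y, Z)) - I(X; Z)} with the named
#' estimator, where \eqn{(Y, Z)} is the per-sample concatenation of the two
#' conditioning blocks. Clipped at zero (the plug-in value is analytically
#' nonnegative; knn/hash differences may dip below zero by estimation noise).
#'
#' With `estimator = "auto"` the choice is resolved once, from the pair
#' `(x, (y, z))`, and used for both chain-rule terms, so the difference is
#' internally consistent.
#'
#' @param x,y,z Paired samples (all of the same length).
#' @inheritParams estimate_mi
#'
#' @return An [mi_estimate] for \eqn{I(X;Y|Z)}.
#' @export
mi_conditional <- function(x, y, z, estimator = "plugin", k = 5,
                           config = hash_config(), base = "nats") {
  bx <- as_sample_blocks(x, "x")
  by <- as_sample_blocks(y, "y")
  bz <- as_sample_blocks(z, "z")
  check_paired(bx$n, by$n)
  check_paired(bx$n, bz$n, c("x", "z"))
  ydf <- as.data.frame(if (is.null(dim(y))) data.frame(..y = y) else y)
  zdf <- as.data.frame(if (is.null(dim(z))) data.frame(..z = z) else z)
  names(ydf) <- paste0("y", seq_along(ydf))
  names(zdf) <- paste0("z", seq_along(zdf))
  yz <- cbind(ydf, zdf)
  if (identical(estimator, "auto")) {
    estimator <- resolve_estimator(bx, as_sample_blocks(yz, "yz"))
  }
  a <- estimate_mi(x, yz, estimator = estimator, k = k, config = config, base = base)
  b <- estimate_mi(x, zdf, estimator = estimator, k = k, config = config, base = base)
  mi_estimate(max(0, a$value - b$value), estimator,
              list(chain_rule = TRUE, k = k), bx$n, base)
}
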