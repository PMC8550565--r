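# Seeded synthetic-data generators for the three benchmark protocols used
# throughout the package's validation experiments. Each returns a tibble of
# numeric features plus a `label` column, with the full generating
# configuration attached as the "config" attribute.

finish_dataset <- function(X, label, config, extra = list()) {
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  out <- tibble::as_tibble(as.data.frame(X))
  out$label <- label
  attr(out, "config") <- config
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Isotropic Gaussian blob classification data
#'
#' Emulates the classic blob benchmark: `centers` cluster centres drawn
#' uniformly in the fixed hypercube \eqn{[-10, 10]^p}, isotropic Gaussian
#' noise of standard deviation `cluster_std` around each, class label = blob
#' id, samples divided as evenly as possible among the blobs and shuffled.
#' With the default geometry, `cluster_std = 20` is the strong-signal
#' setting (a random forest reaches held-out accuracy near 0.95 at
#' `n = 2000, p = 800`) and `cluster_std = 40` the weak-signal one.
#'
#' The centre box is deliberately fixed rather than scaled with
#' `cluster_std`: scaling both centres and noise would make the strong and
#' weak settings affinely equivalent and hence indistinguishable to any
#' classifier.
#'
#' @param n Number of samples (default 2000).
#' @param p Number of features (default 800).
#' @param centers Number of blobs (default 5).
#' @param cluster_std Within-blob standard deviation (default 20).
#' @param center_box Range of the uniform centre draw (default `c(-10, 10)`).
#' @param seed Integer seed; identical seeds give identical tibbles.
#'
#' @return A tibble `n x (p + 1)` with numeric features `F1..Fp` and a
#'   factor `label` with `centers` levels.
#' @export
simulate_blobs <- function(n = 2000, p = 800, centers = 5, cluster_std = 20,
                           center_box = c(-10, 10), seed = 1L) {
  if (n < centers) dvm_abort("`n` must be >= `centers`", "dvmetric_error_config")
  if (cluster_std <= 0) dvm_abort("`cluster_std` must be > 0", "dvmetric_error_config")
  with_seed(seed, {
    ctr <- matrix(stats::runif(centers * p, center_box[1], center_box[2]),
                  centers, p)
    counts <- rep(n %/% centers, centers)
    extra <- n - sum(counts)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    lab <- rep.int(seq_len(centers), counts)
    X <- ctr[lab, , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = cluster_std), n, p)
    ord <- sample.int(n)
    finish_dataset(X[ord, , drop = FALSE],
                   factor(lab[ord], levels = seq_len(centers)),
                   list(generator = "blobs", n = n, p = p, centers = centers,
                        cluster_std = cluster_std, center_box = center_box,
                        seed = seed))
  })
}

signed_cuberoot <- function(u) sign(u) * abs(u)^(1 / 3)

#' Continuous-label (regression) data with cube-root signal
#'
#' Draws rows of `X` from a multivariate Gaussian whose mean-vector entries
#' come from N(0, `mean_prior_var`) and whose diagonal covariance
#' eigenvalues come from Uniform(`eigenvalue_range`), then builds a scalar
#' response \eqn{Y_i = s_i + K \varepsilon_i} with standard-normal noise
#' \eqn{\varepsilon} and a signed cube-root signal \eqn{s_i}. The noise
#' magnitude `K = 10` is the strong-signal setting, `K = 50` the weak one.
#'
#' The reduction of the feature row to a scalar signal is configurable via
#' `aggregate`:
#' \describe{
#'   \item{`"sum_cuberoot"` (default)}{\eqn{s_i = \sum_j \mathrm{sign}(X_{ij}) |X_{ij}|^{1/3}};
#'     the per-sample signal standard deviation grows like \eqn{\sqrt p}, so
#'     it remains detectable against the noise at both K settings.}
#'   \item{`"cuberoot_mean"`}{\eqn{s_i = \mathrm{sign}(\bar X_i)|\bar X_i|^{1/3}}
#'     (cube root of the row mean). Note that the row-mean variance decays
#'     like \eqn{1/p}, so at large `p` this variant carries almost no signal
#'     relative to the noise; it is provided for completeness.}
#' }
#'
#' @param n Number of samples.
#' @param p Number of features (default 800).
#' @param K Noise magnitude: 10 (strong) or 50 (weak).
#' @param mean_prior_var Variance of the Gaussian prior on the mean vector
#'   entries (default 25).
#' @param eigenvalue_range Range of the uniform draw of the diagonal
#'   covariance eigenvalues (default `c(2, 12)`).
#' @param aggregate Signal reduction rule, see Details.
#' @param seed Integer seed.
#'
#' @return A tibble with numeric features and a continuous `label` column;
#'   the noiseless signal is attached as attribute `"signal"`.
#' @export
simulate_cuberoot <- function(n, p = 800, K = 10, mean_prior_var = 25,
                              eigenvalue_range = c(2, 12),
                              aggregate = c("sum_cuberoot", "cuberoot_mean"),
                              seed = 1L) {
  aggregate <- match.arg(aggregate)
  if (K <= 0) dvm_abort("`K` must be > 0", "dvmetric_error_config")
  if (length(eigenvalue_range) != 2 || any(eigenvalue_range <= 0) ||
      diff(eigenvalue_range) < 0) {
    dvm_abort("`eigenvalue_range` must be positive and ordered",
              "dvmetric_error_config")
  }
  with_seed(seed, {
    mu <- stats::rnorm(p, 0, sqrt(mean_prior_var))
    ev <- stats::runif(p, eigenvalue_range[1], eigenvalue_range[2])
    X <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(ev), p) +
      matrix(mu, n, p, byrow = TRUE)
    signal <- switch(aggregate,
      sum_cuberoot = rowSums(signed_cuberoot(X)),
      cuberoot_mean = signed_cuberoot(rowMeans(X))
    )
    y <- signal + K * stats::rnorm(n)
    finish_dataset(X, y,
                   list(generator = "cuberoot", n = n, p = p, K = K,
                        mean_prior_var = mean_prior_var,
                        eigenvalue_range = eigenvalue_range,
                        aggregate = aggregate, seed = seed),
                   extra = list(signal = signal))
  })
}

#' Four-cluster square benchmark for feature selection
#'
#' `n_clusters` Gaussian clusters whose means sit at the corners of a square
#' of edge `square_edge` in exactly two informative coordinates; the
#' remaining `d - 2` coordinates are independent standard-normal noise. The
#' two informative coordinates are placed at seeded random positions among
#' the `d` feature columns (recorded in the `"informative"` attribute), so a
#' feature-selection routine has to find them.
#'
#' @param n Number of samples (default 1000); divided as evenly as possible
#'   among the clusters (first clusters absorb the remainder).
#' @param d Total feature dimension (default 20, must be >= 2).
#' @param n_clusters Number of clusters (default 4; at most the number of
#'   square corners).
#' @param square_edge Edge length of the square (default 1).
#' @param cluster_std Within-cluster standard deviation in the informative
#'   coordinates (default 0.2: separable but noisy).
#' @param seed Integer seed.
#'
#' @return A tibble with numeric features `F1..Fd` and a factor `label`;
#'   attribute `"informative"` gives the names of the two informative
#'   columns.
#' @export
simulate_cluster_square <- function(n = 1000, d = 20, n_clusters = 4,
                                    square_edge = 1, cluster_std = 0.2,
                                    seed = 1L) {
  if (d < 2) dvm_abort("`d` must be >= 2", "dvmetric_error_config")
  if (n_clusters < 2 || n_clusters > 4) {
    dvm_abort("`n_clusters` must be between 2 and 4 (square corners)",
              "dvmetric_error_config")
  }
  with_seed(seed, {
    corners <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE) *
      square_edge
    corners <- corners[seq_len(n_clusters), , drop = FALSE]
    counts <- rep(n %/% n_clusters, n_clusters)
    extra <- n - sum(counts)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    lab <- rep.int(seq_len(n_clusters), counts)
    info <- corners[lab, , drop = FALSE] +
      matrix(stats::rnorm(n * 2, sd = cluster_std), n, 2)
    X <- matrix(stats::rnorm(n * d), n, d)
    pos <- sort(sample.int(d, 2))
    X[, pos] <- info
    ord <- sample.int(n)
    out <- finish_dataset(X[ord, , drop = FALSE],
                          factor(lab[ord], levels = seq_len(n_clusters)),
                          list(generator = "cluster_square", n = n, d = d,
                               n_clusters = n_clusters,
                               square_edge = square_edge,
                               cluster_std = cluster_std, seed = seed),
                          extra = list(informative = paste0("F", pos)))
    out
  })
}
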