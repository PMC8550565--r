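# Independent oracles and small fixture builders used across the suite.

# Brute-force empirical mutual information: direct double loop over the
# observed support. Deliberately independent of the package's contingency
# table implementation.
mi_bruteforce <- function(x, y, base = exp(1)) {
  x <- as.character(x)
  y <- as.character(y)
  s <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- mean(x == a & y == b)
      if (pxy > 0) {
        s <- s + pxy * log(pxy / (mean(x == a) * mean(y == b)), base = base)
      }
    }
  }
  s
}

# A paired discrete sample from a random joint pmf over sx-by-sy states.
random_discrete_pair <- function(n, sx, sy, seed) {
  set.seed(seed)
  pmf <- matrix(rgamma(sx * sy, 1), sx, sy)
  pmf <- pmf / sum(pmf)
  cells <- sample(sx * sy, n, replace = TRUE, prob = as.vector(pmf))
  list(x = (cells - 1) %% sx, y = (cells - 1) %/% sx)
}

# A bivariate Gaussian pair with the given correlation.
gaussian_pair <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  list(x = x, y = rho * x + sqrt(1 - rho^2) * rnorm(n))
}

# Small perfectly learnable classification dataset: one discrete feature,
# label = that feature. Balanced so stratified splits conserve entropy.
perfect_task <- function(n_per_level = 10, levels = 4) {
  x <- rep(seq_len(levels), each = n_per_level)
  tibble::tibble(F1 = as.numeric(x), label = factor(letters[x]))
}

# Four well-separated Gaussian masses in two dimensions (no label column).
separated_masses <- function(n_per = 60, sd = 0.3, seed = 1) {
  set.seed(seed)
  ctr <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, 2, byrow = TRUE)
  lab <- rep(1:4, each = n_per)
  X <- ctr[lab, ] + matrix(rnorm(2 * length(lab), sd = sd), length(lab), 2)
  tibble::tibble(F1 = X[, 1], F2 = X[, 2])
}

# Deterministic custom model: predicts a fixed function of the first
# feature; used to pin fidelity values against the plug-in oracle.
threshold_model <- function() {
  dvm_model_custom(
    fit = function(X, y, hp, seed) NULL,
    apply = function(fitted, X) factor(ifelse(X[, 1] > 0, "hi", "lo")),
    mode = "supervised",
    training_cost = function(n, p, hp) n * p,
    id = "threshold"
  )
}

constant_model <- function() {
  dvm_model_custom(
    fit = function(X, y, hp, seed) NULL,
    apply = function(fitted, X) factor(rep("c", nrow(X))),
    mode = "supervised",
    training_cost = function(n, p, hp) n * p,
    id = "constant"
  )
}
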