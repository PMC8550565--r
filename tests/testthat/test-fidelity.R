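# Supervised / unsupervised fidelity, information-bottleneck identities,
# and the DVM algebra.

test_that("a perfectly learned deterministic task has fidelity exactly 1", {
  d <- perfect_task(n_per_level = 10, levels = 4)
  tree <- dvm_model("decision_tree", minsplit = 2, cp = 0)
  for (beta in c(0, 0.5)) {
    f <- fidelity_supervised(d, tree,
                             cfg = fidelity_config(beta = beta, n_splits = 4,
                                                   seed = 3))
    expect_equal(f$per_split_fidelities, rep(1, 4), tolerance = 1e-12)
  }
})

test_that("a constant-prediction model has fidelity exactly 0", {
  d <- perfect_task(n_per_level = 12, levels = 3)
  f <- fidelity_supervised(d, constant_model(),
                           cfg = fidelity_config(n_splits = 3, seed = 2))
  expect_equal(f$per_split_fidelities, rep(0, 3), tolerance = 1e-12)
})

test_that("beta = 0 fidelity equals the plug-in oracle recomputation over splits", {
  set.seed(9)
  n <- 120
  f1 <- sample(c(-1, 1), n, replace = TRUE)
  f2 <- sample(0:2, n, replace = TRUE)
  y <- factor(ifelse(stats::runif(n) < 0.85, f1 > 0, f1 <= 0))
  d <- tibble::tibble(F1 = f1, F2 = as.numeric(f2), label = y)
  cfg <- fidelity_config(beta = 0, n_splits = 5, estimator = "plugin", seed = 17)
  got <- fidelity_supervised(d, threshold_model(), cfg = cfg)

  # independent recomputation: same splits, brute-force MI sums
  splits <- dvm_splits(n, cfg, labels = y, mode = "supervised")
  denom <- mi_bruteforce(paste(f1, f2), y)
  expected <- vapply(splits, function(sp) {
    t_hat <- ifelse(f1[sp$test] > 0, "hi", "lo")
    mi_bruteforce(t_hat, y[sp$test]) / denom
  }, numeric(1))
  expect_equal(got$per_split_fidelities, expected, tolerance = 1e-12)
  expect_equal(got$fidelity, mean(expected), tolerance = 1e-12)
})

test_that("fidelity is bounded by 1 for deterministic representations (exact plug-in)", {
  worst <- -Inf
  for (seed in 1:30) {
    pr <- random_discrete_pair(180, sample(2:6, 1), sample(2:6, 1), seed + 90)
    set.seed(seed)
    g <- sample(seq_len(max(pr$x) + 1), max(pr$x) + 1, replace = TRUE)
    t <- g[pr$x + 1]
    for (beta in c(0, 0.1, 1)) {
      val <- tryCatch(
        ib_fidelity(pr$x, t, pr$y, beta = beta, estimator = "plugin"),
        dvmetric_error_degenerate_signal = function(e) NA_real_
      )
      if (!is.na(val)) worst <- max(worst, val)
    }
  }
  expect_lte(worst, 1 + 1e-9)

  # equality: Y an invertible function of T = X
  x <- rep(0:3, each = 8)
  y <- factor(letters[(x + 2) %% 4 + 1])
  for (beta in c(0, 0.1, 1)) {
    expect_equal(ib_fidelity(x, x, y, beta = beta, estimator = "plugin"), 1,
                 tolerance = 1e-12)
  }
})

test_that("the conditional form equals the standard bottleneck form for deterministic T", {
  for (seed in 1:10) {
    pr <- random_discrete_pair(150, sample(3:6, 1), sample(2:5, 1), seed + 40)
    set.seed(seed)
    g <- sample(3, max(pr$x) + 1, replace = TRUE)
    t <- g[pr$x + 1]
    ity <- mi_plugin(t, pr$y)$value
    itx <- mi_plugin(t, pr$x)$value
    for (beta in c(0, 0.1, 1)) {
      conditional_form <- ity - beta * mi_conditional(pr$x, t, pr$y)$value
      bottleneck_form <- (1 + beta) * ity - beta * itx
      expect_equal(conditional_form, bottleneck_form, tolerance = 1e-10)
    }
  }
})

test_that("ib_score reduces to I(T;Y) at beta 0 and matches the oracle", {
  set.seed(21)
  x <- sample(0:3, 200, replace = TRUE)
  t <- x %% 2
  y <- factor((x + rbinom(200, 1, 0.2)) %% 4)
  expect_equal(ib_score(x, t, y, beta = 0), mi_plugin(t, y)$value)
  expect_equal(ib_score(x, t, y, beta = 0.3),
               mi_bruteforce(t, y) - 0.3 * mi_bruteforce(x, t),
               tolerance = 1e-12)
  t_ind <- sample(0:1, 200, replace = TRUE)
  expect_lt(abs(ib_score(x, t_ind, y, beta = 0.1)), 0.05)
})

test_that("DVM result satisfies its algebraic identities and is seed-deterministic", {
  d <- simulate_cluster_square(n = 200, d = 5, seed = 4)
  tree <- dvm_model("decision_tree")
  cfg <- fidelity_config(n_splits = 5, seed = 6)
  r <- compute_dvm(d, tree, lambda = 0.37, cfg = cfg)
  expect_identical(r$dvm, r$fidelity - 0.37 * r$regularizer)
  expect_identical(r$fidelity, mean(r$per_split_fidelities))
  expect_lte(r$ci95[["low"]], r$fidelity)
  expect_gte(r$ci95[["high"]], r$fidelity)
  expect_identical(compute_dvm(d, tree, lambda = 0, cfg = cfg)$dvm,
                   compute_dvm(d, tree, lambda = 0, cfg = cfg)$fidelity)

  r2 <- compute_dvm(d, tree, lambda = 0.37, cfg = cfg)
  expect_identical(r, r2) # bit-for-bit under identical config + seed
  r3 <- compute_dvm(d, tree, lambda = 0.37, cfg = fidelity_config(n_splits = 5,
                                                                  seed = 7))
  expect_false(identical(r$per_split_fidelities, r3$per_split_fidelities))

  # broom-style accessors
  expect_identical(nrow(tidy(r)), 5L)
  expect_identical(nrow(glance(r)), 1L)
})

test_that("degenerate inputs fail loudly with classed errors", {
  d <- perfect_task()
  d$label <- factor(rep("only", nrow(d)))
  expect_error(fidelity_supervised(d, dvm_model("decision_tree")),
               class = "dvmetric_error_degenerate_label")

  # independent discrete data: full-data I(X;Y) sits below the floor
  set.seed(123)
  dn <- tibble::tibble(F1 = sample(0:1, 5000, replace = TRUE),
                       label = factor(sample(0:1, 5000, replace = TRUE)))
  expect_error(
    fidelity_supervised(dn, dvm_model("decision_tree"),
                        cfg = fidelity_config(estimator = "plugin", seed = 1)),
    class = "dvmetric_error_degenerate_signal")

  expect_error(fidelity_supervised(perfect_task(), dvm_model("k_means")),
               class = "dvmetric_error_config")
  expect_error(fidelity_config(n_splits = 1), class = "dvmetric_error_config")
  expect_error(fidelity_config(estimator = "edge"),
               class = "dvmetric_error_config")
})

test_that("stable clustering of well-separated masses yields near-maximal fidelity", {
  d <- separated_masses(n_per = 100, seed = 5)
  km <- dvm_model("k_means", k = 4)
  r <- fidelity_unsupervised(d, km, cfg = fidelity_config(seed = 2))
  expect_gt(r$fidelity, 0.9)
  # pure isotropic noise clusters much less stably
  set.seed(6)
  dn <- tibble::tibble(F1 = rnorm(400), F2 = rnorm(400), F3 = rnorm(400))
  rn <- fidelity_unsupervised(dn, km, cfg = fidelity_config(seed = 2))
  expect_lt(rn$fidelity, 0.6)
  expect_lt(rn$fidelity, r$fidelity)
})

test_that("single-cluster output raises a degenerate-clustering error", {
  one_cluster <- dvm_model_custom(
    fit = function(X, y, hp, seed) NULL,
    apply = function(fitted, X) factor(rep(1, nrow(X))),
    mode = "unsupervised",
    training_cost = function(n, p, hp) n * p,
    id = "one_cluster"
  )
  d <- separated_masses(n_per = 30)
  expect_error(fidelity_unsupervised(d, one_cluster),
               class = "dvmetric_error_degenerate_clustering")
})
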