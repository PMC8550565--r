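# Experiment runner: accuracy companion, surfaces, file I/O, CLI.

test_that("held-out accuracy: separable data scores 1, shuffled labels score chance", {
  d <- perfect_task(n_per_level = 12, levels = 3)
  acc <- evaluate_accuracy(d, dvm_model("decision_tree", minsplit = 2, cp = 0),
                           cfg = fidelity_config(n_splits = 3, seed = 1))
  expect_identical(acc$accuracy, 1)

  set.seed(15)
  n <- 400
  dn <- tibble::tibble(F1 = rnorm(n), F2 = rnorm(n),
                       label = factor(sample(0:1, n, replace = TRUE)))
  acc0 <- evaluate_accuracy(dn, dvm_model("decision_tree"),
                            cfg = fidelity_config(n_splits = 5, seed = 2))
  expect_lt(abs(acc0$accuracy - 0.5), 0.1)

  expect_error(evaluate_accuracy(separated_masses(), dvm_model("k_means")),
               class = "dvmetric_error_unsupported_metric")
})

test_that("accuracy and fidelity are computed on identical splits", {
  d <- simulate_cluster_square(n = 200, d = 5, seed = 3)
  cfg <- fidelity_config(n_splits = 4, seed = 11)
  r <- compute_dvm(d, dvm_model("decision_tree"), cfg = cfg)
  a <- evaluate_accuracy(d, dvm_model("decision_tree"), cfg = cfg)
  expect_identical(lapply(r$splits, `[[`, "test"),
                   lapply(a$splits, `[[`, "test"))
  expect_identical(r$per_split_accuracy, a$per_split)
})

test_that("a full-size 1x1 grid reproduces a direct DVM call", {
  d <- simulate_cluster_square(n = 150, d = 5, seed = 4)
  s <- dvm_surface(d, dvm_model("decision_tree"), n_values = 150, p_values = 5,
                   replicates = 1, cfg = fidelity_config(n_splits = 3),
                   seed = 21)
  cell <- s$replicates
  cfg_cell <- fidelity_config(n_splits = 3)
  cfg_cell$seed <- cell$seed[1]
  direct <- compute_dvm(d, dvm_model("decision_tree"), cfg = cfg_cell,
                        reference = c(150, 5))
  expect_identical(cell$dvm[1], direct$dvm)
  expect_identical(cell$fidelity[1], direct$fidelity)
})

test_that("surface runs are bit-reproducible and respect data bounds", {
  d <- simulate_cluster_square(n = 220, d = 6, seed = 5)
  args <- list(d, dvm_model("decision_tree"), n_values = c(120, 220),
               p_values = c(3, 6), replicates = 2,
               cfg = fidelity_config(n_splits = 3), seed = 33)
  s1 <- do.call(dvm_surface, args)
  s2 <- do.call(dvm_surface, args)
  expect_identical(s1, s2)
  expect_identical(nrow(s1$replicates), 2L * 4L) # cells x replicates
  expect_true(all(s1$cells$dvm_ci_low <= s1$cells$dvm_mean + 1e-12))
  expect_true(all(s1$cells$dvm_mean <= s1$cells$dvm_ci_high + 1e-12))
  expect_error(dvm_surface(d, dvm_model("decision_tree"), n_values = 500,
                           p_values = 3),
               class = "dvmetric_error_bounds")
})

test_that("failing cells are recorded and do not abort the sweep", {
  d <- separated_masses(n_per = 40, seed = 6)
  s <- dvm_surface(d, dvm_model("k_means", k = 8), label = NULL,
                   n_values = c(12, 160), p_values = 2, replicates = 1,
                   cfg = fidelity_config(n_splits = 2), seed = 2)
  expect_identical(nrow(s$replicates), 2L)
  expect_true(any(!is.na(s$replicates$error)))
  expect_true(any(is.na(s$replicates$error)))
})

test_that("on a null dataset the fidelity stays indistinguishable from zero", {
  # labels independent of features; the label-information term alone
  fids <- vapply(1:6, function(i) {
    set.seed(i)
    dd <- tibble::tibble(F1 = rnorm(400), F2 = rnorm(400),
                         label = factor(sample(c("a", "b"), 400, TRUE)))
    compute_dvm(dd, dvm_model("decision_tree"), lambda = 0,
                cfg = fidelity_config(beta = 0, seed = i))$fidelity
  }, numeric(1))
  expect_lt(mean(fids), 0.05)
  expect_true(all(abs(fids) < 0.1))
})

test_that("CSV round trip is lossless and parse errors carry context", {
  d <- simulate_blobs(n = 60, p = 5, centers = 3, cluster_std = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_labeled_csv(d, path)
  expect_true(file.exists(paste0(path, ".json"))) # config sidecar
  back <- read_labeled_csv(path)
  expect_equal(as.matrix(back[paste0("F", 1:5)]),
               as.matrix(d[paste0("F", 1:5)]), tolerance = 1e-12)
  expect_identical(as.character(back$label), as.character(d$label))

  expect_error(read_labeled_csv(path, label = "outcome"),
               class = "dvmetric_error_parse")

  bad <- d
  bad$F2[3] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  err <- tryCatch(read_labeled_csv(path2), error = function(e) e)
  expect_s3_class(err, "dvmetric_error_parse")
  expect_match(conditionMessage(err), "row 3")
  expect_match(conditionMessage(err), "F2")
})

test_that("result writers emit the promised JSON and tidy CSV shapes", {
  d <- simulate_cluster_square(n = 150, d = 5, seed = 9)
  tree <- dvm_model("decision_tree")
  cfg <- fidelity_config(n_splits = 3, seed = 1)

  r <- compute_dvm(d, tree, cfg = cfg)
  prefix <- file.path(withr::local_tempdir(), "res")
  write_results(r, prefix)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_true(all(c("fidelity", "per_split_fidelities", "ci95", "regularizer",
                    "lambda", "dvm", "config", "seed") %in% names(js)))
  expect_equal(js$dvm, r$dvm, tolerance = 1e-12)

  s <- dvm_surface(d, tree, n_values = c(80, 150), p_values = c(3, 5),
                   replicates = 2, cfg = cfg, seed = 3)
  prefix2 <- file.path(withr::local_tempdir(), "surf")
  write_results(s, prefix2)
  tidycsv <- readr::read_csv(paste0(prefix2, ".csv"), show_col_types = FALSE)
  expect_identical(nrow(tidycsv), 4L * 2L) # one row per cell and replicate

  tr <- select_features(d, tree, r = 2, cfg = cfg)
  prefix3 <- file.path(withr::local_tempdir(), "sel")
  write_results(tr, prefix3)
  selcsv <- readr::read_csv(paste0(prefix3, ".csv"), show_col_types = FALSE)
  expect_identical(names(selcsv), c("step_feature", "dvm"))
  expect_identical(nrow(selcsv), 2L)
})

test_that("the CLI validates configs and drives simulate / dvm runs", {
  tmp <- withr::local_tempdir()
  cfg_path <- file.path(tmp, "run.yml")
  yaml::write_yaml(list(
    data = list(generator = "cluster_square",
                params = list(n = 120, d = 4)),
    model = list(id = "decision_tree"),
    fidelity = list(n_splits = 3),
    lambda = 0.01
  ), cfg_path)

  expect_identical(dvm_cli(c("simulate", "--config", cfg_path,
                             "--output-dir", tmp, "--seed", "4",
                             "--log-level", "quiet")), 0L)
  expect_true(file.exists(file.path(tmp, "dataset.csv")))
  expect_true(file.exists(file.path(tmp, "dataset.csv.json")))

  out <- utils::capture.output(
    dvm_cli(c("dvm", "--config", cfg_path, "--output-dir", tmp,
              "--seed", "4", "--log-level", "quiet")))
  expect_true(file.exists(file.path(tmp, "dvm_result.json")))
  expect_match(paste(out, collapse = "\n"), "DVM")

  expect_error(dvm_cli(c("dvm", "--config", cfg_path, "--seed")),
               class = "dvmetric_error_config")
  expect_error(validate_run_config(list(model = list(id = "decision_tree")),
                                   "dvm"),
               class = "dvmetric_error_config")
  expect_error(validate_run_config(list(data = list(csv = "x.csv"),
                                        model = list()), "dvm"),
               class = "dvmetric_error_config")
  expect_error(validate_run_config(list(bogus = 1), "simulate"),
               class = "dvmetric_error_config")
})

test_that("autoplot methods return ggplot objects for every result type", {
  d <- simulate_cluster_square(n = 150, d = 5, seed = 30)
  tree <- dvm_model("decision_tree")
  cfg <- fidelity_config(n_splits = 3, seed = 1)
  r <- compute_dvm(d, tree, cfg = cfg)
  expect_s3_class(autoplot(r), "ggplot")
  tr <- select_features(d, tree, r = 2, cfg = cfg)
  expect_s3_class(autoplot(tr), "ggplot")
  s <- dvm_surface(d, tree, n_values = c(80, 150), p_values = 5,
                   replicates = 2, cfg = cfg, seed = 2)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(autoplot(s, metric = "accuracy"), "ggplot")
})
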