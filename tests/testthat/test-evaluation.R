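test_that("a near-identity kernel separates a two-point toy problem", {
  K <- matrix(c(1, 0.1, 0.1, 1), 2, 2)
  model <- svm_fit_precomputed(K, c("a", "b"))
  expect_identical(svm_predict(model, K), c("a", "b"))
})

test_that("fit and prediction are invariant under simultaneous permutation", {
  set.seed(1)
  tab <- make_clean_table(60, seed = 2)
  Z <- apply_rescaler(fit_rescaler(feature_matrix(tab), "quantile_uniform"),
                      feature_matrix(tab))[, 1:5]
  y <- tab$label
  V <- classical_gram(Z, spec = classical_kernel_spec("rbf"))$values
  model <- svm_fit_precomputed(V, y)
  pred <- svm_predict(model, V)

  perm <- sample(60)
  model_p <- svm_fit_precomputed(V[perm, perm], y[perm])
  pred_p <- svm_predict(model_p, V[perm, perm, drop = FALSE])
  expect_equal(mean(pred_p == y[perm]), mean(pred == y))
})

test_that("a block-perfect 14-class kernel trains and tests without error", {
  set.seed(2)
  y <- sample(qkmorph:::class_names(14), 140, replace = TRUE)
  while (length(unique(y)) < 14) y <- sample(qkmorph:::class_names(14),
                                             140, replace = TRUE)
  K <- block_kernel(y) + diag(1e-6, 140)
  model <- svm_fit_precomputed(K, y)
  expect_identical(svm_predict(model, K), y)        # zero training errors

  # block-structured test rows hit the right class
  test_rows <- block_kernel(y)[c(3, 50, 100), , drop = FALSE]
  expect_identical(svm_predict(model, test_rows), y[c(3, 50, 100)])
})

test_that("all-zero kernel rows fall back to the lowest class index", {
  y <- rep(c("a", "b", "c"), each = 4)
  K <- block_kernel(y) + diag(1e-6, 12)
  model <- svm_fit_precomputed(K, y)
  pred <- svm_predict(model, matrix(0, 2, 12))
  expect_identical(pred, c("a", "a"))
})

test_that("shape and class-count validation errors fire", {
  expect_error(svm_fit_precomputed(matrix(1, 2, 3), c("a", "b")), "square")
  expect_error(svm_fit_precomputed(diag(3), rep("a", 3)), "two classes")
  model <- svm_fit_precomputed(diag(4) + 0.1, c("a", "a", "b", "b"))
  expect_error(svm_predict(model, matrix(0, 1, 3)), "align")
})

test_that("holdout split is stratified, exhaustive and seeded", {
  tab <- make_clean_table(100, seed = 5)
  sp <- holdout_split(tab, 0.8, seed = 1)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_equal(length(sp$train), 100 - length(sp$test))
  expect_true(abs(length(sp$train) - 80) <= 14)  # stratification rounding
  # per-class fractions near 0.8
  for (cl in unique(tab$label)) {
    idx <- which(tab$label == cl)
    frac <- mean(idx %in% sp$train)
    expect_true(frac > 0.5 && frac < 1)
  }
  expect_identical(holdout_split(tab, 0.8, seed = 1), sp)
  expect_false(identical(holdout_split(tab, 0.8, seed = 2), sp))

  expect_warning(holdout_split(c("a", "a", "b"), 0.8, 1), "< 2 members")
  expect_error(holdout_split(tab, 1.2), "train_fraction")
})

test_that("cross-validation reports reconcile and nail the block-perfect case", {
  set.seed(3)
  y <- rep(qkmorph:::class_names(4), each = 10)
  K <- block_kernel(y) + diag(1e-6, 40)
  cv <- crossval_precomputed(K, y, k = 5, seed = 1)
  expect_length(cv$fold_scores, 5)
  expect_equal(cv$mean, mean(cv$fold_scores))
  expect_equal(cv$ci95, 1.96 * cv$sd / sqrt(5))
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)

  expect_error(crossval_precomputed(K, y, k = 11, seed = 1), "smallest class")
})

test_that("the benchmark grid runs cells, records errors, and is deterministic", {
  tab <- make_clean_table(120, seed = 4, n_classes = 5)
  cfg <- benchmark_config(
    rescalers = c("quantile_uniform", "maxabs"),
    reducers = list(
      list(mode = "selection", method = "decision_tree", k = 3),
      list(mode = "extraction", method = "ica", n_components = 2)
    ),
    algorithms = c("SVM_rbf", "q_kernel_zz"),
    cv_folds = 3, seed = 1
  )
  rows <- run_benchmark(tab, cfg)
  expect_equal(nrow(rows), 2 * 2 * 2)
  ok <- rows[rows$status != "error", ]
  err <- rows[rows$status == "error", ]
  expect_equal(unique(err$feature_reduction), "ica")
  expect_match(err$message[1], "no installed backend")
  expect_true(all(ok$cv_mean >= 0 & ok$cv_mean <= 1))
  expect_true(all(ok$holdout_accuracy >= 0 & ok$holdout_accuracy <= 1))

  rows2 <- run_benchmark(tab, cfg)
  expect_identical(rows, rows2)
})

test_that("a one-cell grid returns exactly one row", {
  tab <- make_clean_table(80, seed = 6, n_classes = 4)
  cfg <- benchmark_config(
    rescalers = "minmax",
    reducers = list(list(mode = "selection", method = "decision_tree",
                         k = 2)),
    algorithms = "SVM_linear", cv_folds = 3, seed = 1
  )
  rows <- run_benchmark(tab, cfg)
  expect_equal(nrow(rows), 1)
  expect_equal(rows$status, "ok")
})

test_that("default grids enumerate the documented cardinalities", {
  ext <- benchmark_config(reducers = default_reducers("extraction"))
  expect_equal(length(ext$rescalers) * length(ext$reducers), 11 * 14)
  sel <- benchmark_config(reducers = default_reducers("selection"))
  expect_equal(length(sel$reducers), 3)
  expect_error(benchmark_config(reducers = list()), "reducers")
})

test_that("top_n_rows sorts by mean, then std, then cell name", {
  rows <- data.frame(
    rescaling = c("a", "b", "c", "d"),
    feature_reduction = "r", algorithm = "x",
    cv_mean = c(0.93, 0.91, 0.91, NA),
    cv_std = c(0.01, 0.002, 0.001, NA),
    cv_ci95 = NA, holdout_accuracy = NA,
    status = c("ok", "ok", "ok", "error"), message = "",
    stringsAsFactors = FALSE
  )
  top <- top_n_rows(rows, 2)
  expect_equal(top$rescaling, c("a", "c"))   # 0.93 first, tie by lower std
  expect_equal(nrow(top_n_rows(rows, 10)), 3)  # error rows excluded
})

test_that("cv accuracy does not degrade with synthetic sample size", {
  sizes <- c(100, 250, 500)
  stats <- vapply(sizes, function(n) {
    spec <- synthetic_spec(n_neurons = n, n_classes = 7, seed = 1)
    tab <- generate_dataset(spec)
    X <- feature_matrix(tab)
    Z <- apply_rescaler(fit_rescaler(X, "quantile_uniform"), X)
    sel <- select_top_k(tree_importances(Z, tab$label, "decision_tree",
                                         seed = 1), 5)
    cv <- crossval_precomputed(
      kernel_matrix(Z[, sel], feature_map_spec(5, encoding = "zz")),
      tab$label, k = 5, seed = 1)
    c(cv$mean, cv$sd)
  }, numeric(2))
  means <- stats[1, ]; sds <- stats[2, ]
  # non-decreasing within one fold standard deviation
  expect_true(all(diff(means) > -pmax(sds[-length(sds)], sds[-1])))
})
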