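#' One-vs-one SVM on a precomputed kernel
#'
#' Fits the all-pair multiclass SVM: one soft-margin binary SVM per class
#' pair on the corresponding sub-Gram (quadratic programs delegated to
#' \pkg{kernlab}), with prediction by majority vote over pairs and ties
#' broken by the lowest class index.
#'
#' @param K Square `kernel_matrix` or numeric Gram of the training rows
#'   (PSD-repaired where appropriate).
#' @param y Training labels (>= 2 classes; any atomic vector).
#' @param C Soft-margin regularization (default 1).
#' @return A `precomputed_svm` model holding the per-pair kernlab fits,
#'   class levels, and sub-Gram bookkeeping.
#' @export
svm_fit_precomputed <- function(K, y, C = 1) {
  V <- kernel_values(K)
  if (nrow(V) != ncol(V)) stop("training Gram must be square", call. = FALSE)
  y <- as.character(y)
  if (length(y) != nrow(V)) stop("length(y) != nrow(K)", call. = FALSE)
  classes <- sort(unique(y), method = "radix")
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- which(y %in% pr)
    yf <- factor(y[sel], levels = pr)
    fit <- fit_binary_ksvm(V[sel, sel, drop = FALSE], yf, C)
    list(rows = sel, levels = pr, fit = fit)
  })
  structure(
    list(fits = fits, classes = classes, y = y, C = C, n_train = nrow(V)),
    class = "precomputed_svm"
  )
}

#' @export
print.precomputed_svm <- function(x, ...) {
  cat(sprintf("One-vs-one precomputed-kernel SVM: %d classes, %d pairs, C = %g\n",
              length(x$classes), length(x$fits), x$C))
  invisible(x)
}

#' Predict from a precomputed-kernel SVM
#'
#' @param model A `precomputed_svm`.
#' @param K_test_train Rectangular kernel block: rows = test points,
#'   columns aligned with the training rows the model was fit on.
#' @return Character vector of predicted class labels.
#' @export
svm_predict <- function(model, K_test_train) {
  stopifnot(inherits(model, "precomputed_svm"))
  B <- kernel_values(K_test_train)
  if (ncol(B) != model$n_train) {
    stop("K_test_train columns must align with the training rows",
         call. = FALSE)
  }
  votes <- matrix(0L, nrow(B), length(model$classes),
                  dimnames = list(NULL, model$classes))
  for (pf in model$fits) {
    sub <- B[, pf$rows, drop = FALSE]
    sv <- pf$fit$sv_index
    pred <- kernlab::predict(pf$fit$model,
                             kernlab::as.kernelMatrix(sub[, sv, drop = FALSE]))
    pred <- as.character(pred)
    for (lv in pf$levels) {
      votes[, lv] <- votes[, lv] + (pred == lv)
    }
  }
  # ties resolved toward the lowest class index (classes are sorted)
  model$classes[apply(votes, 1, which.max)]
}

#' Stratified holdout split
#'
#' Random stratified-by-class split into train and test index sets. A class
#' with fewer than 2 members stays in training with a warning.
#'
#' @param labels Class label vector (or a `morphometry_table`, whose
#'   `label` column is used).
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Seed.
#' @return A list: `train`, `test` (disjoint, exhaustive integer indices).
#' @export
holdout_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- integer(0)
  for (cl in sort(unique(labels), method = "radix")) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      warning(sprintf("class '%s' has < 2 members; kept entirely in train",
                      cl))
      train <- c(train, idx)
      next
    }
    n_tr <- max(1L, round(train_fraction * length(idx)))
    if (n_tr == length(idx)) n_tr <- length(idx) - 1L
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation on a precomputed kernel
#'
#' Splits the rows into `k` stratified folds; for each fold, fits the
#' one-vs-one SVM on the in-fold sub-Gram and scores accuracy on the
#' held-out block. Reports the fold scores, their mean and standard
#' deviation, and the 95% confidence-interval half-width
#' `1.96 * sd / sqrt(k)`.
#'
#' @param K Square `kernel_matrix` or Gram of all rows.
#' @param y Class labels.
#' @param k Number of folds (default 5); must not exceed the smallest class
#'   count.
#' @param seed Seed for the fold assignment.
#' @param C SVM regularization.
#' @return A `cv_report`: `fold_scores`, `mean`, `sd`, `ci95`, `k`, `seed`.
#' @export
crossval_precomputed <- function(K, y, k = 5L, seed = 1L, C = 1) {
  V <- kernel_values(K)
  y <- as.character(y)
  if (min(table(y)) < k) {
    stop(sprintf("k = %d exceeds the smallest class count (%d)",
                 k, min(table(y))), call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    model <- svm_fit_precomputed(V[tr, tr, drop = FALSE], y[tr], C = C)
    pred <- svm_predict(model, V[te, tr, drop = FALSE])
    mean(pred == y[te])
  }, numeric(1))
  structure(
    list(fold_scores = scores, mean = mean(scores), sd = sd(scores),
         ci95 = 1.96 * sd(scores) / sqrt(k), k = k, seed = seed),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy: %.4f +/- %.4f (sd), CI95 half-width %.4f\n",
              x$k, x$mean, x$sd, x$ci95))
  invisible(x)
}

ALGORITHMS <- c("SVM_linear", "SVM_rbf", "SVM_poly", "SVM_sigmoid",
                "q_kernel_zz", "q_kernel_default", "q_kernel_8",
                "q_kernel_9", "q_kernel_10", "q_kernel_11", "q_kernel_12",
                "q_kernel_training")

algorithm_encoding <- c(
  q_kernel_zz = "zz", q_kernel_default = "default", q_kernel_8 = "k8",
  q_kernel_9 = "k9", q_kernel_10 = "k10", q_kernel_11 = "k11",
  q_kernel_12 = "k12", q_kernel_training = "zz"
)

#' Benchmark grid configuration
#'
#' Declares the (rescaler x reducer x algorithm) grid. The default
#' extraction grid spans all 11 rescalers and all 14 catalogue extraction
#' methods (>= 150 combinations per algorithm); the default selection grid
#' spans the 11 rescalers and the 3 tree selectors.
#'
#' @param rescalers Character vector of rescaler method names.
#' @param reducers List of reducer cells, each
#'   `list(mode = "selection"|"extraction", method = ..., k/n_components)`.
#' @param algorithms Character vector from `ALGORITHMS`.
#' @param cv_folds,train_fraction,C,seed Evaluation protocol settings.
#' @param max_qubits Guardrail: quantum cells refuse more qubits than this
#'   (default 10).
#' @param shots,mode Quantum Gram evaluation mode (default exact).
#' @return A `benchmark_config`.
#' @export
benchmark_config <- function(rescalers = RESCALER_METHODS,
                             reducers = default_reducers("extraction"),
                             algorithms = ALGORITHMS,
                             cv_folds = 5L, train_fraction = 0.8, C = 1,
                             seed = 1L, max_qubits = 10L,
                             shots = 1024L, mode = "exact") {
  stopifnot(all(rescalers %in% RESCALER_METHODS),
            all(algorithms %in% ALGORITHMS), length(reducers) > 0)
  structure(
    list(rescalers = rescalers, reducers = reducers,
         algorithms = algorithms, cv_folds = as.integer(cv_folds),
         train_fraction = train_fraction, C = C, seed = as.integer(seed),
         max_qubits = as.integer(max_qubits), shots = as.integer(shots),
         mode = mode),
    class = "benchmark_config"
  )
}

#' @rdname benchmark_config
#' @param kind `"extraction"` (14 two-component extractors) or
#'   `"selection"` (3 tree selectors at `k` features).
#' @param k Selected feature count for selection reducers (default 5).
#' @param n_components Component count for extraction reducers (default 2).
#' @export
default_reducers <- function(kind = c("extraction", "selection"), k = 5L,
                             n_components = 2L) {
  kind <- match.arg(kind)
  if (kind == "extraction") {
    lapply(EXTRACTION_METHODS, function(m) {
      list(mode = "extraction", method = m, n_components = n_components)
    })
  } else {
    lapply(TREE_METHODS, function(m) {
      list(mode = "selection", method = m, k = k)
    })
  }
}

reducer_label <- function(red) {
  if (red$mode == "selection") {
    sprintf("embedded_%s", red$method)
  } else {
    red$method
  }
}

#' Run the benchmark grid
#'
#' Executes every (rescaler, reducer, algorithm) cell end-to-end on a
#' labeled feature table: stratified 80/20 holdout; rescaler fit on the
#' training split only; reduction (tree-importance selection or component
#' extraction — transductive extractors embed the full matrix with a logged
#' caveat); Gram construction; stratified k-fold CV on the training Gram;
#' holdout accuracy from a refit on the full training split. Cells that
#' error (e.g. Box-Cox on non-positive data, the k11 singularity, missing
#' extractor backends) are recorded as rows with `status = "error"` rather
#' than aborting the grid. Deterministic under the config seed.
#'
#' @param table A `morphometry_table` (complete rows; filter first).
#' @param config A [benchmark_config()].
#' @param quiet Suppress per-cell progress messages (default `TRUE`).
#' @return A data frame of benchmark rows: `rescaling`, `feature_reduction`,
#'   `algorithm`, `cv_mean`, `cv_std`, `cv_ci95`, `holdout_accuracy`,
#'   `status`, `message`.
#' @export
run_benchmark <- function(table, config = benchmark_config(),
                          quiet = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  y <- as.character(table$label)
  X <- feature_matrix(table)
  if (anyNA(X)) stop("table contains missing values; filter first",
                     call. = FALSE)
  split <- holdout_split(y, config$train_fraction, seed = config$seed)

  rows <- list()
  for (resc in config$rescalers) {
    for (red in config$reducers) {
      prep <- tryCatch(
        prepare_cell(X, y, split, resc, red, config),
        error = function(e) e
      )
      for (alg in config$algorithms) {
        cell_name <- sprintf("%s | %s | %s", resc, reducer_label(red), alg)
        if (!quiet) message("cell: ", cell_name)
        row <- if (inherits(prep, "error")) {
          error_row(resc, red, alg, conditionMessage(prep))
        } else {
          tryCatch(
            evaluate_cell(prep, y, split, alg, config, resc, red),
            error = function(e) error_row(resc, red, alg,
                                          conditionMessage(e))
          )
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

prepare_cell <- function(X, y, split, resc, red, config) {
  tr <- split$train; te <- split$test
  rs <- fit_rescaler(X[tr, , drop = FALSE], resc)
  Xtr <- apply_rescaler(rs, X[tr, , drop = FALSE])
  Xte <- apply_rescaler(rs, X[te, , drop = FALSE])

  if (red$mode == "selection") {
    imp <- tree_importances(Xtr, y[tr], method = red$method,
                            seed = config$seed)
    sel <- select_top_k(imp, red$k)
    list(train = Xtr[, sel, drop = FALSE], test = Xte[, sel, drop = FALSE],
         transductive = FALSE)
  } else {
    if (red$method %in% TRANSDUCTIVE_EXTRACTION) {
      # no out-of-sample transform: embed the full design matrix and split
      # afterwards (caveat recorded on the cell rows)
      Xall <- rbind(Xtr, Xte)
      proj <- extract_components(Xall, c(y[tr], y[te]), red$method,
                                 n_components = red$n_components,
                                 seed = config$seed)
      ntr <- length(tr)
      list(train = proj[seq_len(ntr), , drop = FALSE],
           test = proj[ntr + seq_along(te), , drop = FALSE],
           transductive = TRUE)
    } else {
      proj <- extract_components(Xtr, y[tr], red$method,
                                 n_components = red$n_components,
                                 seed = config$seed)
      list(train = proj,
           test = apply_reducer(attr(proj, "reducer"), Xte),
           transductive = FALSE)
    }
  }
}

evaluate_cell <- function(prep, y, split, alg, config, resc, red) {
  ytr <- y[split$train]; yte <- y[split$test]
  Xtr <- prep$train; Xte <- prep$test

  if (startsWith(alg, "SVM_")) {
    cspec <- classical_kernel_spec(sub("SVM_", "", alg))
    Ktr <- classical_gram(Xtr, spec = cspec)
    cspec <- Ktr$classical_spec     # data-derived defaults resolved on train
    Kte <- classical_gram(Xte, Xtr, spec = cspec)
  } else if (alg == "q_kernel_training") {
    if (ncol(Xtr) > config$max_qubits) {
      stop(sprintf("cell needs %d qubits, above the %d-qubit guardrail",
                   ncol(Xtr), config$max_qubits), call. = FALSE)
    }
    spec <- feature_map_spec(ncol(Xtr), encoding = "zz")
    qcfg <- qka_config(C = config$C, seed = config$seed)
    trained <- train_quantum_kernel(Xtr, ytr, spec, qcfg)
    Ktr <- trained$kernel
    Kte <- qka_kernel_matrix(Xte, spec, trained$lambda, Z = Xtr)
  } else {
    if (ncol(Xtr) > config$max_qubits) {
      stop(sprintf("cell needs %d qubits, above the %d-qubit guardrail",
                   ncol(Xtr), config$max_qubits), call. = FALSE)
    }
    spec <- feature_map_spec(ncol(Xtr),
                             encoding = algorithm_encoding[[alg]])
    Ktr <- kernel_matrix(Xtr, spec, mode = config$mode,
                         shots = config$shots, seed = config$seed)
    Kte <- kernel_matrix(Xte, spec, Z = Xtr, mode = config$mode,
                         shots = config$shots, seed = config$seed + 1L)
  }

  Ktr <- psd_projection(Ktr)
  cv <- crossval_precomputed(Ktr, ytr, k = config$cv_folds,
                             seed = config$seed, C = config$C)
  model <- svm_fit_precomputed(Ktr, ytr, C = config$C)
  holdout <- mean(svm_predict(model, Kte) == yte)

  data.frame(
    rescaling = resc, feature_reduction = reducer_label(red),
    algorithm = alg, cv_mean = cv$mean, cv_std = cv$sd, cv_ci95 = cv$ci95,
    holdout_accuracy = holdout,
    status = if (prep$transductive) "ok_transductive" else "ok",
    message = if (prep$transductive) {
      "transductive embedding fit on train+test jointly"
    } else "",
    stringsAsFactors = FALSE
  )
}

error_row <- function(resc, red, alg, msg) {
  data.frame(
    rescaling = resc, feature_reduction = reducer_label(red),
    algorithm = alg, cv_mean = NA_real_, cv_std = NA_real_,
    cv_ci95 = NA_real_, holdout_accuracy = NA_real_, status = "error",
    message = msg, stringsAsFactors = FALSE
  )
}

#' Top-n benchmark rows
#'
#' Sorts successful rows by CV mean descending, ties by lower CV standard
#' deviation, then lexicographic cell name, and returns the first `n`.
#'
#' @param rows A benchmark result data frame.
#' @param n Number of rows (default 5).
#' @return The selected rows.
#' @export
top_n_rows <- function(rows, n = 5L) {
  if (nrow(rows) == 0) stop("no benchmark rows", call. = FALSE)
  ok <- rows[!is.na(rows$cv_mean), , drop = FALSE]
  cell <- paste(ok$rescaling, ok$feature_reduction, ok$algorithm)
  ord <- order(-ok$cv_mean, ok$cv_std, cell)
  head(ok[ord, , drop = FALSE], n)
}
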