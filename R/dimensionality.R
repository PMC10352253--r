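#' Gini impurity of a class-probability vector
#'
#' Gini = 1 - sum(p_i^2): 0 when all mass sits on one class, 0.5 for two
#' equally probable classes, approaching 1 as mass spreads over many classes.
#' This is the node-impurity measure whose total decrease defines the
#' tree-based feature importances used for feature selection.
#'
#' @param p Non-negative probability vector summing to 1 (within 1e-9).
#' @return The impurity, in `[0, 1 - 1/length(p)]`.
#' @export
#' @examples
#' gini_index(1)                    # pure node: 0
#' gini_index(c(0.5, 0.5))          # two equal classes: 0.5
#' gini_index(rep(0.25, 4))         # four equal classes: 0.75
gini_index <- function(p) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p)) {
    stop("p must be a numeric probability vector", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("p must be non-negative and sum to 1 (within 1e-9)", call. = FALSE)
  }
  1 - sum(p^2)
}

TREE_METHODS <- c("random_forest", "decision_tree", "xgboost")

#' Tree-based feature importances
#'
#' Fits one of three tree ensembles and returns per-feature Gini
#' impurity-decrease importances, normalized so they sum to 1. The ensemble
#' fits are delegated to \pkg{randomForest}, \pkg{rpart} and \pkg{xgboost};
#' the aggregation to a full-length, normalized importance vector (absent
#' features scored 0) is owned here.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels (any atomic vector; at least two distinct values).
#' @param method `"random_forest"`, `"decision_tree"` or `"xgboost"`.
#' @param seed Seed for the ensemble fit (default 1).
#' @param n_trees Ensemble size for forest/boosting methods (default 100).
#' @return An `importance_vector`: numeric vector of length `ncol(X)`
#'   summing to 1, with `method` and `seed` attributes.
#' @export
tree_importances <- function(X, y, method = TREE_METHODS, seed = 1L,
                             n_trees = 100L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    stop("y must contain at least two classes", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  raw <- switch(
    method,
    random_forest = {
      fit <- randomForest::randomForest(x = X, y = factor(y),
                                        ntree = n_trees)
      imp <- fit$importance[, "MeanDecreaseGini"]
      setNames(as.numeric(imp), rownames(fit$importance))
    },
    decision_tree = {
      df <- data.frame(.y = factor(y), X, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(cp = 0.001,
                                                         xval = 0))
      fit$variable.importance %||% setNames(numeric(0), character(0))
    },
    xgboost = {
      enc <- encode_labels(y)
      fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(enc$levels),
                      max_depth = 4, eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = enc$y, nthread = 1),
        nrounds = n_trees, verbose = 0
      )
      imp <- xgboost::xgb.importance(model = fit)
      setNames(imp$Gain, imp$Feature)
    }
  )

  full <- setNames(numeric(ncol(X)), colnames(X))
  raw <- raw[names(raw) %in% names(full)]
  full[names(raw)] <- pmax(as.numeric(raw), 0)
  if (sum(full) <= 0) {
    stop("tree ensemble produced no splits; importances undefined",
         call. = FALSE)
  }
  structure(full / sum(full), class = "importance_vector",
            method = method, seed = seed)
}

#' Select the k most important features
#'
#' Pure function of an importance vector: returns the indices of the `k`
#' largest importances, ordered by importance descending, ties broken by
#' ascending feature index.
#'
#' @param imp Numeric importance vector (e.g. from [tree_importances()]).
#' @param k Number of features, `1 <= k <= length(imp)`.
#' @return Integer vector of length `k`.
#' @export
select_top_k <- function(imp, k) {
  imp <- as.numeric(imp)
  if (k < 1 || k > length(imp) || k != round(k)) {
    stop("k must be an integer in [1, length(imp)]", call. = FALSE)
  }
  ord <- order(-imp, seq_along(imp))
  ord[seq_len(k)]
}

EXTRACTION_METHODS <- c(
  "pca", "ica", "ica_pca", "lda", "random_projection", "truncated_svd",
  "isomap", "nca", "tsne", "lle", "hessian_lle", "mlle", "ltsa", "mds"
)

# Methods with an installed R backend; the rest are registered grid members
# that raise a clear error (recorded as error rows by the benchmark grid).
BACKED_EXTRACTION <- c("pca", "lda", "random_projection", "truncated_svd",
                       "isomap", "mds")
TRANSDUCTIVE_EXTRACTION <- c("isomap", "mds", "tsne", "lle", "hessian_lle",
                             "mlle", "ltsa")

#' Project features onto low-dimensional components
#'
#' Uniform adapter over established feature-extraction implementations,
#' reduced to `n_components` (default 2) columns: PCA (`stats::prcomp`),
#' LDA (`MASS::lda`, supervised, at most `n_classes - 1` components),
#' Gaussian random projection (seeded), truncated SVD, Isomap
#' (`vegan::isomap`) and classical MDS (`stats::cmdscale`). Isomap and MDS
#' have no out-of-sample transform and are flagged transductive: they embed
#' the full matrix they are given, and the benchmark grid logs a caveat when
#' it uses them across a train/test split. The remaining catalogue names
#' (ica, ica_pca, nca, tsne, the LLE family, ltsa) have no installed backend
#' here and raise an error naming the method.
#'
#' @param X Numeric matrix.
#' @param y Class labels; required for supervised methods (lda).
#' @param method One of the 14 catalogue names in `EXTRACTION_METHODS`.
#' @param n_components Number of output columns (default 2).
#' @param seed Seed for stochastic methods (random projection).
#' @return Matrix with `n_components` columns and `nrow(X)` rows, with
#'   attributes `reducer` (fitted state for out-of-sample projection via
#'   [apply_reducer()], where supported) and `transductive` (logical).
#' @export
extract_components <- function(X, y = NULL, method, n_components = 2L,
                               seed = 1L) {
  method <- match.arg(method, EXTRACTION_METHODS)
  X <- as.matrix(X)
  if (!method %in% BACKED_EXTRACTION) {
    stop(sprintf("feature extraction method '%s' has no installed backend",
                 method), call. = FALSE)
  }
  out <- switch(
    method,
    pca = {
      fit <- prcomp(X, center = TRUE, scale. = FALSE)
      k <- min(n_components, ncol(fit$rotation))
      proj <- fit$x[, seq_len(k), drop = FALSE]
      if (k < n_components) {
        proj <- cbind(proj, matrix(0, nrow(X), n_components - k))
      }
      list(proj = proj,
           reducer = list(method = "pca", center = fit$center,
                          rotation = fit$rotation[, seq_len(k), drop = FALSE],
                          pad = n_components - k))
    },
    lda = {
      if (is.null(y)) stop("lda requires class labels y", call. = FALSE)
      nc <- length(unique(y))
      if (n_components > nc - 1L) {
        stop(sprintf("lda supports at most n_classes - 1 = %d components",
                     nc - 1L), call. = FALSE)
      }
      fit <- MASS::lda(X, grouping = factor(y))
      proj <- predict(fit, X)$x[, seq_len(n_components), drop = FALSE]
      list(proj = proj, reducer = list(method = "lda", fit = fit,
                                       k = n_components))
    },
    random_projection = {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old))
      set.seed(seed)
      R <- matrix(rnorm(ncol(X) * n_components), ncol(X),
                  n_components) / sqrt(n_components)
      list(proj = X %*% R, reducer = list(method = "random_projection",
                                          R = R))
    },
    truncated_svd = {
      sv <- svd(X, nu = n_components, nv = n_components)
      k <- min(n_components, length(sv$d))
      proj <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                        k, k)
      list(proj = proj, reducer = list(method = "truncated_svd",
                                       v = sv$v[, seq_len(k), drop = FALSE]))
    },
    isomap = {
      d <- dist(X)
      k_nn <- max(4L, min(10L, nrow(X) - 1L))
      fit <- vegan::isomap(d, ndim = n_components, k = k_nn)
      list(proj = fit$points[, seq_len(n_components), drop = FALSE],
           reducer = NULL)
    },
    mds = {
      proj <- cmdscale(dist(X), k = n_components)
      list(proj = proj, reducer = NULL)
    }
  )
  proj <- unname(out$proj)
  attr(proj, "reducer") <- out$reducer
  attr(proj, "transductive") <- method %in% TRANSDUCTIVE_EXTRACTION
  proj
}

#' Project new data with a fitted reducer
#'
#' Out-of-sample projection for inductive extraction methods (pca, lda,
#' random_projection, truncated_svd). Transductive methods carry no reducer
#' state and cannot be applied to new rows.
#'
#' @param reducer The `reducer` attribute of an [extract_components()]
#'   result.
#' @param X New data matrix with the original feature layout.
#' @return Projected matrix.
#' @export
apply_reducer <- function(reducer, X) {
  if (is.null(reducer)) {
    stop("reducer is transductive: no out-of-sample transform available",
         call. = FALSE)
  }
  X <- as.matrix(X)
  switch(
    reducer$method,
    pca = {
      proj <- sweep(X, 2, reducer$center) %*% reducer$rotation
      if (reducer$pad > 0) proj <- cbind(proj, matrix(0, nrow(X),
                                                      reducer$pad))
      proj
    },
    lda = predict(reducer$fit, X)$x[, seq_len(reducer$k), drop = FALSE],
    random_projection = X %*% reducer$R,
    truncated_svd = X %*% reducer$v,
    stop("unknown reducer method", call. = FALSE)
  )
}

#' Export importances as a ranked CSV
#'
#' Writes `feature,importance,rank` sorted by importance descending (the
#' tie-break of [select_top_k()]).
#'
#' @param imp An `importance_vector`.
#' @param path Output CSV path.
#' @export
write_importances <- function(imp, path) {
  ord <- select_top_k(imp, length(imp))
  df <- data.frame(
    feature = names(imp)[ord] %||% as.character(ord),
    importance = as.numeric(imp)[ord],
    rank = seq_along(ord)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
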