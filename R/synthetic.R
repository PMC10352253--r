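#' Specification for a synthetic morphometry table
#'
#' Describes a seed-reproducible synthetic neuron feature table: a number of
#' neurons, M-type classes, and positive-valued morphometric features
#' (L-Measure-style lengths, surfaces, angles, counts), with a small planted
#' subset of informative features carrying the class signal and optional
#' injected artifacts (missing cells, zero soma surfaces, multivariate
#' outliers) exercising the preprocessing filters.
#'
#' @param n_neurons Number of rows to generate.
#' @param n_classes Number of M-type classes (default 14, the full label set).
#' @param n_features Number of morphometric features (default 43).
#' @param n_informative Number of planted informative features (default 5).
#' @param class_proportions Simplex vector of length `n_classes`; defaults to
#'   uniform. Must sum to 1 within 1e-12.
#' @param feature_scale Typical feature magnitude in native units (e.g. µm);
#'   informative and noise features are log-normal around this scale.
#' @param outlier_rate,missing_rate,zero_soma_rate Artifact fractions in
#'   \[0, 1\] applied by [inject_artifacts()].
#' @param seed Root seed; all draws derive per-purpose child streams from it.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [inject_artifacts()],
#'   [informative_feature_indices()]
#' @export
#' @examples
#' spec <- synthetic_spec(n_neurons = 260, seed = 1)
#' tab <- generate_dataset(spec)
#' dim(tab)
synthetic_spec <- function(n_neurons,
                           n_classes = 14L,
                           n_features = 43L,
                           n_informative = 5L,
                           class_proportions = NULL,
                           feature_scale = 100,
                           outlier_rate = 0,
                           missing_rate = 0,
                           zero_soma_rate = 0,
                           seed = 1L) {
  if (!is.numeric(n_neurons) || length(n_neurons) != 1L || n_neurons < 1 ||
      n_neurons != round(n_neurons)) {
    stop("invalid `n_neurons`: must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_classes) || n_classes < 1 || n_classes != round(n_classes)) {
    stop("invalid `n_classes`: must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_features) || n_features < 2 || n_features != round(n_features)) {
    stop("invalid `n_features`: must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(n_informative) || n_informative < 0 ||
      n_informative != round(n_informative) || n_informative > n_features - 1L) {
    stop("invalid `n_informative`: must be an integer in [0, n_features - 1] ",
         "(the soma-surface column is never informative)", call. = FALSE)
  }
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes) {
    stop("invalid `class_proportions`: length must equal n_classes",
         call. = FALSE)
  }
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-12) {
    stop("invalid `class_proportions`: must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (!is.numeric(feature_scale) || feature_scale <= 0) {
    stop("invalid `feature_scale`: must be positive", call. = FALSE)
  }
  for (r in c("outlier_rate", "missing_rate", "zero_soma_rate")) {
    v <- get(r)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("invalid `%s`: must be a fraction in [0, 1]", r),
           call. = FALSE)
    }
  }
  structure(
    list(
      n_neurons = as.integer(n_neurons),
      n_classes = as.integer(n_classes),
      n_features = as.integer(n_features),
      n_informative = as.integer(n_informative),
      class_proportions = as.numeric(class_proportions),
      feature_scale = as.numeric(feature_scale),
      outlier_rate = outlier_rate,
      missing_rate = missing_rate,
      zero_soma_rate = zero_soma_rate,
      seed = as.integer(seed),
      # Fixed generator shape parameters (not user dials): log-scale noise
      # and the inter-class location step of one log-sd between adjacent
      # class ranks — the minimum separation the class structure guarantees.
      sdlog = 0.4,
      location_step = 0.4
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic morphometry spec:", x$n_neurons, "neurons,",
      x$n_classes, "classes,", x$n_features, "features (",
      x$n_informative, "informative ), seed", x$seed, "\n")
  invisible(x)
}

feature_names <- function(n_features) {
  c("Soma_Surface", sprintf("F%02d", seq_len(n_features - 1L)))
}

class_names <- function(n_classes) {
  if (n_classes <= length(M_TYPES)) {
    M_TYPES[seq_len(n_classes)]
  } else {
    c(M_TYPES, sprintf("mtype_%02d", seq_len(n_classes - length(M_TYPES))))
  }
}

#' Indices of the planted informative features
#'
#' Returns the ground-truth informative feature columns of a synthetic spec
#' (1-based positions within the feature block). The set is a deterministic
#' function of the spec's seed and never contains the soma-surface column,
#' so zero-soma artifact injection cannot erase class signal.
#'
#' @param spec A [synthetic_spec()].
#' @return Sorted integer vector of length `n_informative`.
#' @export
informative_feature_indices <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_informative == 0L) return(integer(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(spec$seed, "informative"))
  sort(sample(2:spec$n_features, spec$n_informative))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Graded class ranks per informative feature: each informative coordinate
# orders the classes by an independent random permutation, with adjacent
# ranks one log-sd apart. Every class thus sits at a distinct location on
# every informative feature (morphometric magnitudes genuinely grade across
# M-types), and quantile rescaling maps each class to a narrow distinct
# band instead of smearing it across a shared mode.
class_ranks <- function(n_classes, n_informative, seed) {
  if (n_informative == 0L) {
    return(matrix(0, n_classes, 0))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, "class_ranks"))
  vapply(seq_len(n_informative), function(kj) sample.int(n_classes),
         integer(n_classes))
}

#' Generate a synthetic neuron morphometry table
#'
#' Draws a labeled neuron-by-feature table with the statistical structure the
#' downstream analysis assumes: positive right-skewed (log-normal) features,
#' class-dependent locations on the planted informative columns (each
#' informative feature grades the classes by an independent random
#' permutation of ranks, adjacent ranks one log-standard-deviation apart,
#' so every class occupies a distinct location on every informative
#' feature), and class-independent noise on the rest. Class counts are
#' multinomial under `class_proportions`. Fully deterministic under the
#' spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `morphometry_table`: a data frame with columns `neuron_id`,
#'   `label`, `Soma_Surface`, `F01` ... Feature columns are numeric; no
#'   missing values (artifacts are injected separately by
#'   [inject_artifacts()]).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_neurons
  p <- spec$n_features
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(child_seed(spec$seed, "labels"))
  labels <- class_names(spec$n_classes)[
    sample.int(spec$n_classes, n, replace = TRUE, prob = spec$class_proportions)
  ]

  info_idx <- informative_feature_indices(spec)
  ranks <- class_ranks(spec$n_classes, spec$n_informative, spec$seed)
  rownames(ranks) <- class_names(spec$n_classes)

  set.seed(child_seed(spec$seed, "noise_locations"))
  # Per-feature baseline log-locations, class-independent; soma surface is a
  # surface (µm^2) and sits one decade above the length scale.
  base_loc <- rnorm(p, mean = log(spec$feature_scale), sd = 0.5)
  base_loc[1L] <- log(10 * spec$feature_scale)

  set.seed(child_seed(spec$seed, "features"))
  X <- matrix(0, n, p)
  for (j in seq_len(p)) {
    loc <- rep(base_loc[j], n)
    if (j %in% info_idx) {
      # centered graded ranks: adjacent classes `location_step` apart
      kj <- match(j, info_idx)
      loc <- base_loc[j] +
        (ranks[labels, kj] - (spec$n_classes + 1) / 2) * spec$location_step
    }
    X[, j] <- rlnorm(n, meanlog = loc, sdlog = spec$sdlog)
  }
  colnames(X) <- feature_names(p)

  tab <- data.frame(
    neuron_id = sprintf("syn_%06d", seq_len(n)),
    label = labels,
    X,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  class(tab) <- c("morphometry_table", "data.frame")
  attr(tab, "spec") <- spec
  tab
}

#' Feature block of a morphometry table
#'
#' @param table A `morphometry_table`.
#' @return Numeric matrix of the feature columns (everything after
#'   `neuron_id` and `label`).
#' @export
feature_matrix <- function(table) {
  cols <- setdiff(colnames(table), c("neuron_id", "label"))
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}

#' Inject missing-value, zero-soma and outlier artifacts
#'
#' Modifies a clean synthetic table to exercise the preprocessing filters:
#' marks `floor(missing_rate * n)` cells missing (one per affected row), sets
#' `Soma_Surface` to exactly 0 in `floor(zero_soma_rate * n)` rows, and
#' displaces `floor(outlier_rate * n)` rows by 8 to 12 robust standard
#' deviations per feature (random signs) from their class mean, so each
#' outlier is extreme along its own direction. The three affected row sets
#' are disjoint, so ground-truth bookkeeping identifies each artifact kind
#' exactly under the fixed filter order (missing, zero-soma, Mahalanobis).
#'
#' @param table A `morphometry_table` from [generate_dataset()].
#' @param spec The [synthetic_spec()] carrying the rates and seed.
#' @return A list: `table` (modified copy), `missing_rows`, `zero_soma_rows`,
#'   `outlier_rows` (integer row indices of each artifact kind).
#' @export
inject_artifacts <- function(table, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (r in c("outlier_rate", "missing_rate", "zero_soma_rate")) {
    if (spec[[r]] < 0 || spec[[r]] > 1) {
      stop(sprintf("invalid `%s`: must be in [0, 1]", r), call. = FALSE)
    }
  }
  n <- nrow(table)
  n_missing <- floor(spec$missing_rate * n)
  n_zero <- floor(spec$zero_soma_rate * n)
  n_out <- floor(spec$outlier_rate * n)
  if (n_missing + n_zero + n_out > n) {
    stop("artifact rates sum to more than one row per neuron", call. = FALSE)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(spec$seed, "artifacts"))

  rows <- sample.int(n, n_missing + n_zero + n_out)
  missing_rows <- sort(rows[seq_len(n_missing)])
  zero_rows <- sort(rows[n_missing + seq_len(n_zero)])
  outlier_rows <- sort(rows[n_missing + n_zero + seq_len(n_out)])

  X <- feature_matrix(table)
  p <- ncol(X)

  if (n_out > 0) {
    # Robust per-feature spread and per-class centers from the clean table.
    rsd <- apply(X, 2, mad)
    rsd[rsd == 0] <- sd(X[, 1]) * 1e-3 + 1e-9
    centers <- rowsum(X, table$label) / as.vector(table(table$label)[
      sort(unique(table$label))])
    for (i in outlier_rows) {
      # independent random sign patterns so a group of outliers does not
      # inflate a single covariance direction and mask itself
      mult <- runif(p, 8, 12) * sample(c(-1, 1), p, replace = TRUE)
      X[i, ] <- centers[table$label[i], ] + mult * rsd
    }
  }
  if (n_missing > 0) {
    cells <- sample.int(p, n_missing, replace = TRUE)
    for (k in seq_len(n_missing)) X[missing_rows[k], cells[k]] <- NA_real_
  }
  if (n_zero > 0) X[zero_rows, "Soma_Surface"] <- 0

  out <- table
  out[, colnames(X)] <- X
  list(
    table = out,
    missing_rows = missing_rows,
    zero_soma_rows = zero_rows,
    outlier_rows = outlier_rows
  )
}
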