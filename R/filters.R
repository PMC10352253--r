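#' Row filters for morphometry tables
#'
#' The preprocessing stage applies three row filters in a fixed order:
#' rows with any missing feature are deleted, rows whose soma surface equals
#' exactly 0 are deleted, and multivariate outliers by Mahalanobis distance
#' are deleted. Each filter returns the surviving table together with a
#' `filter_report` reconciling counts and removed indices.
#'
#' @name filters
NULL

new_filter_report <- function(rows_in, removed, kind, threshold = NA_real_) {
  structure(
    list(
      rows_in = rows_in,
      rows_out = rows_in - length(removed),
      removed = as.integer(removed),
      kind = kind,
      threshold = threshold
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter [%s]: %d rows in, %d removed, %d out\n",
              x$kind, x$rows_in, length(x$removed), x$rows_out))
  invisible(x)
}

#' Delete rows containing missing feature values
#'
#' A neuron with any missing feature value is deleted from the dataset
#' (no imputation).
#'
#' @param table A `morphometry_table` (or data frame in the same layout).
#' @return A list with `table` (complete rows only) and `report`
#'   (a `filter_report` whose `removed` lists the deleted row indices).
#' @export
drop_incomplete_rows <- function(table) {
  X <- feature_matrix(table)
  bad <- which(rowSums(is.na(X)) > 0)
  out <- table[setdiff(seq_len(nrow(table)), bad), , drop = FALSE]
  if (nrow(out) == 0L) warning("all rows removed by the missing-value filter")
  list(table = out, report = new_filter_report(nrow(table), bad, "missing"))
}

#' Delete rows whose soma surface equals zero
#'
#' Strict equality against 0, as reconstructions with an absent soma are
#' recorded with a surface of exactly 0; arbitrarily small positive surfaces
#' are kept.
#'
#' @param table A `morphometry_table` with a `Soma_Surface` column.
#' @return A list with `table` and `report` as in [drop_incomplete_rows()].
#' @export
drop_zero_soma <- function(table) {
  if (!"Soma_Surface" %in% colnames(table)) {
    stop("table has no `Soma_Surface` column", call. = FALSE)
  }
  bad <- which(!is.na(table$Soma_Surface) & table$Soma_Surface == 0)
  out <- table[setdiff(seq_len(nrow(table)), bad), , drop = FALSE]
  list(table = out, report = new_filter_report(nrow(table), bad, "zero_soma"))
}

#' Mahalanobis multivariate outlier filter
#'
#' Removes rows whose squared Mahalanobis distance to the column mean exceeds
#' the chi-squared quantile at `1 - alpha` with `ncol(X)` degrees of freedom.
#' Distances use a shrinkage-regularized covariance (Schaefer-Strimmer /
#' Ledoit-Wolf-style scalar shrinkage via \pkg{corpcor}) by default, which
#' keeps the filter usable when the feature count approaches the sample size.
#'
#' @param X Numeric feature matrix (no missing values).
#' @param alpha Upper-tail probability of the chi-squared cutoff
#'   (default 0.025, i.e. the 97.5th percentile).
#' @param shrinkage Use shrinkage covariance (default `TRUE`). With
#'   `shrinkage = FALSE` a singular sample covariance is an error.
#' @return A list: `keep` (surviving row indices), `distances` (squared
#'   Mahalanobis distances), and `report` (a `filter_report` with the cutoff
#'   in `threshold`).
#' @export
mahalanobis_filter <- function(X, alpha = 0.025, shrinkage = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; filter them first",
                     call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (shrinkage) {
    S <- suppressWarnings(
      as.matrix(corpcor::cov.shrink(X, verbose = FALSE))
    )
  } else {
    S <- cov(X)
    if (!is.finite(rcond_sym(S)) || rcond_sym(S) < 1e-12) {
      stop("sample covariance is singular; enable `shrinkage = TRUE`",
           call. = FALSE)
    }
  }
  d2 <- mahalanobis(X, colMeans(X), S)
  cutoff <- qchisq(1 - alpha, df = ncol(X))
  bad <- which(d2 > cutoff)
  list(
    keep = setdiff(seq_len(nrow(X)), bad),
    distances = d2,
    report = new_filter_report(nrow(X), bad, "mahalanobis", cutoff)
  )
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Run all three row filters in order
#'
#' Applies [drop_incomplete_rows()], [drop_zero_soma()] and
#' [mahalanobis_filter()] in the fixed preprocessing order and returns the
#' surviving table with the three reports. Removed-index lists refer to row
#' positions in the table each filter received, plus `removed_original`
#' entries mapped back to the input table.
#'
#' @param table A `morphometry_table`.
#' @param alpha Mahalanobis tail probability (see [mahalanobis_filter()]).
#' @param shrinkage Passed to [mahalanobis_filter()].
#' @return A list: `table`, `reports` (list of the three `filter_report`s),
#'   `removed_original` (list of original row indices removed per filter).
#' @export
filter_table <- function(table, alpha = 0.025, shrinkage = TRUE) {
  orig <- seq_len(nrow(table))

  s1 <- drop_incomplete_rows(table)
  rm1 <- orig[s1$report$removed]
  orig <- setdiff(orig, rm1)

  s2 <- drop_zero_soma(s1$table)
  rm2 <- orig[s2$report$removed]
  orig <- setdiff(orig, rm2)

  s3 <- mahalanobis_filter(feature_matrix(s2$table), alpha = alpha,
                           shrinkage = shrinkage)
  rm3 <- orig[s3$report$removed]

  list(
    table = s2$table[s3$keep, , drop = FALSE],
    reports = list(missing = s1$report, zero_soma = s2$report,
                   mahalanobis = s3$report),
    removed_original = list(missing = rm1, zero_soma = rm2,
                            mahalanobis = rm3)
  )
}

#' Encode class labels as integers
#'
#' Deterministic bijective label encoding: distinct label strings are sorted
#' lexicographically (C collation) and mapped to consecutive integers
#' starting at 0.
#'
#' @param labels Character (or factor) vector of class labels.
#' @return A list: `y` (integer codes, 0-based), `levels` (sorted label
#'   names; `levels[y + 1]` decodes).
#' @export
encode_labels <- function(labels) {
  labels <- as.character(labels)
  lev <- sort(unique(labels), method = "radix")
  list(y = match(labels, lev) - 1L, levels = lev)
}

#' Decode integer labels back to names
#'
#' @param y Integer codes from [encode_labels()].
#' @param levels The `levels` component from [encode_labels()].
#' @return Character vector of label names.
#' @export
decode_labels <- function(y, levels) levels[y + 1L]
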