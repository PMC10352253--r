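#' Read and write morphometry feature tables
#'
#' The on-disk dialect is plain CSV with header
#' `neuron_id,label,Soma_Surface,F01,...`, UTF-8, `.` decimal separator,
#' missing cells empty. `read_feature_table()` validates the header and
#' every feature cell, reporting the offending row and column on failure;
#' row order is preserved and empty cells become `NA` (the missing mask).
#'
#' @param path CSV file path.
#' @param table A `morphometry_table` (or data frame in the same layout).
#' @return `read_feature_table()` returns a `morphometry_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 3L || !identical(colnames(raw)[1:2],
                                   c("neuron_id", "label"))) {
    stop("malformed header: expected `neuron_id,label,<features...>`",
         call. = FALSE)
  }
  feat_cols <- colnames(raw)[-(1:2)]
  for (j in feat_cols) {
    cell <- raw[[j]]
    empty <- cell == "" | is.na(cell)
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric feature cell at row %d, column `%s`: '%s'",
                   bad[1], j, cell[bad[1]]), call. = FALSE)
    }
    raw[[j]] <- num
  }
  class(raw) <- c("morphometry_table", "data.frame")
  raw
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Export and import kernel matrices
#'
#' Gram matrices are written as tab-delimited text with a JSON sidecar
#' (`<path>.json`) recording mode, shots, seed and the generating feature
#' map, so any exact-mode artifact can be re-derived bit-identically.
#'
#' @param K A `kernel_matrix`.
#' @param path Output path for the delimited values.
#' @return `read_kernel_matrix()` returns the restored `kernel_matrix`.
#' @export
write_kernel_matrix <- function(K, path) {
  stopifnot(inherits(K, "kernel_matrix"))
  utils::write.table(K$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(
    mode = K$mode,
    shots = if (is.na(K$shots)) NULL else K$shots,
    seed = if (is.na(K$seed)) NULL else K$seed,
    n = nrow(K$values),
    package_version = as.character(utils::packageVersion("qkmorph"))
  )
  if (!is.null(K$spec)) {
    pr <- K$spec$pairs
    sidecar$feature_map <- list(
      n_qubits = K$spec$n_qubits, reps = K$spec$reps,
      encoding = K$spec$encoding,
      pairs = lapply(seq_len(nrow(pr)), function(i) as.integer(pr[i, ])),
      bit_order = K$spec$bit_order
    )
  }
  if (!is.null(K$lambda)) sidecar$lambda <- K$lambda
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kernel_matrix
#' @export
read_kernel_matrix <- function(path) {
  V <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(V) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  spec <- NULL
  if (!is.null(side$feature_map)) {
    fm <- side$feature_map
    pairs <- if (length(fm$pairs) > 0) {
      do.call(rbind, lapply(fm$pairs, function(p) as.integer(unlist(p))))
    } else {
      matrix(integer(0), 0, 2)
    }
    spec <- feature_map_spec(fm$n_qubits, reps = fm$reps,
                             entanglement = pairs, encoding = fm$encoding)
  }
  K <- new_kernel_matrix(V, mode = side$mode,
                         shots = side$shots %||% NA_integer_,
                         seed = side$seed %||% NA_integer_, spec = spec)
  if (!is.null(side$lambda)) K$lambda <- as.numeric(unlist(side$lambda))
  K
}

#' Round-trip a feature map spec through YAML
#'
#' @param spec A [feature_map_spec()].
#' @param path YAML file path.
#' @return `read_feature_map_spec()` returns the restored spec.
#' @export
write_feature_map_spec <- function(spec, path) {
  stopifnot(inherits(spec, "feature_map_spec"))
  yaml::write_yaml(list(
    n_qubits = spec$n_qubits, reps = spec$reps, encoding = spec$encoding,
    pairs = if (nrow(spec$pairs)) lapply(seq_len(nrow(spec$pairs)),
                                         function(i) as.integer(spec$pairs[i, ]))
            else list(),
    bit_order = spec$bit_order
  ), path)
  invisible(path)
}

#' @rdname write_feature_map_spec
#' @export
read_feature_map_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  ent <- if (length(obj$pairs) > 0) {
    do.call(rbind, lapply(obj$pairs, as.integer))
  } else {
    matrix(integer(0), 0, 2)
  }
  # an empty pair set is only the "full" default for 1 qubit; pass the
  # explicit matrix otherwise
  if (nrow(ent) == 0 && obj$n_qubits == 1) ent <- "full"
  feature_map_spec(obj$n_qubits, reps = obj$reps, entanglement = ent,
                   encoding = obj$encoding)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report` (or the `reports` list from
#'   [filter_table()]).
#' @param path JSON output path.
#' @export
write_filter_report <- function(report, path) {
  to_list <- function(r) {
    list(kind = r$kind, rows_in = r$rows_in, rows_out = r$rows_out,
         removed = as.integer(r$removed),
         threshold = if (is.na(r$threshold)) NULL else r$threshold)
  }
  obj <- if (inherits(report, "filter_report")) to_list(report) else
    lapply(report, to_list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
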