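#' Diagonal Pauli-Z feature map specification
#'
#' Describes the fidelity-kernel feature map: `n_qubits` equals the number of
#' input features; each encoding block applies a Hadamard layer followed by a
#' diagonal phase gate `exp(i * sum_S phi_S(x) prod_{i in S} Z_i)` with
#' singleton terms on every qubit and pair terms on the entanglement graph
#' (default: all pairs i < j, "full"); the block is repeated `reps` times
#' (default 2). The encoding name selects the pair phase function
#' (see [pair_phase()]).
#'
#' Basis-ordering convention: amplitude index `b` (0-based) encodes the
#' computational basis state whose bit `i` (qubit `i`) is the i-th least
#' significant bit of `b`. Fidelity kernels are invariant to this choice; it
#' is fixed so dense oracle constructions can match amplitudes exactly.
#'
#' @param n_qubits Number of qubits (>= 1).
#' @param reps Number of encoding-block repetitions (default 2).
#' @param entanglement `"full"` or a two-column integer matrix of qubit
#'   pairs (1-based, i < j).
#' @param encoding One of `"zz"`, `"default"`, `"k8"`, `"k9"`, `"k10"`,
#'   `"k11"`, `"k12"`.
#' @return A `feature_map_spec`.
#' @export
feature_map_spec <- function(n_qubits, reps = 2L, entanglement = "full",
                             encoding = ENCODINGS) {
  encoding <- match.arg(encoding)
  if (!is.numeric(n_qubits) || n_qubits < 1 || n_qubits != round(n_qubits)) {
    stop("n_qubits must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(reps) || reps < 1 || reps != round(reps)) {
    stop("reps must be an integer >= 1", call. = FALSE)
  }
  if (identical(entanglement, "full")) {
    pairs <- if (n_qubits > 1) t(utils::combn(n_qubits, 2)) else
      matrix(integer(0), 0, 2)
  } else {
    pairs <- as.matrix(entanglement)
    if (ncol(pairs) != 2 ||
        any(pairs < 1) || any(pairs > n_qubits) ||
        any(pairs[, 1] >= pairs[, 2]) ||
        anyDuplicated(paste(pairs[, 1], pairs[, 2]))) {
      stop("entanglement must be distinct ordered qubit pairs (i < j)",
           call. = FALSE)
    }
  }
  structure(
    list(n_qubits = as.integer(n_qubits), reps = as.integer(reps),
         pairs = pairs, encoding = encoding, bit_order = "qubit0_lsb"),
    class = "feature_map_spec"
  )
}

ENCODINGS <- c("zz", "default", "k8", "k9", "k10", "k11", "k12")

#' @export
print.feature_map_spec <- function(x, ...) {
  cat(sprintf("Feature map: %d qubits, %d reps, %d pair terms, encoding %s\n",
              x$n_qubits, x$reps, nrow(x$pairs), x$encoding))
  invisible(x)
}

#' Singleton encoding phase
#'
#' All encodings share the singleton map `phi_{i}(x) = x_i`.
#'
#' @param x_i Feature value (finite).
#' @return `x_i`.
#' @export
singleton_phase <- function(x_i) {
  if (!all(is.finite(x_i))) stop("non-finite input", call. = FALSE)
  x_i
}

#' Pair encoding phase
#'
#' The two-argument pair phase functions attached to ZZ terms:
#' * `zz` and `default`: `(pi - x_i)(pi - x_j)` (the product form
#'   `prod(pi - x_j)` of the default map coincides with the zz form on a
#'   pair)
#' * `k8`: `pi * x_i * x_j`
#' * `k9`: `(pi/2) (1 - x_i)(1 - x_j)`
#' * `k10`: `exp(|x_i - x_j|^2 / (8 / ln(pi)))`
#' * `k11`: `pi / (3 cos(x_i) cos(x_j))` — singular where the cosine product
#'   vanishes; inputs must be rescaled into a bounded interval first, and
#'   the function refuses rather than clamps
#' * `k12`: `pi * cos(x_i) * cos(x_j)`
#'
#' @param encoding Encoding name.
#' @param x_i,x_j Feature values (finite, vectorized).
#' @return Phase value(s).
#' @export
pair_phase <- function(encoding, x_i, x_j) {
  encoding <- match.arg(encoding, ENCODINGS)
  if (!all(is.finite(x_i)) || !all(is.finite(x_j))) {
    stop("non-finite input", call. = FALSE)
  }
  switch(
    encoding,
    zz = ,
    default = (pi - x_i) * (pi - x_j),
    k8 = pi * x_i * x_j,
    k9 = (pi / 2) * (1 - x_i) * (1 - x_j),
    k10 = exp(abs(x_i - x_j)^2 / (8 / log(pi))),
    k11 = {
      cc <- cos(x_i) * cos(x_j)
      if (any(abs(cc) < 1e-12)) {
        stop("k11 encoding singular: cos(x_i)*cos(x_j) ~ 0; rescale inputs ",
             "into a bounded interval away from odd multiples of pi/2",
             call. = FALSE)
      }
      pi / (3 * cc)
    },
    k12 = pi * cos(x_i) * cos(x_j)
  )
}

#' Diagonal of the phase-gate generator
#'
#' For input vector `x` and a feature-map spec, returns the 2^n real phases
#' `theta_b = sum_i phi_i(x) (-1)^{b_i} + sum_{(i,j)} phi_ij(x)
#' (-1)^{b_i + b_j}` — the diagonal of the Hermitian generator of the phase
#' gate, under the spec's bit-ordering convention. The phase gate multiplies
#' amplitude `b` by `exp(i * theta_b)`.
#'
#' @param x Numeric vector of length `n_qubits`.
#' @param spec A [feature_map_spec()].
#' @return Numeric vector of length `2^n_qubits`.
#' @export
phase_table <- function(x, spec) {
  stopifnot(inherits(spec, "feature_map_spec"))
  n <- spec$n_qubits
  if (length(x) != n) {
    stop(sprintf("input length %d does not match n_qubits = %d",
                 length(x), n), call. = FALSE)
  }
  S <- sign_matrix(n)                       # 2^n x n of (-1)^{b_i}
  theta <- as.numeric(S %*% singleton_phase(x))
  if (nrow(spec$pairs) > 0) {
    i <- spec$pairs[, 1]; j <- spec$pairs[, 2]
    phi_ij <- pair_phase(spec$encoding, x[i], x[j])
    theta <- theta + as.numeric((S[, i, drop = FALSE] *
                                   S[, j, drop = FALSE]) %*% phi_ij)
  }
  theta
}

# (-1)^{bit i of b} for b = 0 .. 2^n - 1 (qubit 0 = least significant bit).
sign_matrix <- function(n) {
  b <- 0:(2^n - 1)
  vapply(seq_len(n), function(i) 1 - 2 * bitwAnd(b %/% 2^(i - 1), 1L),
         numeric(2^n))
}

#' Fast Walsh-Hadamard transform
#'
#' Applies the n-fold tensor Hadamard `H^(x)n` to an amplitude vector in
#' O(n 2^n) via the in-place butterfly, including the `2^(-n/2)`
#' normalization, so the operation is unitary (self-inverse).
#'
#' @param amplitudes Complex (or numeric) vector of power-of-two length.
#' @return Transformed amplitude vector.
#' @export
walsh_hadamard <- function(amplitudes) {
  m <- length(amplitudes)
  n <- as.integer(round(log2(m)))
  if (m < 1 || 2^n != m) {
    stop("amplitude length must be a power of 2", call. = FALSE)
  }
  a <- amplitudes
  b <- 0:(m - 1)
  h <- 1L
  while (h < m) {
    idx <- b[bitwAnd(b, h) == 0L]
    lo <- idx + 1L
    hi <- idx + h + 1L
    x <- a[lo]; y <- a[hi]
    a[lo] <- x + y
    a[hi] <- x - y
    h <- h * 2L
  }
  a / sqrt(m)
}

#' Feature-map statevector
#'
#' Prepares `|psi(x)> = (D_Phi(x) H^(x)n)^reps |0^n>`, where `D_Phi(x)`
#' multiplies amplitude `b` by `exp(i * phase_table(x)[b])`. With the
#' default `reps = 2` this is the standard second-order evolution
#' `U_Phi H^(x)n U_Phi H^(x)n |0^n>`.
#'
#' @param x Numeric vector of length `n_qubits`.
#' @param spec A [feature_map_spec()].
#' @return A `statevector`: list with complex `amplitudes` (unit norm) and
#'   `n_qubits`.
#' @export
feature_state <- function(x, spec) {
  theta <- phase_table(x, spec)
  phase <- exp(1i * theta)
  amp <- c(1 + 0i, rep(0 + 0i, 2^spec$n_qubits - 1))
  for (r in seq_len(spec$reps)) {
    amp <- phase * walsh_hadamard(amp)
  }
  new_statevector(amp, spec$n_qubits)
}

new_statevector <- function(amplitudes, n_qubits) {
  structure(list(amplitudes = amplitudes, n_qubits = n_qubits),
            class = "statevector")
}

#' @export
print.statevector <- function(x, ...) {
  cat(sprintf("Statevector on %d qubit(s), norm %.12f\n", x$n_qubits,
              sqrt(sum(Mod(x$amplitudes)^2))))
  invisible(x)
}

#' Exact fidelity between two statevectors
#'
#' `|<a|b>|^2`, the transition amplitude defining the quantum kernel entry.
#'
#' @param a,b `statevector`s (or complex amplitude vectors) of equal
#'   dimension.
#' @return Fidelity in `[0, 1]`.
#' @export
kernel_entry_exact <- function(a, b) {
  av <- if (inherits(a, "statevector")) a$amplitudes else a
  bv <- if (inherits(b, "statevector")) b$amplitudes else b
  if (length(av) != length(bv)) {
    stop("statevector dimensions differ", call. = FALSE)
  }
  min(1, Mod(sum(Conj(av) * bv))^2)
}

# All feature states of a dataset as a 2^n x m complex matrix, honoring a
# memory budget (bytes) on the statevector cache.
state_matrix <- function(X, spec, memory_budget = 2 * 1024^3) {
  m <- nrow(X)
  need <- m * 2^spec$n_qubits * 16
  if (need > memory_budget) {
    stop(sprintf(
      "statevector cache needs %.2f GiB but the budget is %.2f GiB; ",
      need / 1024^3, memory_budget / 1024^3),
      "reduce qubits/samples or raise `memory_budget`", call. = FALSE)
  }
  vapply(seq_len(m),
         function(i) feature_state(as.numeric(X[i, ]), spec)$amplitudes,
         complex(2^spec$n_qubits))
}

#' Fidelity kernel (Gram) matrix
#'
#' Computes the quantum kernel `K_ij = |<psi(x_j)|psi(x_i)>|^2` for every
#' row pair of `X` (or between `X` and `Z` for a rectangular test-vs-train
#' block). In `"exact"` mode the statevectors are computed once and the Gram
#' assembled from pairwise inner products (upper triangle mirrored, unit
#' diagonal). In `"shots"` mode each off-diagonal entry is replaced by the
#' relative frequency `m/shots` of the all-zero outcome, `m ~
#' Binomial(shots, exact entry)`, emulating quantum kernel estimation with a
#' finite shot budget; the diagonal stays fixed at 1.
#'
#' @param X Numeric matrix; column count must equal `n_qubits`.
#' @param spec A [feature_map_spec()].
#' @param Z Optional second matrix for a rectangular block (rows of the
#'   result index `X`, columns index `Z`).
#' @param mode `"exact"` or `"shots"`.
#' @param shots Shot count per entry in shots mode (default 1024).
#' @param seed Seed for shot sampling.
#' @param memory_budget Statevector-cache budget in bytes (default 2 GiB).
#' @return A `kernel_matrix`: list with `values`, `mode`, `shots`, `seed`
#'   and the generating `spec`.
#' @export
kernel_matrix <- function(X, spec, Z = NULL, mode = c("exact", "shots"),
                          shots = 1024L, seed = 1L,
                          memory_budget = 2 * 1024^3) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (ncol(X) != spec$n_qubits) {
    stop(sprintf("X has %d feature(s) but the feature map has %d qubit(s)",
                 ncol(X), spec$n_qubits), call. = FALSE)
  }
  square <- is.null(Z)
  Psi <- state_matrix(X, spec, memory_budget)
  if (square) {
    G <- Conj(t(Psi)) %*% Psi
    K <- Mod(G)^2
    K <- (K + t(K)) / 2
    K <- pmin(K, 1)
    diag(K) <- 1
  } else {
    Z <- as.matrix(Z)
    if (ncol(Z) != spec$n_qubits) {
      stop("Z feature count does not match n_qubits", call. = FALSE)
    }
    Phi <- state_matrix(Z, spec, memory_budget)
    K <- pmin(Mod(Conj(t(Psi)) %*% Phi)^2, 1)
  }
  if (mode == "shots") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    if (square) {
      ut <- upper.tri(K)
      K[ut] <- rbinom(sum(ut), shots, K[ut]) / shots
      K[lower.tri(K)] <- t(K)[lower.tri(K)]
      diag(K) <- 1
    } else {
      K[] <- rbinom(length(K), shots, as.numeric(K)) / shots
    }
  }
  new_kernel_matrix(K, mode = mode,
                    shots = if (mode == "shots") as.integer(shots) else NA_integer_,
                    seed = if (mode == "shots") as.integer(seed) else NA_integer_,
                    spec = spec)
}

new_kernel_matrix <- function(values, mode, shots = NA_integer_,
                              seed = NA_integer_, spec = NULL) {
  structure(list(values = values, mode = mode, shots = shots, seed = seed,
                 spec = spec),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("Kernel matrix %d x %d (%s mode%s)\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (!is.na(x$shots)) paste0(", ", x$shots, " shots") else ""))
  invisible(x)
}

#' @export
as.matrix.kernel_matrix <- function(x, ...) x$values

kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
}

#' Project a kernel matrix onto the PSD cone
#'
#' Repairs indefiniteness (e.g. from shot noise) by clipping negative
#' eigenvalues to zero and restoring the unit diagonal. Matrices already PSD
#' within tolerance pass through unchanged.
#'
#' @param K A `kernel_matrix` or symmetric numeric matrix.
#' @param tol Eigenvalue tolerance below which no repair is performed
#'   (default 1e-10).
#' @return Same type as the input, PSD with unit diagonal.
#' @export
psd_projection <- function(K, tol = 1e-10) {
  V <- kernel_values(K)
  if (max(abs(V - t(V))) > 1e-8) {
    stop("kernel matrix is not symmetric", call. = FALSE)
  }
  eg <- eigen(V, symmetric = TRUE)
  if (min(eg$values) >= -tol) {
    return(K)
  }
  lam <- pmax(eg$values, 0)
  W <- eg$vectors %*% (lam * t(eg$vectors))
  d <- diag(W)
  d[d <= 0] <- 1
  W <- W / sqrt(outer(d, d))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  if (inherits(K, "kernel_matrix")) {
    K$values <- W
    K
  } else {
    W
  }
}
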