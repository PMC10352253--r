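# Independent dense-matrix oracles for the statevector engine.
#
# These build the feature-map unitary explicitly from kronecker products and
# an eigen-decomposition matrix exponential, sharing no code with the fast
# phase-table / Walsh-Hadamard path they check.

PAULI_Z <- diag(c(1, -1))

# Operator acting as M on qubit `q` (0-based, qubit 0 = least significant
# bit) and identity elsewhere: kron chain runs from qubit n-1 down to 0.
dense_single <- function(M, q, n) {
  mats <- rev(lapply(seq_len(n) - 1L, function(i) {
    if (i == q) M else diag(2)
  }))
  Reduce(kronecker, mats)
}

dense_pair_zz <- function(qi, qj, n) {
  mats <- rev(lapply(seq_len(n) - 1L, function(i) {
    if (i %in% c(qi, qj)) PAULI_Z else diag(2)
  }))
  Reduce(kronecker, mats)
}

# exp(i G) for a real symmetric generator G
dense_expi <- function(G) {
  eg <- eigen(G, symmetric = TRUE)
  eg$vectors %*% diag(exp(1i * eg$values), nrow(G)) %*% t(eg$vectors)
}

dense_hadamard_n <- function(n) {
  H1 <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  Reduce(kronecker, rep(list(H1), n))
}

# Dense phase-gate unitary for one input vector under a feature-map spec.
dense_phase_gate <- function(x, spec) {
  n <- spec$n_qubits
  G <- matrix(0, 2^n, 2^n)
  for (i in seq_len(n)) {
    G <- G + singleton_phase(x[i]) * dense_single(PAULI_Z, i - 1L, n)
  }
  if (nrow(spec$pairs) > 0) {
    for (r in seq_len(nrow(spec$pairs))) {
      i <- spec$pairs[r, 1]; j <- spec$pairs[r, 2]
      G <- G + pair_phase(spec$encoding, x[i], x[j]) *
        dense_pair_zz(i - 1L, j - 1L, n)
    }
  }
  dense_expi(G)
}

# Dense statevector |psi(x)> = (U_Phi H^n)^reps |0^n>
dense_feature_state <- function(x, spec) {
  n <- spec$n_qubits
  U <- dense_phase_gate(x, spec)
  Hn <- dense_hadamard_n(n)
  psi <- c(1, rep(0, 2^n - 1))
  for (r in seq_len(spec$reps)) psi <- U %*% (Hn %*% psi)
  as.complex(psi)
}

dense_fidelity <- function(x, z, spec) {
  a <- dense_feature_state(x, spec)
  b <- dense_feature_state(z, spec)
  Mod(sum(Conj(a) * b))^2
}

# Dense aligned state: (U_Phi H^n)^(reps-1) U_Phi U_lambda |0^n>
dense_qka_state <- function(x, spec, lambda) {
  n <- spec$n_qubits
  lambda <- rep_len(lambda, n)
  Ry <- function(th) matrix(c(cos(th / 2), sin(th / 2),
                              -sin(th / 2), cos(th / 2)), 2, 2)
  Ul <- Reduce(kronecker, rev(lapply(seq_len(n), function(q) Ry(lambda[q]))))
  U <- dense_phase_gate(x, spec)
  Hn <- dense_hadamard_n(n)
  psi <- U %*% (Ul %*% c(1, rep(0, 2^n - 1)))
  if (spec$reps > 1) {
    for (r in seq_len(spec$reps - 1L)) psi <- U %*% (Hn %*% psi)
  }
  as.complex(psi)
}

# Brute-force soft-margin SVM dual objective on a dense alpha grid,
# independent of any QP solver. Binary labels y in {-1, +1}; the equality
# constraint sum(alpha * y) = 0 is solved for the last coefficient.
brute_force_dual <- function(K, y, C, steps = 41L) {
  n <- length(y)
  stopifnot(n >= 2)
  Q <- outer(y, y) * K
  obj <- function(a) sum(a) - 0.5 * as.numeric(t(a) %*% Q %*% a)
  grid <- seq(0, C, length.out = steps)
  free <- as.matrix(expand.grid(rep(list(grid), n - 1L)))
  best <- -Inf
  for (r in seq_len(nrow(free))) {
    a_free <- free[r, ]
    a_last <- -sum(a_free * y[-n]) / y[n]
    if (a_last < -1e-12 || a_last > C + 1e-12) next
    a <- c(a_free, min(max(a_last, 0), C))
    val <- obj(a)
    if (val > best) best <- val
  }
  best
}

# Small deterministic fixtures -------------------------------------------

make_clean_table <- function(n = 120, seed = 1, ...) {
  generate_dataset(synthetic_spec(n_neurons = n, seed = seed, ...))
}

# Block-perfect kernel: within-class 1, cross-class 0.
block_kernel <- function(y) {
  outer(y, y, function(a, b) as.numeric(a == b))
}
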