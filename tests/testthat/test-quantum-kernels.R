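test_that("feature map spec validates its fields", {
  sp <- feature_map_spec(3)
  expect_equal(nrow(sp$pairs), 3)          # full entanglement on 3 qubits
  expect_equal(sp$reps, 2L)
  expect_error(feature_map_spec(0), "n_qubits")
  expect_error(feature_map_spec(2, reps = 0), "reps")
  expect_error(feature_map_spec(2, entanglement = rbind(c(2, 1))), "pairs")
  expect_error(feature_map_spec(2, entanglement = rbind(c(1, 3))), "pairs")
})

test_that("encoding functions match their printed formulas", {
  expect_equal(singleton_phase(1.7), 1.7)
  expect_equal(singleton_phase(pi), pi)
  expect_error(singleton_phase(Inf), "non-finite")

  expect_equal(pair_phase("zz", pi, 0.3), 0)          # (pi - pi) factor
  expect_equal(pair_phase("zz", 0.5, 1), (pi - 0.5) * (pi - 1))
  expect_equal(pair_phase("default", 0.5, 1), pair_phase("zz", 0.5, 1))
  expect_equal(pair_phase("k8", 0.5, 2), pi)
  expect_equal(pair_phase("k9", 0, 0), pi / 2)
  expect_equal(pair_phase("k10", 0.7, 0.7), 1)        # exp(0)
  expect_equal(pair_phase("k10", 0, 2), exp(4 * log(pi) / 8))
  expect_equal(pair_phase("k11", 0, 0), pi / 3)
  expect_equal(pair_phase("k12", 0, 0), pi)
  expect_error(pair_phase("k11", pi / 2, 0.1), "singular")
})

test_that("phase table matches the sign-weighted sums and the dense generator diagonal", {
  # n = 1: eigenvalues of Z are +1 (|0>) and -1 (|1>)
  sp1 <- feature_map_spec(1)
  expect_equal(phase_table(0.8, sp1), c(0.8, -0.8))

  # zero input under k8: all phases vanish
  sp <- feature_map_spec(3, encoding = "k8")
  expect_equal(phase_table(c(0, 0, 0), sp), rep(0, 8))

  # dense-oracle diagonal, n = 2 zz
  sp2 <- feature_map_spec(2, encoding = "zz")
  x <- c(0.5, 1.0)
  G <- singleton_phase(x[1]) * dense_single(PAULI_Z, 0, 2) +
    singleton_phase(x[2]) * dense_single(PAULI_Z, 1, 2) +
    pair_phase("zz", x[1], x[2]) * dense_pair_zz(0, 1, 2)
  expect_equal(phase_table(x, sp2), diag(G))
  expect_error(phase_table(c(1, 2, 3), sp2), "n_qubits")
})

test_that("walsh-hadamard transform is the unitary tensor Hadamard", {
  expect_equal(walsh_hadamard(c(1, 0)), c(1, 1) / sqrt(2))
  # involution
  set.seed(1)
  a <- complex(real = rnorm(8), imaginary = rnorm(8))
  expect_equal(walsh_hadamard(walsh_hadamard(a)), a, tolerance = 1e-12)
  # dense 8x8 oracle
  expect_equal(walsh_hadamard(a), as.complex(dense_hadamard_n(3) %*% a),
               tolerance = 1e-12)
  expect_error(walsh_hadamard(rep(1, 3)), "power of 2")
})

test_that("feature states match the dense construction and stay normalized", {
  sp <- feature_map_spec(2, encoding = "zz")
  st <- feature_state(c(0.5, 1.0), sp)
  expect_equal(st$amplitudes, dense_feature_state(c(0.5, 1.0), sp),
               tolerance = 1e-12)

  # vanishing phases at x = 0 under k8: (D H)(D H)|00> = |00>
  spk8 <- feature_map_spec(2, encoding = "k8")
  st0 <- feature_state(c(0, 0), spk8)
  expect_equal(st0$amplitudes, c(1 + 0i, 0, 0, 0), tolerance = 1e-12)

  set.seed(2)
  for (n in 1:4) {
    st <- feature_state(runif(n, 0, 2 * pi), feature_map_spec(n))
    expect_equal(sum(Mod(st$amplitudes)^2), 1, tolerance = 1e-12)
  }
})

test_that("exact kernel entries are fidelities", {
  e00 <- c(1 + 0i, 0, 0, 0); e01 <- c(0, 1 + 0i, 0, 0)
  expect_equal(kernel_entry_exact(e00, e00), 1)
  expect_equal(kernel_entry_exact(e00, e01), 0)
  expect_error(kernel_entry_exact(e00, c(1 + 0i, 0)), "dimensions")

  sp <- feature_map_spec(2, encoding = "zz")
  x <- c(0.4, 1.2); z <- c(2.0, 0.7)
  expect_equal(
    kernel_entry_exact(feature_state(x, sp), feature_state(z, sp)),
    dense_fidelity(x, z, sp), tolerance = 1e-10)
})

test_that("engine matches the dense oracle across encodings and qubit counts", {
  set.seed(7)
  for (n in 1:3) {
    sp_base <- feature_map_spec(n)
    for (enc in qkmorph:::ENCODINGS) {
      sp <- feature_map_spec(n, encoding = enc)
      for (r in 1:5) {
        x <- runif(n, 0, 2 * pi); z <- runif(n, 0, 2 * pi)
        got <- kernel_entry_exact(feature_state(x, sp), feature_state(z, sp))
        expect_equal(got, dense_fidelity(x, z, sp), tolerance = 1e-10)
      }
    }
  }
})

test_that("exact Gram matrices satisfy the kernel invariants", {
  set.seed(3)
  X <- matrix(runif(40 * 4, 0, 2), 40, 4)
  K <- kernel_matrix(X, feature_map_spec(4, encoding = "zz"))
  V <- K$values
  expect_equal(diag(V), rep(1, 40), tolerance = 1e-10)
  expect_lt(max(abs(V - t(V))), 1e-12)
  expect_true(all(V >= 0 & V <= 1))
  expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
            -1e-9)

  # duplicated rows give unit entries
  X2 <- rbind(X[1, ], X)
  V2 <- kernel_matrix(X2, feature_map_spec(4, encoding = "zz"))$values
  expect_equal(V2[1, 2], 1, tolerance = 1e-12)
})

test_that("row permutations conjugate the Gram matrix", {
  set.seed(4)
  X <- matrix(runif(10 * 3, 0, 2), 10, 3)
  sp <- feature_map_spec(3, encoding = "k9")
  V <- kernel_matrix(X, sp)$values
  perm <- sample(10)
  Vp <- kernel_matrix(X[perm, ], sp)$values
  expect_equal(Vp, V[perm, perm], tolerance = 1e-12)
})

test_that("rectangular blocks agree with entrywise fidelities", {
  set.seed(5)
  sp <- feature_map_spec(2, encoding = "zz")
  X <- matrix(runif(6, 0, 2), 3, 2)
  Z <- matrix(runif(4, 0, 2), 2, 2)
  B <- kernel_matrix(X, sp, Z = Z)$values
  for (i in 1:3) for (j in 1:2) {
    expect_equal(B[i, j],
                 kernel_entry_exact(feature_state(X[i, ], sp),
                                    feature_state(Z[j, ], sp)),
                 tolerance = 1e-12)
  }
})

test_that("shots mode is a seeded binomial draw around the exact entry", {
  sp <- feature_map_spec(2, encoding = "zz")
  X <- matrix(c(0.2, 1.4, 1.1, 0.3), 2, 2)
  p <- kernel_matrix(X, sp)$values[1, 2]
  Ks <- kernel_matrix(X, sp, mode = "shots", shots = 1024, seed = 9)
  expect_equal(Ks$values[1, 2] * 1024, round(Ks$values[1, 2] * 1024))
  expect_equal(diag(Ks$values), c(1, 1))
  expect_identical(Ks$values,
                   kernel_matrix(X, sp, mode = "shots", shots = 1024,
                                 seed = 9)$values)
  # unbiasedness over repeats
  reps <- vapply(1:400, function(s) {
    kernel_matrix(X, sp, mode = "shots", shots = 1024, seed = s)$values[1, 2]
  }, numeric(1))
  se <- sqrt(p * (1 - p) / 1024) / sqrt(400)
  expect_lt(abs(mean(reps) - p), 4 * se)
})

test_that("input validation and memory budget errors are informative", {
  sp <- feature_map_spec(3)
  expect_error(kernel_matrix(matrix(1, 2, 2), sp), "qubit")
  expect_error(kernel_matrix(matrix(1, 4, 3), sp, memory_budget = 10),
               "budget")
})

test_that("psd projection clips negative eigenvalues and restores the diagonal", {
  V <- matrix(c(1, 1.2, 1.2, 1), 2, 2)     # eigenvalues 2.2, -0.2
  W <- psd_projection(V)
  expect_gte(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  expect_equal(diag(W), c(1, 1))

  set.seed(6)
  X <- matrix(runif(12, 0, 2), 6, 2)
  K <- kernel_matrix(X, feature_map_spec(2))
  expect_identical(psd_projection(K)$values, K$values)   # PSD passthrough
  expect_error(psd_projection(matrix(c(1, 2, 3, 1), 2, 2)), "symmetric")
})
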