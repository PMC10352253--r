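#' Quantum kernel alignment configuration
#'
#' Settings for training a parametrized fiducial state by simultaneous
#' perturbation stochastic approximation (SPSA) against the SVM dual
#' objective (SVCLoss). Defaults follow the study protocol: at most 10
#' iterations, learning rate 0.05 and perturbation magnitude 0.05, with
#' constant gain sequences so the two printed values are honored exactly
#' (`decay = TRUE` switches to the conventional decaying gains).
#'
#' @param maxiter Maximum SPSA iterations (>= 1, default 10).
#' @param learning_rate SPSA step size `a` (default 0.05).
#' @param perturbation SPSA finite-difference magnitude `c` (default 0.05).
#' @param C SVM soft-margin regularization for the loss (default 1).
#' @param decay Use decaying gain sequences `a_k = a/k^0.602`,
#'   `c_k = c/k^0.101` instead of constants (default `FALSE`).
#' @param seed Seed for the Rademacher perturbation draws.
#' @return A `qka_config`.
#' @export
qka_config <- function(maxiter = 10L, learning_rate = 0.05,
                       perturbation = 0.05, C = 1, decay = FALSE,
                       seed = 1L) {
  if (!is.numeric(maxiter) || maxiter < 1 || maxiter != round(maxiter)) {
    stop("maxiter must be an integer >= 1", call. = FALSE)
  }
  if (learning_rate <= 0 || perturbation <= 0) {
    stop("learning_rate and perturbation must be positive", call. = FALSE)
  }
  structure(
    list(maxiter = as.integer(maxiter), learning_rate = learning_rate,
         perturbation = perturbation, C = C, decay = isTRUE(decay),
         seed = as.integer(seed)),
    class = "qka_config"
  )
}

#' Fiducial state of a Y-rotation layer
#'
#' Applies one layer of single-qubit rotations `R_y(lambda_q)` to `|0^n>`:
#' each qubit is prepared in `(cos(lambda/2), sin(lambda/2))`, and the full
#' state is their tensor product (qubit 0 least significant). A length-1
#' `lambda` is broadcast to all qubits. Amplitudes are real with unit norm.
#'
#' @param lambda Rotation angle(s): length 1 or `n_qubits`.
#' @param n_qubits Number of qubits.
#' @return A `statevector`.
#' @export
fiducial_state <- function(lambda, n_qubits) {
  if (!length(lambda) %in% c(1L, n_qubits)) {
    stop("lambda must have length 1 or n_qubits", call. = FALSE)
  }
  if (!all(is.finite(lambda))) stop("lambda must be finite", call. = FALSE)
  lambda <- rep_len(lambda, n_qubits)
  amp <- 1
  for (q in seq_len(n_qubits)) {
    # kron(next qubit, existing): qubit q occupies bit q-1 (LSB first)
    amp <- kronecker(c(cos(lambda[q] / 2), sin(lambda[q] / 2)), amp)
  }
  new_statevector(as.complex(amp), n_qubits)
}

# Aligned feature state: the fiducial layer U_lambda replaces the first
# Hadamard layer of the encoding block, so for reps = 2:
#   |psi_lambda(x)> = D_Phi(x) H^(x)n D_Phi(x) U_lambda |0^n>
qka_feature_state <- function(x, spec, lambda) {
  theta <- phase_table(x, spec)
  phase <- exp(1i * theta)
  amp <- fiducial_state(lambda, spec$n_qubits)$amplitudes
  amp <- phase * amp
  if (spec$reps > 1) {
    for (r in seq_len(spec$reps - 1L)) {
      amp <- phase * walsh_hadamard(amp)
    }
  }
  new_statevector(amp, spec$n_qubits)
}

#' Aligned (fiducial-state) kernel matrix
#'
#' Fidelity kernel `K_lambda(x, x~) = |<psi_lambda(x)|psi_lambda(x~)>|^2`
#' in which the data-encoding block acts on the fiducial state
#' `U_lambda|0^n>` (a layer of Y-rotations) instead of the Hadamard-prepared
#' plus state: the fiducial layer replaces the first Hadamard layer of the
#' feature map. At `lambda = pi/2` every qubit of the fiducial is an equal
#' superposition with real amplitudes, the same state the Hadamard layer
#' prepares, so the aligned kernel coincides with [kernel_matrix()]; this is
#' the documented base case (`lambda = 0` starts from `|0^n>` itself and
#' yields a different, valid kernel).
#'
#' @param X Numeric matrix (columns = qubits).
#' @param spec A [feature_map_spec()].
#' @param lambda Fiducial angles (length 1 or `n_qubits`).
#' @param Z Optional second matrix for a rectangular block.
#' @return A `kernel_matrix` (exact mode).
#' @export
qka_kernel_matrix <- function(X, spec, lambda, Z = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != spec$n_qubits) {
    stop("X feature count does not match n_qubits", call. = FALSE)
  }
  states <- function(M) {
    vapply(seq_len(nrow(M)),
           function(i) qka_feature_state(as.numeric(M[i, ]), spec,
                                         lambda)$amplitudes,
           complex(2^spec$n_qubits))
  }
  Psi <- states(X)
  if (is.null(Z)) {
    K <- Mod(Conj(t(Psi)) %*% Psi)^2
    K <- pmin((K + t(K)) / 2, 1)
    diag(K) <- 1
  } else {
    K <- pmin(Mod(Conj(t(Psi)) %*% states(as.matrix(Z)))^2, 1)
  }
  out <- new_kernel_matrix(K, mode = "exact", spec = spec)
  out$lambda <- lambda
  out
}

#' SVM dual objective (SVCLoss) of a kernel on binary labels
#'
#' Solves the soft-margin SVM dual on a precomputed kernel with binary
#' labels and returns the attained dual objective
#' `sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij` — the quantity
#' quantum kernel alignment minimizes over the fiducial parameters
#' (minimizing it maximizes the margin attainable on the aligned kernel).
#' The quadratic program is solved by the interior-point solver
#' \code{kernlab::ipop}; the loss is assembled here from the optimal dual
#' coefficients.
#'
#' @param K A `kernel_matrix` or symmetric numeric matrix (PSD-repaired).
#' @param y Binary labels: two distinct values (±1 or any two levels).
#' @param C Soft-margin regularization (default 1).
#' @return The dual objective value (non-negative).
#' @export
svc_loss <- function(K, y, C = 1) {
  V <- kernel_values(K)
  yf <- factor(y)
  if (nlevels(yf) != 2L) {
    stop("svc_loss requires exactly two classes", call. = FALSE)
  }
  yn <- ifelse(as.integer(yf) == 1L, 1, -1)
  n <- length(yn)
  Q <- outer(yn, yn) * V
  sol <- kernlab::ipop(c = rep(-1, n), H = Q + diag(1e-10, n),
                       A = matrix(yn, 1), b = 0,
                       l = rep(0, n), u = rep(C, n), r = 0,
                       maxiter = 100)
  a <- kernlab::primal(sol)
  sum(a) - 0.5 * as.numeric(t(a) %*% Q %*% a)
}

# Binary C-SVC on a precomputed kernel via kernlab, returning dual data.
fit_binary_ksvm <- function(V, yf, C) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(V), yf, type = "C-svc",
                     C = C, scaled = FALSE)
  list(model = m,
       alpha = unlist(kernlab::alpha(m)),
       coef = unlist(kernlab::coef(m)),
       sv_index = unlist(kernlab::alphaindex(m)),
       b = kernlab::b(m))
}

#' SPSA minimization
#'
#' Simultaneous perturbation stochastic approximation with two objective
#' evaluations per iteration: draw a Rademacher direction `Delta`, estimate
#' the gradient as `[f(l + c Delta) - f(l - c Delta)] / (2c)` elementwise
#' divided by `Delta`, and step `l <- l - a * ghat`. Gains are constant
#' (`a_k = a`, `c_k = c`) unless the config requests decay. Returns the best
#' *evaluated* point (over the initial point, all perturbed points, and the
#' final iterate) and the full evaluation trace.
#'
#' @param objective Function of the parameter vector returning a scalar.
#' @param lambda0 Initial parameter vector.
#' @param config A [qka_config()].
#' @return A list: `lambda` (best evaluated), `value` (its objective),
#'   `trace` (data frame with `eval`, `iteration`, `kind`, `objective`, and
#'   one `lambda*` column per parameter).
#' @export
spsa_minimize <- function(objective, lambda0, config = qka_config()) {
  stopifnot(inherits(config, "qka_config"))
  d <- length(lambda0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  evals <- list()
  record <- function(iter, kind, lam, val) {
    evals[[length(evals) + 1L]] <<- c(
      list(iteration = iter, kind = kind, objective = val),
      as.list(setNames(lam, sprintf("lambda%d", seq_len(d))))
    )
    if (!is.finite(val)) {
      stop("objective returned a non-finite value; trace has ",
           length(evals), " evaluations", call. = FALSE)
    }
    val
  }

  lam <- as.numeric(lambda0)
  record(0L, "initial", lam, objective(lam))
  for (k in seq_len(config$maxiter)) {
    a_k <- if (config$decay) config$learning_rate / k^0.602 else
      config$learning_rate
    c_k <- if (config$decay) config$perturbation / k^0.101 else
      config$perturbation
    delta <- sample(c(-1, 1), d, replace = TRUE)
    fp <- record(k, "plus", lam + c_k * delta,
                 objective(lam + c_k * delta))
    fm <- record(k, "minus", lam - c_k * delta,
                 objective(lam - c_k * delta))
    ghat <- (fp - fm) / (2 * c_k) / delta
    lam <- lam - a_k * ghat
  }
  record(config$maxiter, "final", lam, objective(lam))

  trace <- do.call(rbind, lapply(evals, function(e) {
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
  trace <- cbind(eval = seq_len(nrow(trace)), trace)
  best <- which.min(trace$objective)
  list(
    lambda = as.numeric(trace[best, sprintf("lambda%d", seq_len(d))]),
    value = trace$objective[best],
    trace = trace
  )
}

#' Train a quantum kernel by alignment
#'
#' Minimizes the summed one-vs-one SVCLoss over the fiducial parameters with
#' SPSA: for a candidate `lambda`, the aligned Gram is computed once, the
#' binary dual objective is evaluated on every class pair's sub-Gram, and
#' the sum is the alignment objective. Returns the best `lambda`, the
#' aligned kernel at that `lambda`, and the optimization trace.
#'
#' @param X Preprocessed numeric matrix (columns = qubits).
#' @param y Integer or factor class labels (>= 2 classes).
#' @param spec A [feature_map_spec()].
#' @param config A [qka_config()].
#' @param lambda0 Initial fiducial angles (default `pi/2` per qubit, the
#'   Hadamard-equivalent base case).
#' @return A list: `lambda`, `kernel` (a `kernel_matrix`), `value`, `trace`.
#' @export
train_quantum_kernel <- function(X, y, spec, config = qka_config(),
                                 lambda0 = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y), method = "radix")
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  if (is.null(lambda0)) lambda0 <- rep(pi / 2, spec$n_qubits)
  pairs <- utils::combn(classes, 2, simplify = FALSE)

  objective <- function(lam) {
    K <- psd_projection(qka_kernel_matrix(X, spec, lam))$values
    total <- 0
    for (pr in pairs) {
      sel <- y %in% pr
      total <- total + svc_loss(K[sel, sel, drop = FALSE], y[sel],
                                C = config$C)
    }
    total
  }

  res <- spsa_minimize(objective, lambda0, config)
  list(
    lambda = res$lambda,
    kernel = qka_kernel_matrix(X, spec, res$lambda),
    value = res$value,
    trace = res$trace
  )
}

#' Export a QKA training trace as CSV
#'
#' Writes `eval,iteration,kind,objective,lambda1,...` for reproducibility.
#'
#' @param trace The `trace` component of [spsa_minimize()] /
#'   [train_quantum_kernel()].
#' @param path Output CSV path.
#' @export
write_qka_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
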