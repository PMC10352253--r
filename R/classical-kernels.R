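#' Classical SVM kernel specification
#'
#' The four classical kernels, evaluated as precomputed Gram matrices so
#' that classical and quantum kernels flow through the identical SVM code
#' path:
#' * `linear`: `x_i . x_j`
#' * `rbf`: `exp(-||x_i - x_j||^2 / (2 sigma^2))`
#' * `poly`: `(x_i . x_j + a)^b`
#' * `sigmoid`: `tanh(a x_i . x_j - b)`
#'
#' Defaults where unspecified by the protocol: `sigma` such that
#' `1/(2 sigma^2) = 1/(n_features * var(X))` (derived at Gram time when left
#' `NULL`); `poly` offset `a = 1`, degree `b = 3`; `sigmoid` slope
#' `a = 1/n_features`, offset `b = 0`.
#'
#' @param kernel One of `"linear"`, `"rbf"`, `"poly"`, `"sigmoid"`.
#' @param sigma RBF width (> 0), or `NULL` to derive from the data.
#' @param a,b Offset/degree (poly) or slope/offset (sigmoid).
#' @return A `classical_kernel_spec`.
#' @export
classical_kernel_spec <- function(kernel = c("linear", "rbf", "poly",
                                             "sigmoid"),
                                  sigma = NULL, a = NULL, b = NULL) {
  kernel <- match.arg(kernel)
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (kernel == "poly") {
    a <- a %||% 1
    b <- b %||% 3
    if (b < 1 || b != round(b)) {
      stop("poly degree b must be a positive integer", call. = FALSE)
    }
  }
  if (kernel == "sigmoid") {
    b <- b %||% 0
  }
  structure(list(kernel = kernel, sigma = sigma, a = a, b = b),
            class = "classical_kernel_spec")
}

#' Classical kernel Gram matrix
#'
#' Entry `(i, j)` is the kernel of row `i` of `X` with row `j` of `Z`.
#' `Z = NULL` gives the square symmetric training Gram; otherwise the
#' rectangular test-vs-train block. Data-derived defaults (RBF `sigma`,
#' sigmoid slope) are resolved from `X` and recorded on the result so train
#' and test blocks use identical parameters when the returned spec is
#' passed back in.
#'
#' @param X Numeric matrix.
#' @param Z Optional second matrix (same feature count).
#' @param spec A [classical_kernel_spec()].
#' @return A `kernel_matrix` (exact mode) with the resolved spec attached.
#' @export
classical_gram <- function(X, Z = NULL, spec) {
  stopifnot(inherits(spec, "classical_kernel_spec"))
  X <- as.matrix(X)
  square <- is.null(Z)
  Z <- if (square) X else as.matrix(Z)
  if (ncol(X) != ncol(Z)) stop("feature counts differ", call. = FALSE)
  p <- ncol(X)

  K <- switch(
    spec$kernel,
    linear = X %*% t(Z),
    rbf = {
      if (is.null(spec$sigma)) {
        v <- mean(apply(X, 2, var))
        spec$sigma <- sqrt(max(p * v, .Machine$double.eps) / 2)
      }
      d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * X %*% t(Z)
      exp(-pmax(d2, 0) / (2 * spec$sigma^2))
    },
    poly = (X %*% t(Z) + spec$a)^spec$b,
    sigmoid = {
      if (is.null(spec$a)) spec$a <- 1 / p
      tanh(spec$a * (X %*% t(Z)) - spec$b)
    }
  )
  if (square) K <- (K + t(K)) / 2
  out <- new_kernel_matrix(unname(K), mode = "exact")
  out$classical_spec <- spec
  out
}
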