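#' Feature rescaling transforms
#'
#' Eleven rescaling methods are available, each fit on training data only and
#' then applied to any matrix with the same feature layout
#' (fit/transform separation):
#'
#' * `standard`: z = (x - mean) / sd (population sd, so training columns
#'   have exactly unit second moment about the mean)
#' * `minmax`: (x - min) / (max - min)
#' * `maxabs`: x / max(|x|)
#' * `robust`: (x - Q1) / (Q3 - Q1). The Q1 numerator is the method's
#'   definition here; `options$center = "median"` gives the conventional
#'   median-centered variant.
#' * `l2norm`: each row divided by its Euclidean norm (a row operation;
#'   nothing is fitted)
#' * `logistic`: 1 / (1 + exp(-x)) elementwise
#' * `lognormal`: Phi(ln(x) / sigma) for x >= 0 (`options$sigma`, default 1)
#' * `boxcox`: (x^lambda - 1) / lambda (log x at lambda = 0), lambda fitted
#'   per feature by maximum likelihood; requires strictly positive values
#' * `yeojohnson`: the four-branch power transform with per-feature
#'   maximum-likelihood lambda; defined for all reals
#' * `quantile_normal`: empirical CDF mapped through the normal quantile
#'   function mu + sigma * sqrt(2) * erfinv(2p - 1)
#' * `quantile_uniform`: empirical CDF mapped through the uniform quantile
#'   function a(1 - p) + b p
#'
#' Quantile methods store an empirical quantile table at `min(1000, n)`
#' uniformly spaced probabilities; probabilities of transformed points are
#' clamped to `[1/(2n), 1 - 1/(2n)]` so the normal map stays finite.
#' Constant features under methods that would divide by zero pass through
#' unchanged with a warning.
#'
#' @param X Numeric training matrix (rows = neurons, columns = features).
#' @param method One of the eleven method names above.
#' @param options Named list of method options (`center`, `sigma`, `mu`,
#'   `a`, `b`, `n_quantiles`).
#' @return `fit_rescaler()` returns a `rescaler_spec`; `apply_rescaler()`
#'   the transformed matrix.
#' @export
#' @examples
#' X <- matrix(rlnorm(200), 50, 4)
#' sp <- fit_rescaler(X, "standard")
#' Z <- apply_rescaler(sp, X)
#' round(colMeans(Z), 12)
fit_rescaler <- function(X, method, options = list()) {
  X <- as.matrix(X)
  method <- match.arg(method, RESCALER_METHODS)
  p <- ncol(X)
  params <- switch(
    method,
    standard = {
      # population (1/n) standard deviation, so a two-point feature {0, 2}
      # maps exactly to {-1, +1}
      m <- colMeans(X)
      s <- sqrt(colMeans(sweep(X, 2, m)^2))
      const <- s == 0
      if (any(const)) warning("constant feature(s) pass through unchanged: ",
                              paste(which(const), collapse = ", "))
      list(mean = m, sd = s, constant = const)
    },
    minmax = {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      const <- hi == lo
      if (any(const)) warning("constant feature(s) pass through unchanged: ",
                              paste(which(const), collapse = ", "))
      list(min = lo, max = hi, constant = const)
    },
    maxabs = {
      ma <- apply(abs(X), 2, max)
      const <- ma == 0
      if (any(const)) warning("all-zero feature(s) pass through unchanged: ",
                              paste(which(const), collapse = ", "))
      list(maxabs = ma, constant = const)
    },
    robust = {
      q1 <- apply(X, 2, quantile, probs = 0.25, names = FALSE)
      q3 <- apply(X, 2, quantile, probs = 0.75, names = FALSE)
      med <- apply(X, 2, median)
      const <- q3 == q1
      if (any(const)) warning("zero-IQR feature(s) pass through unchanged: ",
                              paste(which(const), collapse = ", "))
      list(q1 = q1, q3 = q3, median = med, constant = const,
           center = options$center %||% "q1")
    },
    l2norm = list(),
    logistic = list(),
    lognormal = {
      if (any(X < 0)) stop("lognormal rescaler requires x >= 0", call. = FALSE)
      list(sigma = options$sigma %||% 1)
    },
    boxcox = {
      if (any(X <= 0)) {
        stop("boxcox requires strictly positive values in every feature",
             call. = FALSE)
      }
      list(lambda = apply(X, 2, boxcox_lambda_mle))
    },
    yeojohnson = {
      list(lambda = apply(X, 2, yeojohnson_lambda_mle))
    },
    quantile_normal = ,
    quantile_uniform = {
      n <- nrow(X)
      m <- min(options$n_quantiles %||% 1000L, n)
      probs <- seq(0, 1, length.out = max(m, 2L))
      qt <- apply(X, 2, quantile, probs = probs, names = FALSE, type = 7)
      list(probs = probs, quantiles = qt, n_train = n,
           mu = options$mu %||% 0, sigma = options$sigma %||% 1,
           a = options$a %||% 0, b = options$b %||% 1)
    }
  )
  structure(
    list(method = method, n_features = p, params = params,
         feature_names = colnames(X)),
    class = "rescaler_spec"
  )
}

RESCALER_METHODS <- c(
  "standard", "minmax", "maxabs", "robust", "l2norm", "logistic",
  "lognormal", "boxcox", "yeojohnson", "quantile_normal", "quantile_uniform"
)

#' @export
print.rescaler_spec <- function(x, ...) {
  cat("Rescaler spec:", x$method, "fitted on", x$n_features, "features\n")
  invisible(x)
}

#' @rdname fit_rescaler
#' @param spec A fitted `rescaler_spec`.
#' @export
apply_rescaler <- function(spec, X) {
  stopifnot(inherits(spec, "rescaler_spec"))
  X <- as.matrix(X)
  if (ncol(X) != spec$n_features) {
    stop(sprintf("feature count mismatch: spec fitted on %d, got %d",
                 spec$n_features, ncol(X)), call. = FALSE)
  }
  pr <- spec$params
  out <- switch(
    spec$method,
    standard = {
      Z <- sweep(sweep(X, 2, pr$mean), 2, ifelse(pr$constant, 1, pr$sd), "/")
      Z[, pr$constant] <- X[, pr$constant]
      Z
    },
    minmax = {
      rng <- ifelse(pr$constant, 1, pr$max - pr$min)
      Z <- sweep(sweep(X, 2, pr$min), 2, rng, "/")
      Z[, pr$constant] <- X[, pr$constant]
      Z
    },
    maxabs = {
      Z <- sweep(X, 2, ifelse(pr$constant, 1, pr$maxabs), "/")
      Z[, pr$constant] <- X[, pr$constant]
      Z
    },
    robust = {
      ctr <- if (identical(pr$center, "median")) pr$median else pr$q1
      iqr <- ifelse(pr$constant, 1, pr$q3 - pr$q1)
      Z <- sweep(sweep(X, 2, ctr), 2, iqr, "/")
      Z[, pr$constant] <- X[, pr$constant]
      Z
    },
    l2norm = {
      nrm <- sqrt(rowSums(X^2))
      nrm[nrm == 0] <- 1
      X / nrm
    },
    logistic = plogis(X),
    lognormal = {
      if (any(X < 0)) stop("lognormal rescaler requires x >= 0", call. = FALSE)
      pnorm(suppressWarnings(log(X)) / pr$sigma)
    },
    boxcox = {
      if (any(X <= 0)) {
        stop("boxcox transform requires strictly positive values",
             call. = FALSE)
      }
      Z <- X
      for (j in seq_len(ncol(X))) Z[, j] <- boxcox_transform(X[, j],
                                                             pr$lambda[j])
      Z
    },
    yeojohnson = {
      Z <- X
      for (j in seq_len(ncol(X))) Z[, j] <- yeojohnson_transform(X[, j],
                                                                 pr$lambda[j])
      Z
    },
    quantile_normal = ,
    quantile_uniform = {
      Z <- X
      eps <- 1 / (2 * pr$n_train)
      for (j in seq_len(ncol(X))) {
        qj <- pr$quantiles[, j]
        if (diff(range(qj)) == 0) {
          # constant training feature: every value maps to the median
          p <- rep(0.5, nrow(X))
        } else {
          p <- approx(qj, pr$probs, xout = X[, j], rule = 2, ties = mean)$y
        }
        p <- pmin(pmax(p, eps), 1 - eps)
        Z[, j] <- if (spec$method == "quantile_normal") {
          # mu + sigma * sqrt(2) * erfinv(2p - 1), i.e. the normal quantile
          qnorm(p, mean = pr$mu, sd = pr$sigma)
        } else {
          pr$a * (1 - p) + pr$b * p
        }
      }
      Z
    }
  )
  dimnames(out) <- dimnames(X)
  out
}

# Box-Cox power transform of one feature at a fixed lambda.
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

# Profile log-likelihood MLE of the Box-Cox lambda (normality of the
# transformed variable), maximized on [-5, 5].
boxcox_lambda_mle <- function(x, interval = c(-5, 5)) {
  n <- length(x)
  slx <- sum(log(x))
  ll <- function(l) {
    z <- boxcox_transform(x, l)
    v <- mean((z - mean(z))^2)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * slx
  }
  optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

# Four-branch Yeo-Johnson transform at a fixed lambda.
yeojohnson_transform <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -log1p(-x[!pos])
  } else {
    out[!pos] <- -(((-x[!pos] + 1)^(2 - lambda)) - 1) / (2 - lambda)
  }
  out[is.na(x)] <- NA_real_
  out
}

yeojohnson_lambda_mle <- function(x, interval = c(-5, 5)) {
  n <- length(x)
  s <- sum(sign(x) * log1p(abs(x)))
  ll <- function(l) {
    z <- yeojohnson_transform(x, l)
    v <- mean((z - mean(z))^2)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * s
  }
  optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

#' Serialize and restore a fitted rescaler
#'
#' Round-trips a `rescaler_spec` through YAML for reproducibility manifests.
#'
#' @param spec A `rescaler_spec`.
#' @param path File path.
#' @return `read_rescaler_spec()` returns the restored `rescaler_spec`.
#' @export
write_rescaler_spec <- function(spec, path) {
  stopifnot(inherits(spec, "rescaler_spec"))
  obj <- unclass(spec)
  # matrices are not YAML-native; store the quantile table column-major
  if (!is.null(obj$params$quantiles)) {
    q <- obj$params$quantiles
    obj$params$quantiles <- as.numeric(q)
    obj$params$quantile_dim <- dim(q)
  }
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_rescaler_spec
#' @export
read_rescaler_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.null(obj$params$quantile_dim)) {
    obj$params$quantiles <- matrix(as.numeric(obj$params$quantiles),
                                   obj$params$quantile_dim[[1]],
                                   obj$params$quantile_dim[[2]])
    obj$params$quantile_dim <- NULL
  }
  for (nm in c("mean", "sd", "min", "max", "maxabs", "q1", "q3", "median",
               "lambda", "probs")) {
    if (!is.null(obj$params[[nm]])) {
      obj$params[[nm]] <- as.numeric(obj$params[[nm]])
    }
  }
  if (!is.null(obj$params$constant)) {
    obj$params$constant <- as.logical(obj$params$constant)
  }
  structure(obj[c("method", "n_features", "params", "feature_names")],
            class = "rescaler_spec")
}
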