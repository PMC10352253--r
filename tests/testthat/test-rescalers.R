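test_that("closed-form examples hold for the simple scalers", {
  # two-point feature {0, 2}: mean 1, population sd 1, transforms to -1, +1
  X <- matrix(c(0, 2), 2, 1)
  sp <- fit_rescaler(X, "standard")
  expect_equal(sp$params$mean, 1, ignore_attr = TRUE)
  expect_equal(sp$params$sd, 1, ignore_attr = TRUE)
  expect_equal(as.numeric(apply_rescaler(sp, X)), c(-1, 1))

  # minmax endpoints
  X <- matrix(c(3, 5, 11), 3, 1)
  Z <- apply_rescaler(fit_rescaler(X, "minmax"), X)
  expect_equal(Z[1], 0)
  expect_equal(Z[3], 1)

  # logistic at 0
  sp <- fit_rescaler(matrix(0), "logistic")
  expect_equal(as.numeric(apply_rescaler(sp, matrix(0))), 0.5)

  # robust as printed: (x - Q1) / (Q3 - Q1)
  x <- c(1, 2, 3, 4, 5)
  Z <- apply_rescaler(fit_rescaler(matrix(x), "robust"), matrix(x))
  q1 <- quantile(x, 0.25, names = FALSE); q3 <- quantile(x, 0.75, names = FALSE)
  expect_equal(as.numeric(Z), (x - q1) / (q3 - q1))
})

test_that("standard and l2norm invariants hold on training data", {
  set.seed(1)
  X <- matrix(rlnorm(500), 100, 5)
  Z <- apply_rescaler(fit_rescaler(X, "standard"), X)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(colMeans(sweep(Z, 2, colMeans(Z))^2) - 1) < 1e-9))

  Z <- apply_rescaler(fit_rescaler(X, "l2norm"), X)
  expect_true(all(abs(sqrt(rowSums(Z^2)) - 1) < 1e-12))
})

test_that("lognormal maps through the normal CDF of log(x)/sigma and rejects x < 0", {
  X <- matrix(c(0.5, 1, 2, 8), 4, 1)
  sp <- fit_rescaler(X, "lognormal", options = list(sigma = 2))
  expect_equal(as.numeric(apply_rescaler(sp, X)), pnorm(log(X) / 2),
               ignore_attr = TRUE)
  expect_error(apply_rescaler(sp, matrix(-1)), "x >= 0")
  expect_error(fit_rescaler(matrix(c(-1, 1)), "lognormal"), "x >= 0")
})

test_that("box-cox matches its printed branches and rejects non-positive data", {
  # lambda = 0 branch: B(e, 0) = log(e) = 1
  expect_equal(qkmorph:::boxcox_transform(exp(1), 0), 1)
  expect_equal(qkmorph:::boxcox_transform(4, 2), (16 - 1) / 2)
  expect_error(fit_rescaler(matrix(c(0, 1, 2)), "boxcox"), "positive")

  # MLE recovers the generating transform direction: lognormal data wants
  # lambda near 0
  set.seed(2)
  x <- rlnorm(3000, 0, 0.5)
  lam <- qkmorph:::boxcox_lambda_mle(x)
  expect_lt(abs(lam), 0.15)
})

test_that("yeo-johnson MLE is near 1 on symmetric normal data and matches an independent grid search", {
  set.seed(3)
  x <- rnorm(5000)
  lam <- qkmorph:::yeojohnson_lambda_mle(x)
  expect_lt(abs(lam - 1), 0.15)

  # independent likelihood grid via car's Yeo-Johnson machinery
  skip_if_not_installed("car")
  grid <- seq(0.5, 1.5, by = 0.01)
  ll <- vapply(grid, function(l) {
    z <- car::yjPower(x, l)
    -length(x) / 2 * log(mean((z - mean(z))^2)) +
      (l - 1) * sum(sign(x) * log1p(abs(x)))
  }, numeric(1))
  expect_lt(abs(lam - grid[which.max(ll)]), 0.02)

  # four-branch agreement with car on mixed-sign data
  y <- c(-3, -0.5, 0, 0.5, 3)
  for (l in c(-0.5, 0, 1, 2, 2.5)) {
    expect_equal(qkmorph:::yeojohnson_transform(y, l), car::yjPower(y, l),
                 tolerance = 1e-12)
  }
})

test_that("quantile maps hit the printed anchor points and distribution targets", {
  set.seed(4)
  X <- matrix(rlnorm(400), 400, 1)
  spn <- fit_rescaler(X, "quantile_normal")
  med <- median(X)
  expect_equal(as.numeric(apply_rescaler(spn, matrix(med))), 0,
               tolerance = 1e-9)

  spu <- fit_rescaler(X, "quantile_uniform")
  U <- apply_rescaler(spu, X)
  expect_true(all(U >= 0 & U <= 1))
  # Kolmogorov distance to uniform on training data below 2/sqrt(n)
  ks <- max(abs(sort(U) - (seq_along(U) - 0.5) / length(U)))
  expect_lt(ks, 2 / sqrt(nrow(X)))

  # custom uniform range via a, b
  spu2 <- fit_rescaler(X, "quantile_uniform", options = list(a = -1, b = 3))
  U2 <- apply_rescaler(spu2, X)
  expect_true(all(U2 >= -1 & U2 <= 3))
})

test_that("fit/transform separation: test rows never alter fitted parameters", {
  set.seed(5)
  Xtr <- matrix(rlnorm(200), 50, 4)
  Xte <- matrix(rlnorm(40, 5), 10, 4)   # far outside the training range
  for (m in c("standard", "minmax", "robust", "quantile_uniform")) {
    sp <- fit_rescaler(Xtr, m)
    before <- apply_rescaler(sp, Xtr)
    invisible(apply_rescaler(sp, Xte))
    expect_identical(apply_rescaler(sp, Xtr), before)
  }
})

test_that("constant features pass through with a warning where division occurs", {
  X <- cbind(rnorm(20), rep(3, 20))
  expect_warning(sp <- fit_rescaler(X, "standard"), "constant")
  Z <- suppressWarnings(apply_rescaler(sp, X))
  expect_equal(Z[, 2], X[, 2])
})

test_that("feature-count mismatch and unknown methods are rejected", {
  sp <- fit_rescaler(matrix(rnorm(20), 10, 2), "standard")
  expect_error(apply_rescaler(sp, matrix(rnorm(30), 10, 3)), "mismatch")
  expect_error(fit_rescaler(matrix(1:4, 2), "zscore"))
})

test_that("rescaler specs round-trip through YAML", {
  set.seed(6)
  X <- matrix(rlnorm(300), 100, 3)
  for (m in c("standard", "robust", "boxcox", "quantile_normal")) {
    sp <- fit_rescaler(X, m)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_rescaler_spec(sp, path)
    sp2 <- read_rescaler_spec(path)
    expect_equal(apply_rescaler(sp2, X), apply_rescaler(sp, X),
                 tolerance = 1e-12)
  }
})
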