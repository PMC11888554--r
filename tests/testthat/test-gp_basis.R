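test_that("periodic Fourier basis reproduces the periodic SE kernel", {
  dom <- condition_domain(condition_dim("periodic", 0, 2 * pi,
                                        lengthscale = 1, variance = 1))
  bas <- build_basis(dom, 25L)
  g <- seq(0, 2 * pi, length.out = 50)
  err <- max(abs(basis_kernel(bas, g) - periodic_se_kernel(g, g)))
  expect_lt(err, 1e-3)
  # stationarity: kernel depends only on wrapped distance
  k1 <- basis_kernel(bas, 0.3, 1.1)
  k2 <- basis_kernel(bas, 4.0, 4.8)
  expect_equal(k1, k2, tolerance = 1e-12)
  # Gram matrix is PSD by construction (outer-product kernel)
  ev <- eigen(basis_kernel(bas, g), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("interval features approximate the SE kernel and constant basis is the flat limit", {
  di <- condition_domain(condition_dim("interval", 0, 2,
                                       lengthscale = 0.4, variance = 1.5))
  bi <- build_basis(di, 41L)
  g <- seq(0, 2, length.out = 40)
  Ktrue <- outer(g, g, function(a, b) 1.5 * exp(-(a - b)^2 / (2 * 0.4^2)))
  expect_lt(max(abs(basis_kernel(bi, g) - Ktrue)), 1e-3)
  # L = 1: constant basis, kernel sigma^2 everywhere
  b1 <- build_basis(condition_domain(condition_dim("interval", 0, 1,
                                                   variance = 2)), 1L)
  expect_equal(drop(basis_kernel(b1, 0.1, 0.9)), 2)
  expect_equal(evaluate_basis(b1, 0.5), sqrt(2))
})

test_that("discrete-embedded levels correlate by the SE kernel at their distance", {
  d3 <- condition_domain(condition_dim("discrete_embedded", levels = c(0, 1),
                                       lengthscale = 0.5, variance = 1))
  b3 <- build_basis(d3, 31L)
  ratio <- drop(basis_kernel(b3, 0, 1) / basis_kernel(b3, 0, 0))
  expect_equal(ratio, exp(-1 / (2 * 0.5^2)), tolerance = 1e-3)
  expect_error(evaluate_basis(b3, 0.5), "discrete")
})

test_that("basis evaluation is deterministic, periodic, and kernel-consistent", {
  dom <- condition_domain(condition_dim("periodic", 0, 2 * pi))
  bas <- build_basis(dom, 9L)
  v1 <- evaluate_basis(bas, 1.2)
  expect_identical(v1, evaluate_basis(bas, 1.2))
  expect_equal(v1, evaluate_basis(bas, 1.2 + 2 * pi), tolerance = 1e-12)
  expect_length(v1, 9L)
  expect_equal(sum(v1 * v1), drop(basis_kernel(bas, 1.2, 1.2)))
  # out-of-domain on a non-periodic interval errors rather than extrapolating
  bi <- build_basis(condition_domain(condition_dim("interval", 0, 1)), 5L)
  expect_error(evaluate_basis(bi, 1.7), "outside")
})

test_that("invalid hyperparameters are rejected", {
  expect_error(condition_dim("interval", 0, 1, lengthscale = -1), "lengthscale")
  expect_error(condition_dim("interval", 0, 1, variance = 0), "variance")
  expect_error(condition_dim("interval", 2, 1), "lower")
})

test_that("multi-dimensional bases tensor-multiply into a product kernel", {
  dom <- condition_domain(
    condition_dim("periodic", 0, 2 * pi, lengthscale = 1),
    condition_dim("discrete_embedded", levels = c(0, 1), lengthscale = 0.5))
  bas <- build_basis(dom, c(9L, 15L))
  expect_equal(bas$L, 9L * 15L)
  u1 <- c(1.0, 0); u2 <- c(2.5, 1)
  k2d <- drop(basis_kernel(bas, matrix(u1, 1), matrix(u2, 1)))
  b_per <- build_basis(condition_domain(condition_dim("periodic", 0, 2 * pi,
                                                      lengthscale = 1)), 9L)
  b_dis <- build_basis(condition_domain(
    condition_dim("discrete_embedded", levels = c(0, 1), lengthscale = 0.5)), 15L)
  expect_equal(k2d,
               drop(basis_kernel(b_per, 1.0, 2.5)) * drop(basis_kernel(b_dis, 0, 1)),
               tolerance = 1e-12)
})

test_that("sampled functions carry the prior variance and the Eq-style layout", {
  dom <- condition_domain(condition_dim("periodic", 0, 2 * pi))
  bas <- build_basis(dom, 11L)
  w1 <- sample_function(bas, 2L, 3L, seed = 7)
  w2 <- sample_function(bas, 2L, 3L, seed = 7)
  expect_identical(w1$W, w2$W)
  expect_equal(dim(w1$W), c(3L * 11L, 2L))
  # Monte-Carlo prior variance at a fixed point matches k(u, u) within 3 SE
  u0 <- 2.0
  phi <- evaluate_basis(bas, u0)
  set.seed(11)
  draws <- replicate(10000, sum(phi * rnorm(length(phi))))
  kuu <- drop(basis_kernel(bas, u0, u0))
  se <- sqrt(2 / (10000 - 1)) * kuu   # SE of a variance estimate, normal case
  expect_lt(abs(var(draws) - kuu), 3 * se)
})

test_that("weight-parameterized functions obey the Kronecker identities", {
  dom <- condition_domain(condition_dim("periodic", 0, 2 * pi))
  bas <- build_basis(dom, 7L)
  set.seed(3)
  w <- sample_function(bas, 2L, 3L, seed = 3)
  for (rep in 1:5) {
    u <- runif(1, 0, 2 * pi)
    X <- matrix(rnorm(6), 3L, 2L)
    M <- evaluate_function(w, bas, u)
    rhs <- crossprod(w$W, kronecker(matrix(evaluate_basis(bas, u), ncol = 1), X))
    expect_equal(M %*% X, rhs, tolerance = 1e-12)
    # and W^T z with z = phi (x) x reproduces M(u) x
    x <- rnorm(3)
    z <- expand_features(evaluate_basis(bas, u), x)
    expect_equal(drop(crossprod(w$W, z)), drop(M %*% x), tolerance = 1e-12)
  }
  # zero weights give the zero function; constant basis gives a constant
  w0 <- function_weights(matrix(0, 3L * 7L, 2L), 2L, 3L, 7L)
  expect_equal(evaluate_function(w0, bas, 1.0), matrix(0, 2L, 3L))
  b1 <- build_basis(condition_domain(condition_dim("interval", 0, 1)), 1L)
  wc <- function_weights(matrix(rnorm(6), 3L, 2L), 2L, 3L, 1L)
  expect_equal(evaluate_function(wc, b1, 0.1), evaluate_function(wc, b1, 0.9))
  # sequence evaluation agrees with pointwise evaluation
  us <- c(0.5, 3.0, 5.0)
  arr <- evaluate_function_seq(w, bas, us)
  for (t in 1:3)
    expect_equal(arr[, , t], evaluate_function(w, bas, us[t]), tolerance = 1e-12)
})
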