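const_model <- function(A, b, C = NULL, N = 2L, Q = 0.05, R = 0.05,
                        variance = 1) {
  D <- nrow(A)
  dom <- condition_domain(condition_dim("interval", 0, 1, variance = variance))
  bas <- build_basis(dom, 1L)
  sc <- sqrt(variance)
  if (is.null(C)) C <- diag(N)[, 1:D, drop = FALSE] + 0.1
  clds_model(bas, D, N,
             const_weights(A, D, D, sc, "A"), const_weights(b, D, 1, sc, "b"),
             const_weights(C, N, D, sc, "C"), NULL,
             const_weights(rep(0, D), D, 1, sc, "m"),
             diag(D), Q * diag(D), R * diag(N))
}

test_that("fixed points solve the linear system exactly", {
  # A = 0: x* = b
  m1 <- const_model(matrix(0, 2, 2), c(0.7, -0.3))
  fp1 <- fixed_points(m1, 0.5)
  expect_equal(drop(fp1$points), c(0.7, -0.3), tolerance = 1e-10)
  # A = 0.5 I, b = (1, 0): x* = (2, 0)
  m2 <- const_model(0.5 * diag(2), c(1, 0))
  fp2 <- fixed_points(m2, 0.5)
  expect_equal(drop(fp2$points), c(2, 0), tolerance = 1e-10)
  expect_true(all(fp2$residual < 1e-8))
  # eigenvalue at 1: flagged singular, others still solved
  m3 <- const_model(diag(c(1, 0)), c(0, 1))
  fp3 <- fixed_points(m3, c(0.2, 0.8))
  expect_true(all(fp3$singular))
})

test_that("dynamics spectra are ordered and match the quadratic formula", {
  om <- 0.7
  rot <- matrix(c(cos(om), sin(om), -sin(om), cos(om)), 2, 2)
  mr <- const_model(0.9 * rot, c(0, 0))
  sp <- dynamics_spectrum(mr, 0.5)
  expect_equal(sort(Arg(sp$eigvals[1, ])), c(-om, om), tolerance = 1e-10)
  expect_equal(Mod(sp$eigvals[1, ]), c(0.9, 0.9), tolerance = 1e-10)
  # random 2x2: roots of the characteristic polynomial
  set.seed(8)
  for (rep in 1:5) {
    A <- matrix(rnorm(4), 2, 2)
    mm <- const_model(A, c(0, 0))
    ev <- dynamics_spectrum(mm, 0.3)$eigvals[1, ]
    tr <- sum(diag(A)); dt <- det(A)
    roots <- polyroot(c(dt, -tr, 1))
    expect_equal(sort(Mod(ev)), sort(Mod(roots)), tolerance = 1e-8)
  }
})

test_that("composite field of a condition-independent model is the linear field", {
  A <- matrix(c(0.8, 0.1, -0.1, 0.7), 2, 2); b <- c(0.2, -0.1)
  mod <- const_model(A, b, N = 4L, C = matrix(rnorm(8), 4, 2))
  set.seed(14)
  trials <- lapply(1:3, function(k)
    sample_trial(mod, matrix(runif(40), 40, 1), seed = 20 + k))
  ts <- trial_set(trials, mod$basis$domain)
  cf <- composite_field(mod, ts, n_bins = 8L)
  expect_equal(sum(cf$occupancy), 120L)
  lin_err <- 0
  for (i in 1:8) for (j in 1:8) {
    if (cf$occupancy[i, j] > 0) {
      xc <- c(cf$centers_x[i], cf$centers_y[j])
      lin_err <- max(lin_err, max(abs(cf$vectors[i, j, ] - (A %*% xc + b - xc))))
    } else {
      expect_true(all(is.na(cf$vectors[i, j, ])))
    }
  }
  expect_lt(lin_err, 1e-8)
})

test_that("ring composite field points inward outside the attractor ring", {
  ds <- generate_dataset(ring_config(K = 8L, T = 100L, dyn_noise_sd = 0.25,
                                     seed = 21))
  cf <- composite_field(ds$model, ds$trialset, n_bins = 15L)
  checked <- 0L
  for (i in 1:15) for (j in 1:15) {
    if (cf$occupancy[i, j] >= 5L) {
      xc <- c(cf$centers_x[i], cf$centers_y[j])
      r <- sqrt(sum(xc^2))
      if (r > 1.2) {
        radial <- sum(cf$vectors[i, j, ] * xc / r)
        expect_lt(radial, 0)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 3L)
})

test_that("model tuning curves recover empirical tuning on clean ring data", {
  ds <- generate_dataset(ring_config(K = 10L, T = 100L, obs_noise_sd = 0.02,
                                     dyn_noise_sd = 0.02, seed = 23))
  tc <- tuning_curves(ds$model, ds$trialset, n_bins = 16L)
  # empirical curve for a few neurons, same binning
  th <- unlist(lapply(ds$trialset$trials, function(tr) tr$u[, 1]))
  brk <- seq(0, 2 * pi, length.out = 17)
  bin <- cut(th, brk, include.lowest = TRUE)
  for (i in c(1, 4, 8)) {
    yi <- unlist(lapply(ds$trialset$trials, function(tr) tr$y[, i]))
    emp <- tapply(yi, bin, mean)
    ok <- tc$counts > 20
    expect_lt(max(abs(tc$curves[ok, i] - emp[ok]), na.rm = TRUE), 0.15)
  }
})

test_that("degenerate tuning-curve cases behave as expected", {
  A <- 0.5 * diag(2); b <- c(0.4, 0.1)
  modz <- const_model(A, b, N = 3L, C = matrix(0, 3, 2))
  set.seed(31)
  ts <- trial_set(list(sample_trial(modz, matrix(runif(30), 30, 1), seed = 32)),
                  modz$basis$domain)
  tc <- tuning_curves(modz, ts, n_bins = 8L)
  expect_true(all(abs(tc$curves[tc$counts > 0, ]) < 1e-12))
  expect_true(all(is.na(tc$curves[tc$counts == 0, ])))
})
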