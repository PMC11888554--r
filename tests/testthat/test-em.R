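# reference accumulation with explicit kronecker() loops, against which the
# vectorized sufficient-statistics assembly is checked
loop_stats <- function(model, trialset) {
  D <- model$D; L <- model$basis$L; N <- model$N
  p <- D + 1L
  S_dyn <- matrix(0, p * L, p * L); B_dyn <- matrix(0, p * L, D)
  S_em <- matrix(0, D * L, D * L); B_em <- matrix(0, D * L, N)
  for (trial in trialset$trials) {
    post <- kalman_smoother(model, trial)
    Phi <- evaluate_basis(model$basis, trial$u)
    Tn <- nrow(trial$y)
    for (t in seq_len(Tn)) {
      Ex <- post$means[t, ]
      P <- post$covs[, , t] + Ex %o% Ex
      pp <- Phi[t, ] %o% Phi[t, ]
      if (t < Tn) {
        aug <- rbind(cbind(P, Ex), c(Ex, 1))
        S_dyn <- S_dyn + kronecker(pp, aug)
        G <- rbind(t(post$cross[, , t]), post$means[t + 1L, ])
        B_dyn <- B_dyn + kronecker(matrix(Phi[t, ], ncol = 1), G)
      }
      S_em <- S_em + kronecker(pp, P)
      B_em <- B_em + kronecker(matrix(Phi[t, ], ncol = 1),
                               matrix(Ex, ncol = 1)) %*% t(trial$y[t, ])
    }
  }
  list(S_dyn = S_dyn, B_dyn = B_dyn, S_em = S_em, B_em = B_em)
}

test_that("vectorized sufficient statistics equal the direct Kronecker sums", {
  mod <- random_small_model(D = 2L, N = 3L, L = 4L, seed = 61)
  trials <- lapply(1:2, function(k) random_trial(mod, Tn = 5L, seed = 70 + k))
  ts <- trial_set(trials, mod$basis$domain)
  st <- e_step(mod, ts)
  ref <- loop_stats(mod, ts)
  expect_equal(st$dyn$S, ref$S_dyn, tolerance = 1e-10)
  expect_equal(st$dyn$B, ref$B_dyn, tolerance = 1e-10)
  expect_equal(st$em$S, ref$S_em, tolerance = 1e-10)
  expect_equal(st$em$B, ref$B_em, tolerance = 1e-10)
  expect_equal(st$dyn$n, 8L)
  expect_equal(st$em$n, 10L)
})

test_that("sufficient statistics are additive over identical trials", {
  mod <- random_small_model(D = 2L, N = 2L, L = 3L, seed = 62)
  tr <- random_trial(mod, Tn = 4L, seed = 63)
  ts1 <- trial_set(list(tr), mod$basis$domain)
  ts3 <- trial_set(list(tr, tr, tr), mod$basis$domain)
  s1 <- e_step(mod, ts1); s3 <- e_step(mod, ts3)
  expect_equal(s3$dyn$S, 3 * s1$dyn$S, tolerance = 1e-9)
  expect_equal(s3$dyn$B, 3 * s1$dyn$B, tolerance = 1e-9)
  expect_equal(s3$em$S, 3 * s1$em$S, tolerance = 1e-9)
  expect_equal(s3$loglik, 3 * s1$loglik, tolerance = 1e-9)
})

test_that("with near-degenerate noise the statistics equal empirical latent moments", {
  mod <- random_small_model(D = 2L, N = 4L, L = 3L, seed = 64)
  mod$Q <- 1e-10 * diag(2); mod$Q1 <- 1e-10 * diag(2); mod$R <- 1e-10 * diag(4)
  tr <- sample_trial(mod, with_seed_local(65, runif(6, 0, 2 * pi)), seed = 66)
  ts <- trial_set(list(tr), mod$basis$domain)
  st <- e_step(mod, ts)
  Phi <- evaluate_basis(mod$basis, tr$u)
  S_ref <- matrix(0, nrow(st$dyn$S), ncol(st$dyn$S))
  for (t in 1:5) {
    aug <- c(tr$x[t, ], 1)
    S_ref <- S_ref + kronecker(Phi[t, ] %o% Phi[t, ], aug %o% aug)
  }
  expect_equal(st$dyn$S, S_ref, tolerance = 1e-4)
})

test_that("scalar two-step statistics match the joint-Gaussian oracle", {
  mod <- random_small_model(D = 1L, N = 1L, L = 2L, seed = 67)
  tr <- random_trial(mod, Tn = 2L, seed = 68)
  ts <- trial_set(list(tr), mod$basis$domain)
  st <- e_step(mod, ts)
  orc <- oracle_posterior_model(mod, tr)
  Phi <- evaluate_basis(mod$basis, tr$u)
  P1 <- orc$covs[, , 1] + orc$means[1, ]^2
  aug <- matrix(c(P1, orc$means[1, ], orc$means[1, ], 1), 2, 2)
  expect_equal(st$dyn$S, kronecker(Phi[1, ] %o% Phi[1, ], aug), tolerance = 1e-8)
  G <- c(orc$cross[, , 1], orc$means[2, ])
  expect_equal(st$dyn$B, kronecker(matrix(Phi[1, ], ncol = 1), matrix(G, ncol = 1)),
               tolerance = 1e-8)
  expect_equal(st$loglik, orc$loglik, tolerance = 1e-8)
})

test_that("M-steps return zeros for zero statistics and correct shapes otherwise", {
  mod <- random_small_model(D = 2L, N = 3L, L = 4L, seed = 69)
  ts <- trial_set(list(random_trial(mod, 5L, 71)), mod$basis$domain)
  st <- e_step(mod, ts)
  st0 <- st
  st0$dyn$B <- st0$dyn$B * 0
  dyn0 <- m_step_dynamics(st0, mod$Q)
  expect_equal(dyn0$A$W, matrix(0, 2 * 4, 2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(dyn0$b$W, matrix(0, 4, 2), tolerance = 1e-12, ignore_attr = TRUE)
  dyn <- m_step_dynamics(st, mod$Q)
  expect_equal(dim(dyn$A$W), c(2L * 4L, 2L))
  expect_equal(dim(dyn$b$W), c(4L, 2L))
  em <- m_step_emissions(st, mod$R)
  expect_equal(dim(em$C$W), c(2L * 4L, 3L))
  mm <- m_step_initial(st, mod$Q1)
  expect_equal(dim(mm$W), c(4L, 2L))
})

test_that("constant-basis initial update is the ridge-shrunk trial average", {
  dom <- condition_domain(condition_dim("interval", 0, 1))
  bas <- build_basis(dom, 1L)
  mod <- random_small_model(D = 2L, N = 3L, L = 5L, seed = 72)
  # build a constant-basis model with the same covariances
  cw <- function(M, D1, D2) function_weights(matrix(as.numeric(M), D2, D1), D1, D2, 1L)
  set.seed(73)
  modc <- clds_model(bas, 2L, 3L, cw(0.5 * diag(2), 2, 2), cw(c(0.1, -0.2), 2, 1),
                     cw(matrix(rnorm(6), 3, 2), 3, 2), NULL, cw(c(0, 0), 2, 1),
                     diag(2), 0.1 * diag(2), 0.1 * diag(3), fixed = "d")
  trials <- lapply(1:4, function(k)
    sample_trial(modc, matrix(runif(5), 5, 1), seed = 80 + k))
  ts <- trial_set(trials, dom)
  st <- e_step(modc, ts)
  mw <- m_step_initial(st, modc$Q1)
  # with phi = [1]: m solves K m + m Q1 = sum Ex1  (ridge toward zero)
  Ex1 <- st$init$Ex1
  m_ref <- solve(4 * diag(2) + modc$Q1) %*% colSums(Ex1)
  # Q1 = I so the Sylvester equation is exactly (K + Q1) m = sum Ex1
  expect_equal(drop(mw$W), drop(m_ref), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("EM objective is monotone, deterministic under seed, and max_iter = 0 is the init", {
  ds <- generate_dataset(ring_config(K = 3L, T = 40L, seed = 5))
  fit0 <- fit_em(ds$trialset, ds$model$basis, 2L, max_iter = 0L, seed = 3,
                 C = ds$model$C, learn_C = FALSE)
  expect_equal(nrow(fit0$trace), 0L)
  # initialization is the prior sample: same seed, same weights
  fit0b <- fit_em(ds$trialset, ds$model$basis, 2L, max_iter = 0L, seed = 3,
                  C = ds$model$C, learn_C = FALSE)
  expect_identical(fit0$model$A$W, fit0b$model$A$W)
  fit <- fit_em(ds$trialset, ds$model$basis, 2L, max_iter = 8L, tol = 0,
                seed = 3, C = ds$model$C, learn_C = FALSE)
  expect_true(all(diff(fit$trace$objective) > -1e-8))
  fitb <- fit_em(ds$trialset, ds$model$basis, 2L, max_iter = 8L, tol = 0,
                 seed = 3, C = ds$model$C, learn_C = FALSE)
  expect_identical(fit$trace$objective, fitb$trace$objective)
})

test_that("constant-basis EM reduces to textbook linear-Gaussian EM", {
  # weak prior via large basis variance: MAP updates -> MLE updates
  res <- classical_reduction_run(seed = 91, n_problems = 1L, iters = 1:4)
  expect_lt(res$max_rel_err, 1e-6)
})

test_that("hyperparameter selection returns tables, respects ties, needs K >= 5", {
  ds <- generate_dataset(ring_config(K = 6L, T = 30L, seed = 7))
  grid1 <- data.frame(L = 7L, kappa = 1, sigma2 = 1)
  sel <- select_hyperparameters(ds$trialset, grid1, D = 2L, seed = 2,
                                C = ds$model$C, learn_C = FALSE, max_iter = 5L)
  expect_equal(nrow(sel$table), 1L)
  expect_equal(sel$best$L, 7L)
  expect_true(is.finite(sel$table$cosmoothing))
  # duplicate grid rows: first wins
  grid2 <- rbind(grid1, grid1)
  sel2 <- select_hyperparameters(ds$trialset, grid2, D = 2L, seed = 2,
                                 C = ds$model$C, learn_C = FALSE, max_iter = 5L)
  expect_equal(rownames(sel2$best), "1")
  expect_error(select_hyperparameters(ds$trialset, data.frame(), D = 2L), "empty")
  small <- trial_set(ds$trialset$trials[1:3], ds$trialset$domain)
  expect_error(select_hyperparameters(small, grid1, D = 2L), "at least 5")
})
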