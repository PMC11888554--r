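# Independent oracles used across the suite. These deliberately avoid the
# package's filtering/EM code paths: moments are obtained by brute-force
# linear-Gaussian propagation and dense conditioning.

# Joint Gaussian of (x_{1:T}, y_{1:T}) for given per-step parameters,
# conditioned on the observed y. Returns smoothed marginals, adjacent
# cross-moments E[x_{t+1} x_t^T | y], and the marginal log-likelihood.
oracle_posterior <- function(pars, Q1, Q, R, y) {
  Tn <- nrow(y); D <- length(pars[[1L]]$m); N <- nrow(as.matrix(pars[[1L]]$C))
  mux <- matrix(0, Tn, D)
  Sxx <- matrix(0, Tn * D, Tn * D)
  xr <- function(t) ((t - 1L) * D + 1L):(t * D)
  yr <- function(t) ((t - 1L) * N + 1L):(t * N)
  mux[1L, ] <- pars[[1L]]$m
  Sxx[xr(1L), xr(1L)] <- Q1
  if (Tn > 1L) for (t in 1:(Tn - 1L)) {
    A <- pars[[t]]$A
    mux[t + 1L, ] <- A %*% mux[t, ] + pars[[t]]$b
    for (s in 1:t) {
      blk <- A %*% Sxx[xr(t), xr(s)]
      Sxx[xr(t + 1L), xr(s)] <- blk
      Sxx[xr(s), xr(t + 1L)] <- t(blk)
    }
    Sxx[xr(t + 1L), xr(t + 1L)] <- A %*% Sxx[xr(t), xr(t)] %*% t(A) + Q
  }
  Cb <- matrix(0, Tn * N, Tn * D); muy <- numeric(Tn * N)
  for (t in 1:Tn) {
    Cb[yr(t), xr(t)] <- pars[[t]]$C
    muy[yr(t)] <- pars[[t]]$C %*% mux[t, ] + pars[[t]]$d
  }
  Syy <- Cb %*% Sxx %*% t(Cb) + kronecker(diag(Tn), R)
  Sxy <- Sxx %*% t(Cb)
  yv <- as.numeric(t(y))
  cS <- chol((Syy + t(Syy)) / 2)
  alpha <- backsolve(cS, forwardsolve(t(cS), yv - muy))
  loglik <- -0.5 * (Tn * N * log(2 * pi) + 2 * sum(log(diag(cS))) +
                      sum((yv - muy) * alpha))
  pm <- as.numeric(t(mux)) + Sxy %*% backsolve(cS, forwardsolve(t(cS), yv - muy))
  pV <- Sxx - Sxy %*% chol2inv(cS) %*% t(Sxy)
  means <- matrix(pm, Tn, D, byrow = TRUE)
  covs <- array(0, c(D, D, Tn))
  for (t in 1:Tn) covs[, , t] <- pV[xr(t), xr(t)]
  cross <- if (Tn > 1L) {
    cr <- array(0, c(D, D, Tn - 1L))
    for (t in 1:(Tn - 1L))
      cr[, , t] <- pV[xr(t + 1L), xr(t)] + means[t + 1L, ] %o% means[t, ]
    cr
  }
  list(means = means, covs = covs, cross = cross, loglik = loglik)
}

oracle_posterior_model <- function(model, trial) {
  Tn <- nrow(trial$y)
  pars <- lapply(seq_len(Tn), function(t)
    evaluate_params(model, drop(trial$u[t, , drop = FALSE])))
  oracle_posterior(pars, model$Q1, model$Q, model$R, trial$y)
}

# Random small weight-parameterized model on a periodic domain.
random_small_model <- function(D = 2L, N = 3L, L = 5L, seed = 1L) {
  dom <- condition_domain(condition_dim("periodic", 0, 2 * pi,
                                        lengthscale = 1, variance = 0.6))
  bas <- build_basis(dom, L)
  rnd_spd <- function(n, scale) {
    M <- matrix(stats::rnorm(n * n), n, n)
    scale * (crossprod(M) / n + diag(n))
  }
  withr_seed <- seed
  set.seed(withr_seed)
  mod <- clds_model(bas, D, N,
    A = sample_function(bas, D, D, "A"),
    b = sample_function(bas, D, 1L, "b"),
    C = sample_function(bas, N, D, "C"),
    d = sample_function(bas, N, 1L, "d"),
    m = sample_function(bas, D, 1L, "m"),
    Q1 = rnd_spd(D, 0.5), Q = rnd_spd(D, 0.2), R = rnd_spd(N, 0.3),
    fixed = character(0))
  mod
}

random_trial <- function(model, Tn = 4L, seed = 1L) {
  u <- with_seed_local(seed, stats::runif(Tn, 0, 2 * pi))
  sample_trial(model, u, seed = seed + 1L)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Textbook maximum-likelihood EM for a time-invariant linear-Gaussian
# state-space model x_{t+1} = A x_t + b + eps, y_t = C x_t + omega, written
# independently of the package's smoother and M-steps (direct RTS recursions
# and plain least-squares updates, no prior).
textbook_lds_em <- function(trials, A, b, C, m, Q1, Q, R, n_iter) {
  D <- nrow(A); N <- nrow(C)
  for (iter in seq_len(n_iter)) {
    Saug <- matrix(0, D + 1L, D + 1L); Baug <- matrix(0, D + 1L, D)
    SP <- matrix(0, D, D); SYX <- matrix(0, N, D)
    Ex1s <- NULL; P1s <- array(0, c(D, D, length(trials)))
    posts <- list()
    for (k in seq_along(trials)) {
      y <- trials[[k]]$y; Tn <- nrow(y)
      # forward filter
      mp <- matrix(0, Tn, D); Vp <- array(0, c(D, D, Tn))
      mf <- matrix(0, Tn, D); Vf <- array(0, c(D, D, Tn))
      mprev <- m; Vprev <- Q1
      for (t in 1:Tn) {
        mp[t, ] <- mprev; Vp[, , t] <- Vprev
        S <- C %*% Vprev %*% t(C) + R
        Kg <- Vprev %*% t(C) %*% solve(S)
        mf[t, ] <- mprev + Kg %*% (y[t, ] - C %*% mprev)
        Vf[, , t] <- Vprev - Kg %*% C %*% Vprev
        if (t < Tn) {
          mprev <- drop(A %*% mf[t, ] + b)
          Vprev <- A %*% Vf[, , t] %*% t(A) + Q
        }
      }
      ms <- mf; Vs <- Vf
      cross <- array(0, c(D, D, max(Tn - 1L, 1L)))
      if (Tn > 1L) for (t in (Tn - 1L):1L) {
        J <- Vf[, , t] %*% t(A) %*% solve(Vp[, , t + 1L])
        ms[t, ] <- mf[t, ] + J %*% (ms[t + 1L, ] - mp[t + 1L, ])
        Vs[, , t] <- Vf[, , t] + J %*% (Vs[, , t + 1L] - Vp[, , t + 1L]) %*% t(J)
        cross[, , t] <- Vs[, , t + 1L] %*% t(J) + ms[t + 1L, ] %o% ms[t, ]
      }
      posts[[k]] <- list(ms = ms, Vs = Vs, cross = cross, y = y)
      for (t in 1:Tn) {
        P <- Vs[, , t] + ms[t, ] %o% ms[t, ]
        SP <- SP + P
        SYX <- SYX + y[t, ] %o% ms[t, ]
        if (t < Tn) {
          aug <- rbind(cbind(P, ms[t, ]), c(ms[t, ], 1))
          Saug <- Saug + aug
          Baug <- Baug + rbind(t(cross[, , t]), ms[t + 1L, ])
        }
      }
      Ex1s <- rbind(Ex1s, ms[1L, ])
      P1s[, , k] <- Vs[, , 1L] + ms[1L, ] %o% ms[1L, ]
    }
    AB <- t(solve(Saug, Baug))            # D x (D+1)
    A <- AB[, 1:D, drop = FALSE]; b <- AB[, D + 1L]
    C <- SYX %*% solve(SP)
    m <- colMeans(Ex1s)
    # covariances from expected residuals with the new parameters
    K <- length(trials)
    Q1n <- matrix(0, D, D)
    for (k in 1:K) Q1n <- Q1n + P1s[, , k] - Ex1s[k, ] %o% m - m %o% Ex1s[k, ] + m %o% m
    Q1 <- (Q1n + t(Q1n)) / (2 * K)
    Qn <- matrix(0, D, D); nQ <- 0L
    Rn <- matrix(0, N, N); nR <- 0L
    for (k in 1:K) {
      ms <- posts[[k]]$ms; Vs <- posts[[k]]$Vs; cross <- posts[[k]]$cross
      y <- posts[[k]]$y; Tn <- nrow(y)
      for (t in 1:Tn) {
        P <- Vs[, , t] + ms[t, ] %o% ms[t, ]
        r <- y[t, ] - drop(C %*% ms[t, ])
        Rn <- Rn + r %o% r + C %*% Vs[, , t] %*% t(C)
        nR <- nR + 1L
        if (t < Tn) {
          P2 <- Vs[, , t + 1L] + ms[t + 1L, ] %o% ms[t + 1L, ]
          Cc <- cross[, , t]
          res <- P2 - Cc %*% t(A) - A %*% t(Cc) + A %*% P %*% t(A)
          mu2 <- ms[t + 1L, ] - drop(A %*% ms[t, ])
          res <- res - mu2 %o% b - b %o% mu2 + b %o% b
          Qn <- Qn + res
          nQ <- nQ + 1L
        }
      }
    }
    Q <- (Qn + t(Qn)) / (2 * nQ)
    R <- (Rn + t(Rn)) / (2 * nR)
  }
  list(A = A, b = b, C = C, m = m, Q1 = Q1, Q = Q, R = R)
}

# Closed-form periodic squared-exponential kernel (the L -> Inf target).
periodic_se_kernel <- function(u, u2, kappa = 1, sigma2 = 1) {
  outer(u, u2, function(a, b) sigma2 * exp(-2 * sin((a - b) / 2)^2 / kappa^2))
}

ring_truth_grid <- function(theta, epsilon = 0.1) {
  lapply(theta, function(th) {
    e1 <- c(cos(th), sin(th)); e2 <- c(-sin(th), cos(th))
    list(A = (1 - epsilon) * e2 %o% e2, b = e1)
  })
}

# Constant-basis weights encoding a fixed matrix M under basis scale `scale`
# (evaluated function value equals M exactly).
const_weights <- function(M, D1, D2, scale, label = "M") {
  M <- matrix(as.numeric(M), D1, D2)
  function_weights(t(M) / scale, D1, D2, 1L, label)
}

# Runs the kappa -> Inf reduction: constant-basis MAP EM vs the textbook
# maximum-likelihood EM from a shared initialization, on `n_problems` random
# small datasets; returns the worst relative parameter discrepancy over the
# requested per-iteration comparisons.
classical_reduction_run <- function(seed, n_problems = 3L, iters = 1:3) {
  sc2 <- 1e8; sc <- sqrt(sc2)
  dom <- condition_domain(condition_dim("interval", 0, 1, variance = sc2))
  bas <- build_basis(dom, 1L)
  worst <- 0
  rel <- function(a, b) {
    den <- max(abs(b), 1e-3)
    max(abs(a - b)) / den
  }
  for (pb in seq_len(n_problems)) {
    set.seed(seed + pb)
    D <- 2L; N <- 3L
    A0 <- matrix(c(0.6, 0.1, -0.2, 0.5), 2, 2) + 0.05 * matrix(rnorm(4), 2, 2)
    b0 <- c(0.3, -0.1); C0 <- matrix(rnorm(6), 3, 2); m0 <- c(0.2, 0)
    trials <- lapply(1:3, function(k) {
      x <- matrix(0, 30, D); y <- matrix(0, 30, N)
      x[1, ] <- m0 + rnorm(2)
      for (t in 1:30) {
        y[t, ] <- C0 %*% x[t, ] + 0.3 * rnorm(3)
        if (t < 30) x[t + 1, ] <- A0 %*% x[t, ] + b0 + 0.2 * rnorm(2)
      }
      clds_trial(y, matrix(runif(30), 30, 1), x)
    })
    ts <- trial_set(trials, dom)
    Ai <- 0.5 * diag(2); bi <- c(0, 0); Ci <- C0 + 0.3; mi <- c(0, 0)
    init <- clds_model(bas, D, N,
      const_weights(Ai, 2, 2, sc, "A"), const_weights(bi, 2, 1, sc, "b"),
      const_weights(Ci, 3, 2, sc, "C"), NULL, const_weights(mi, 2, 1, sc, "m"),
      Q1 = diag(2), Q = 0.1 * diag(2), R = 0.1 * diag(3), fixed = "d")
    for (it in iters) {
      fit <- fit_em(ts, bas, D, max_iter = it, tol = 0, init_model = init,
                    learn_C = TRUE, learn_d = FALSE)
      tb <- textbook_lds_em(trials, Ai, bi, Ci, mi, diag(2), 0.1 * diag(2),
                            0.1 * diag(3), n_iter = it)
      pf <- evaluate_params(fit$model, 0.5)
      worst <- max(worst,
                   rel(pf$A, tb$A), rel(pf$b, tb$b), rel(pf$C, tb$C),
                   rel(pf$m, tb$m), rel(fit$model$Q, tb$Q),
                   rel(fit$model$R, tb$R), rel(fit$model$Q1, tb$Q1))
    }
  }
  list(max_rel_err = worst)
}
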