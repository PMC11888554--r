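#' Kalman filter for a conditionally linear model
#'
#' Runs the standard predict/update recursions with per-step parameters
#' `{A(u_t), b(u_t), C(u_t), d(u_t)}` evaluated along the trial's covariate
#' sequence, accumulating the exact marginal log-likelihood from the
#' innovation densities. Covariance updates use the Joseph form followed by
#' symmetrization for numerical robustness.
#'
#' @param model A [clds_model()].
#' @param trial A [clds_trial()].
#' @param params Optional precomputed output of the internal per-sequence
#'   parameter evaluation (used by EM to avoid re-evaluating frozen functions).
#' @return A list with `means` (`T x D` filtered means), `covs` (`D x D x T`),
#'   `pred_means`, `pred_covs` (one-step predictive moments), and `loglik`.
#' @export
kalman_filter <- function(model, trial, params = NULL) {
  if (is.null(params)) params <- evaluate_params_seq(model, trial$u)
  D <- model$D; N <- model$N; Tn <- nrow(trial$y)
  y <- trial$y
  mf <- matrix(0, Tn, D); Vf <- array(0, c(D, D, Tn))
  mp <- matrix(0, Tn, D); Vp <- array(0, c(D, D, Tn))
  Q <- model$Q; R <- model$R
  ID <- diag(D)
  loglik <- 0
  m_prev <- params$m; V_prev <- model$Q1
  for (t in seq_len(Tn)) {
    mp[t, ] <- m_prev; Vp[, , t] <- V_prev
    Ct <- matrix(params$C[, , t], N, D)
    S <- Ct %*% V_prev %*% t(Ct) + R
    S <- (S + t(S)) / 2
    cS <- tryCatch(chol(S), error = function(e)
      stop("numerical failure: innovation covariance not positive definite at t = ", t))
    e <- y[t, ] - drop(Ct %*% m_prev) - params$d[t, ]
    alpha <- backsolve(cS, forwardsolve(t(cS), e))
    loglik <- loglik - 0.5 * (N * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(e * alpha))
    K <- V_prev %*% t(Ct) %*% chol2inv(cS)
    mf[t, ] <- m_prev + drop(K %*% e)
    IKC <- ID - K %*% Ct
    Vt <- IKC %*% V_prev %*% t(IKC) + K %*% R %*% t(K)
    Vf[, , t] <- (Vt + t(Vt)) / 2
    if (t < Tn) {
      At <- matrix(params$A[, , t], D, D)
      m_prev <- drop(At %*% mf[t, ]) + params$b[t, ]
      V_prev <- At %*% Vf[, , t] %*% t(At) + Q
      V_prev <- (V_prev + t(V_prev)) / 2
    }
  }
  list(means = mf, covs = Vf, pred_means = mp, pred_covs = Vp, loglik = loglik)
}

#' Kalman (RTS) smoother for a conditionally linear model
#'
#' Backward Rauch-Tung-Striebel pass over the filtered moments, producing
#' smoothed marginal means and covariances, adjacent cross-moments
#' `E[x_{t+1} x_t^T | y_{1:T}]` (the statistic consumed by the dynamics
#' M-step), and the marginal log-likelihood (identical to the filter's).
#'
#' @inheritParams kalman_filter
#' @return An object of class `clds_posterior` with fields `means` (`T x D`),
#'   `covs` (`D x D x T`), `cross` (`D x D x (T-1)`), and `loglik`.
#' @export
kalman_smoother <- function(model, trial, params = NULL) {
  if (is.null(params)) params <- evaluate_params_seq(model, trial$u)
  filt <- kalman_filter(model, trial, params)
  D <- model$D; Tn <- nrow(trial$y)
  ms <- filt$means; Vs <- filt$covs
  cross <- if (Tn > 1L) array(0, c(D, D, Tn - 1L)) else NULL
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      At <- matrix(params$A[, , t], D, D)
      # J_t = Vf_t A_t^T (Vp_{t+1})^{-1}; pseudo-solve handles the degenerate
      # (rank-deficient predicted covariance) limit of vanishing dynamics noise
      J <- t(sym_psolve(filt$pred_covs[, , t + 1L], At %*% filt$covs[, , t]))
      ms[t, ] <- filt$means[t, ] + drop(J %*% (ms[t + 1L, ] - filt$pred_means[t + 1L, ]))
      Vt <- filt$covs[, , t] + J %*% (Vs[, , t + 1L] - filt$pred_covs[, , t + 1L]) %*% t(J)
      Vs[, , t] <- (Vt + t(Vt)) / 2
      cross[, , t] <- Vs[, , t + 1L] %*% t(J) + ms[t + 1L, ] %o% ms[t, ]
    }
  }
  structure(list(means = ms, covs = Vs, cross = cross, loglik = filt$loglik),
            class = "clds_posterior")
}

#' @export
print.clds_posterior <- function(x, ...) {
  cat(sprintf("<clds_posterior> T = %d, D = %d, loglik = %.4f\n",
              nrow(x$means), ncol(x$means), x$loglik))
  invisible(x)
}

# solve M X = B for symmetric PSD M, falling back to the eigenvalue
# pseudo-inverse when M is numerically singular
sym_psolve <- function(M, B) {
  M <- (M + t(M)) / 2
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch) && rcond(M) > 1e-12)
    return(backsolve(ch, forwardsolve(t(ch), B)))
  eg <- eigen(M, symmetric = TRUE)
  tol <- max(eg$values, 0) * 1e-12
  inv_vals <- ifelse(eg$values > tol, 1 / eg$values, 0)
  eg$vectors %*% (inv_vals * crossprod(eg$vectors, B))
}

#' Posterior mode of the latent trajectory
#'
#' For the Gaussian model the posterior mode equals the smoothed mean; this
#' is the latent estimate consumed by reconstruction, co-smoothing, composite
#' dynamics, and tuning-curve computations.
#'
#' @inheritParams kalman_filter
#' @return A `T x D` matrix of smoothed latent means.
#' @export
posterior_mode <- function(model, trial, params = NULL) {
  kalman_smoother(model, trial, params)$means
}
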