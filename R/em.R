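# ---- vectorized accumulation of Kronecker-structured moments ----------------
#
# The M-steps consume sums over time of Kronecker-product moments,
#   S = sum_t (phi_t phi_t^T) (x) M_t,   B = sum_t phi_t (x) G_t,
# with M_t a (p x p) second-moment block and G_t a (p x q) cross-moment block.
# Rather than looping kronecker() calls, both are computed as one crossprod
# over flattened per-step blocks and then re-indexed.

sum_kron_outer <- function(Phi, Mflat, p) {
  L <- ncol(Phi)
  PhiPhi <- Phi[, rep(seq_len(L), times = L), drop = FALSE] *
    Phi[, rep(seq_len(L), each = L), drop = FALSE]        # col = a + (b-1)L
  V <- crossprod(PhiPhi, Mflat)                            # [ab, cd]
  S <- matrix(aperm(array(V, c(L, L, p, p)), c(3L, 1L, 4L, 2L)), p * L, p * L)
  (S + t(S)) / 2
}

sum_kron_cross <- function(Phi, Gflat, p, q) {
  L <- ncol(Phi)
  V <- crossprod(Phi, Gflat)                               # [a, ce]
  matrix(aperm(array(V, c(L, p, q)), c(2L, 1L, 3L)), p * L, q)
}

# T x (p^2) flattened augmented second moments [[P, Ex],[Ex^T, 1]]
build_aug_flat <- function(Ex, Pflat, D) {
  Tn <- nrow(Ex); p <- D + 1L
  out <- matrix(0, Tn, p * p)
  for (dcol in seq_len(D)) {
    cols <- seq_len(D) + (dcol - 1L) * p
    out[, cols] <- Pflat[, seq_len(D) + (dcol - 1L) * D, drop = FALSE]
    out[, p + (dcol - 1L) * p] <- Ex[, dcol]               # bottom row
  }
  out[, seq_len(D) + D * p] <- Ex                          # last column
  out[, p * p] <- 1
  out
}

# ---- E-step -----------------------------------------------------------------

#' Expectation step: smooth every trial and accumulate sufficient statistics
#'
#' Runs the Kalman smoother on each trial and accumulates the expected
#' feature-space moments consumed by the M-steps: the dynamics block uses the
#' intercept-augmented features `phi(u_t) (x) [x_t; 1]` (so the dynamics
#' matrix and bias are updated jointly), the emission block analogously, and
#' the initial block regresses `E[x_1]` on `phi(u_1)` across trials.
#' Expectations of quadratic forms use `E[x x^T] = cov + mean mean^T` and the
#' smoothed adjacent cross-moments.
#'
#' @param model A [clds_model()].
#' @param trialset A [trial_set()].
#' @param cache Optional precomputed per-trial cache from the internal
#'   `make_fit_cache()` (basis matrices, frozen parameter evaluations).
#' @param emissions If `FALSE`, skip the emission block (used when `C` and
#'   `d` are both frozen).
#' @param learn_d If `TRUE`, augment the emission features with an intercept
#'   so `d` is updated jointly with `C`.
#' @return An object of class `clds_suffstats`; also carries the per-trial
#'   smoothed posteriors and the total marginal log-likelihood.
#' @export
e_step <- function(model, trialset, cache = NULL, emissions = TRUE,
                   learn_d = FALSE) {
  if (is.null(cache)) cache <- make_fit_cache(model, trialset)
  D <- model$D; L <- model$basis$L; N <- model$N
  p <- D + 1L
  S_dyn <- matrix(0, p * L, p * L); B_dyn <- matrix(0, p * L, D); n_dyn <- 0L
  pe <- if (learn_d) D + 1L else D
  S_em <- matrix(0, pe * L, pe * L); B_em <- matrix(0, pe * L, N); n_em <- 0L
  K <- n_trials(trialset)
  Phi1 <- matrix(0, K, L); Ex1 <- matrix(0, K, D); P1 <- array(0, c(D, D, K))
  posteriors <- vector("list", K)
  loglik <- 0
  for (k in seq_len(K)) {
    trial <- trialset$trials[[k]]
    Phi <- cache[[k]]$Phi
    params <- trial_params(model, trial, cache[[k]])
    post <- kalman_smoother(model, trial, params)
    posteriors[[k]] <- post
    loglik <- loglik + post$loglik
    Tn <- nrow(trial$y)
    Ex <- post$means
    Pflat <- t(matrix(post$covs, D * D, Tn)) +
      Ex[, rep(seq_len(D), times = D), drop = FALSE] *
      Ex[, rep(seq_len(D), each = D), drop = FALSE]        # T x D^2, col i+(j-1)D
    if (Tn > 1L) {
      idx <- seq_len(Tn - 1L)
      Aug <- build_aug_flat(Ex[idx, , drop = FALSE], Pflat[idx, , drop = FALSE], D)
      S_dyn <- S_dyn + sum_kron_outer(Phi[idx, , drop = FALSE], Aug, p)
      # G_t = E[[x_t; 1] x_{t+1}^T]; E[x_t x_{t+1}^T][c, e] = cross[e, c, t]
      crossflat <- t(matrix(post$cross, D * D, Tn - 1L))   # col e + (c-1)D
      G <- matrix(0, Tn - 1L, p * D)
      for (e in seq_len(D)) {
        G[, seq_len(D) + (e - 1L) * p] <-
          crossflat[, e + (seq_len(D) - 1L) * D, drop = FALSE]
        G[, p + (e - 1L) * p] <- Ex[idx + 1L, e]
      }
      B_dyn <- B_dyn + sum_kron_cross(Phi[idx, , drop = FALSE], G, p, D)
      n_dyn <- n_dyn + Tn - 1L
    }
    if (emissions) {
      if (learn_d) {
        Aug <- build_aug_flat(Ex, Pflat, D)
        S_em <- S_em + sum_kron_outer(Phi, Aug, pe)
        Zk <- Phi[, rep(seq_len(L), each = pe), drop = FALSE] *
          cbind(Ex, 1)[, rep(seq_len(pe), times = L), drop = FALSE]
      } else {
        S_em <- S_em + sum_kron_outer(Phi, Pflat, pe)
        Zk <- Phi[, rep(seq_len(L), each = pe), drop = FALSE] *
          Ex[, rep(seq_len(pe), times = L), drop = FALSE]
      }
      B_em <- B_em + crossprod(Zk, trial$y)
      n_em <- n_em + Tn
    }
    Phi1[k, ] <- Phi[1L, ]
    Ex1[k, ] <- Ex[1L, ]
    P1[, , k] <- post$covs[, , 1L] + Ex[1L, ] %o% Ex[1L, ]
  }
  structure(list(
    dyn = list(S = S_dyn, B = B_dyn, n = n_dyn),
    em = if (emissions) list(S = S_em, B = B_em, n = n_em, learn_d = learn_d),
    init = list(S = crossprod(Phi1), B = crossprod(Phi1, Ex1),
                Phi1 = Phi1, Ex1 = Ex1, P1 = P1),
    posteriors = posteriors, loglik = loglik,
    D = D, N = N, L = L), class = "clds_suffstats")
}

# ---- M-steps ----------------------------------------------------------------

split_aug_weights <- function(W, D, L, labels = c("A", "b")) {
  p <- D + 1L
  rows_A <- as.vector(vapply(seq_len(L), function(l) (l - 1L) * p + seq_len(D),
                             integer(D)))
  rows_b <- (seq_len(L) - 1L) * p + p
  list(function_weights(W[rows_A, , drop = FALSE], ncol(W), D, L, labels[1L]),
       function_weights(W[rows_b, , drop = FALSE], ncol(W), 1L, L, labels[2L]))
}

#' Dynamics M-step: joint MAP update of A and b
#'
#' One Sylvester-equation regression solve on the intercept-augmented
#' dynamics block of the sufficient statistics, with noise covariance `Q`.
#'
#' @param stats A [e_step()] result.
#' @param Q Current dynamics noise covariance.
#' @return A list with updated `A` and `b` [function_weights()].
#' @export
m_step_dynamics <- function(stats, Q) {
  W <- solve_map_weights(clr_problem(Q, StS = stats$dyn$S, StY = stats$dyn$B))
  sp <- split_aug_weights(W, stats$D, stats$L, c("A", "b"))
  list(A = sp[[1L]], b = sp[[2L]])
}

#' Emission M-step: MAP update of C (and d when learned)
#'
#' @param stats A [e_step()] result with an emission block.
#' @param R Current observation noise covariance.
#' @return A list with updated `C` (and `d` when the block was augmented).
#' @export
m_step_emissions <- function(stats, R) {
  if (is.null(stats$em)) stop("E-step was run without the emission block")
  W <- solve_map_weights(clr_problem(R, StS = stats$em$S, StY = stats$em$B))
  if (isTRUE(stats$em$learn_d)) {
    sp <- split_aug_weights(W, stats$D, stats$L, c("C", "d"))
    list(C = sp[[1L]], d = sp[[2L]])
  } else {
    list(C = function_weights(W, stats$N, stats$D, stats$L, "C"), d = NULL)
  }
}

#' Initial-state M-step: MAP update of m
#'
#' Regresses the smoothed `E[x_1]` on `phi(u_1)` across trials with noise
#' covariance `Q1`; with few trials the unit-normal weight prior shrinks the
#' estimate toward zero.
#'
#' @param stats A [e_step()] result.
#' @param Q1 Current initial-state covariance.
#' @return Updated `m` [function_weights()].
#' @export
m_step_initial <- function(stats, Q1) {
  W <- solve_map_weights(clr_problem(Q1, StS = stats$init$S, StY = stats$init$B))
  function_weights(W, stats$D, 1L, stats$L, "m")
}

#' Covariance M-step: expected residual outer products
#'
#' Standard linear-Gaussian EM covariance updates with the condition-dependent
#' parameters (evaluated from the freshly updated weights) inserted. Outputs
#' are symmetrized and floored at `floor` on the eigenvalue scale to guard
#' against degeneracy.
#'
#' @param stats A [e_step()] result (carries the smoothed posteriors).
#' @param model A model holding the updated parameter functions.
#' @param trialset The training data.
#' @param cache Optional per-trial cache.
#' @param learn_Q1 If `FALSE`, `Q1` is returned unchanged from `model`.
#' @param floor Eigenvalue floor for the returned covariances.
#' @return A list with `Q1`, `Q`, `R`.
#' @export
update_covariances <- function(stats, model, trialset, cache = NULL,
                               learn_Q1 = TRUE, floor = 1e-6) {
  if (is.null(cache)) cache <- make_fit_cache(model, trialset)
  D <- model$D; N <- model$N
  Qacc <- matrix(0, D, D); nQ <- 0L
  Racc <- matrix(0, N, N); nR <- 0L
  Q1acc <- matrix(0, D, D)
  K <- n_trials(trialset)
  for (k in seq_len(K)) {
    trial <- trialset$trials[[k]]
    post <- stats$posteriors[[k]]
    params <- trial_params(model, trial, cache[[k]])
    Tn <- nrow(trial$y)
    Ex <- post$means
    # initial block
    mk <- drop(eval_param(model$m, model$basis, drop(trial$u[1L, , drop = FALSE])))
    dx <- Ex[1L, ] - mk
    Q1acc <- Q1acc + post$covs[, , 1L] + dx %o% dx
    # dynamics block
    if (Tn > 1L) {
      for (t in seq_len(Tn - 1L)) {
        At <- matrix(params$A[, , t], D, D); bt <- params$b[t, ]
        P1 <- post$covs[, , t] + Ex[t, ] %o% Ex[t, ]
        P2 <- post$covs[, , t + 1L] + Ex[t + 1L, ] %o% Ex[t + 1L, ]
        Cc <- post$cross[, , t]                      # E[x_{t+1} x_t^T]
        res <- P2 - Cc %*% t(At) - At %*% t(Cc) + At %*% P1 %*% t(At)
        mu2 <- Ex[t + 1L, ] - drop(At %*% Ex[t, ])
        res <- res - mu2 %o% bt - bt %o% mu2 + bt %o% bt
        Qacc <- Qacc + res
      }
      nQ <- nQ + Tn - 1L
    }
    # emission block
    r <- trial$y - params$d
    CE <- matrix(0, Tn, N)
    for (t in seq_len(Tn)) {
      Ct <- matrix(params$C[, , t], N, D)
      CE[t, ] <- Ct %*% Ex[t, ]
      Racc <- Racc + Ct %*% post$covs[, , t] %*% t(Ct)
    }
    E <- r - CE
    Racc <- Racc + crossprod(E)
    nR <- nR + Tn
  }
  list(Q1 = if (learn_Q1) spd_floor(Q1acc / K, floor) else model$Q1,
       Q = spd_floor(Qacc / max(nQ, 1L), floor),
       R = spd_floor(Racc / nR, floor))
}

spd_floor <- function(M, floor = 1e-6) {
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  vals <- pmax(eg$values, floor)
  M <- eg$vectors %*% (vals * t(eg$vectors))
  (M + t(M)) / 2
}

# ---- fitting ---------------------------------------------------------------

make_fit_cache <- function(model, trialset) {
  lapply(trialset$trials, function(trial) {
    u <- check_covariates(model$basis$domain, trial$u)
    Phi <- evaluate_basis_matrix(model$basis, u)
    cc <- list(Phi = Phi, u = u)
    if (!inherits(model$C, "clds_weights") || "C" %in% model$fixed)
      cc$C <- eval_param_seq(model$C, model$basis, u, Phi)
    if (!inherits(model$d, "clds_weights") || "d" %in% model$fixed)
      cc$d <- t(matrix(eval_param_seq(model$d, model$basis, u, Phi), model$N))
    cc
  })
}

trial_params <- function(model, trial, cc) {
  as_rows <- function(arr) t(matrix(arr, nrow = dim(arr)[1L]))
  list(
    A = eval_param_seq(model$A, model$basis, cc$u, cc$Phi),
    b = as_rows(eval_param_seq(model$b, model$basis, cc$u, cc$Phi)),
    C = if (!is.null(cc$C)) cc$C else eval_param_seq(model$C, model$basis, cc$u, cc$Phi),
    d = if (!is.null(cc$d)) cc$d
        else as_rows(eval_param_seq(model$d, model$basis, cc$u, cc$Phi)),
    m = drop(eval_param(model$m, model$basis, drop(cc$u[1L, , drop = FALSE]))))
}

weight_prior_penalty <- function(model) {
  pen <- 0
  for (nm in c("A", "b", "C", "d", "m")) {
    pf <- model[[nm]]
    if (inherits(pf, "clds_weights") && !(nm %in% model$fixed))
      pen <- pen + 0.5 * sum(pf$W^2)
  }
  pen
}

#' Fit a CLDS model by MAP expectation-maximization
#'
#' Alternates exact Kalman-smoothing E-steps with closed-form conditional
#' M-steps: one Sylvester-equation regression per parameter function (the
#' dynamics matrix and bias jointly, the emission matrix and offset jointly
#' when both are learned, and the initial mean), followed by expected-residual
#' covariance updates. Each conditional maximization cannot decrease the
#' penalized marginal log-likelihood (log-likelihood minus the Gaussian weight
#' prior penalty), so the recorded objective trace is non-decreasing.
#'
#' Learned parameter functions are initialized at draws from their GP priors;
#' frozen functions (`C` and/or `d` supplied with `learn_* = FALSE`) are used
#' as given and never updated.
#'
#' @param trialset Training data ([trial_set()]).
#' @param basis A [build_basis()] on the trial set's domain.
#' @param D Latent dimension.
#' @param max_iter Maximum EM iterations; `max_iter = 0` returns the
#'   initialization unchanged.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed for the prior-sample initialization.
#' @param C,d Optional emission matrix / offset functions. By default `C` is
#'   learned and `d` is frozen at zero.
#' @param learn_C,learn_d Whether to update `C` / `d` in the M-steps.
#' @param learn_Q1 Whether to update `Q1` (with few trials this update is
#'   noisy; set `FALSE` to keep the initial value, default identity).
#' @param Q1,Q,R Initial covariances (defaults: identity, `0.1 I`, `0.1 I`).
#' @param init_model Optional [clds_model()] to initialize from (overrides
#'   the prior-sample initialization).
#' @param verbose Print the objective each iteration.
#' @return An object of class `clds_fit`: list with the fitted `model`, a
#'   `trace` data frame (iteration, log-likelihood, penalized objective), and
#'   a `converged` flag.
#' @export
fit_em <- function(trialset, basis, D, max_iter = 200L, tol = 1e-6,
                   seed = NULL, C = NULL, d = NULL,
                   learn_C = is.null(C), learn_d = FALSE,
                   learn_Q1 = TRUE, Q1 = NULL, Q = NULL, R = NULL,
                   init_model = NULL, verbose = FALSE) {
  stopifnot(inherits(trialset, "clds_trialset"), n_trials(trialset) >= 1L)
  N <- ncol(trialset$trials[[1L]]$y)
  if (is.null(init_model)) {
    sd_seed <- function(off) if (is.null(seed)) NULL else seed + off
    A0 <- sample_function(basis, D, D, "A", sd_seed(1L))
    b0 <- sample_function(basis, D, 1L, "b", sd_seed(2L))
    m0 <- sample_function(basis, D, 1L, "m", sd_seed(3L))
    C0 <- if (is.null(C)) sample_function(basis, N, D, "C", sd_seed(4L)) else C
    d0 <- if (is.null(d)) {
      if (learn_d) sample_function(basis, N, 1L, "d", sd_seed(5L)) else zero_fn(N)
    } else d
    fixed <- c(if (!learn_C) "C", if (!learn_d) "d")
    model <- clds_model(basis, D, N, A0, b0, C0, d0, m0,
                        Q1 = if (is.null(Q1)) diag(D) else Q1,
                        Q = if (is.null(Q)) 0.1 * diag(D) else Q,
                        R = if (is.null(R)) 0.1 * diag(N) else R,
                        fixed = fixed)
  } else model <- init_model
  trace <- data.frame(iter = integer(0), loglik = numeric(0),
                      objective = numeric(0))
  if (max_iter == 0L)
    return(structure(list(model = model, trace = trace, converged = FALSE),
                     class = "clds_fit"))
  cache <- make_fit_cache(model, trialset)
  emissions_free <- learn_C || learn_d
  converged <- FALSE
  prev_obj <- -Inf
  for (it in seq_len(max_iter)) {
    stats <- e_step(model, trialset, cache, emissions = emissions_free,
                    learn_d = learn_d)
    obj <- stats$loglik - weight_prior_penalty(model)
    if (!is.finite(obj))
      stop("EM aborted: non-finite objective at iteration ", it,
           " (loglik = ", stats$loglik, ")")
    trace <- rbind(trace, data.frame(iter = it, loglik = stats$loglik,
                                     objective = obj))
    if (verbose) message(sprintf("iter %3d  objective %.6f", it, obj))
    if (it > 1L && abs(obj - prev_obj) < tol * (abs(prev_obj) + 1e-10)) {
      converged <- TRUE
      break
    }
    prev_obj <- obj
    dyn <- m_step_dynamics(stats, model$Q)
    model$A <- dyn$A; model$b <- dyn$b
    if (emissions_free) {
      em <- m_step_emissions(stats, model$R)
      if (learn_C) model$C <- em$C
      if (learn_d && !is.null(em$d)) model$d <- em$d
    }
    model$m <- m_step_initial(stats, model$Q1)
    covs <- update_covariances(stats, model, trialset, cache,
                               learn_Q1 = learn_Q1)
    model$Q1 <- covs$Q1; model$Q <- covs$Q; model$R <- covs$R
  }
  structure(list(model = model, trace = trace, converged = converged),
            class = "clds_fit")
}

#' @export
print.clds_fit <- function(x, ...) {
  cat(sprintf("<clds_fit> %d EM iteration(s), final objective %.4f, %s\n",
              nrow(x$trace), utils::tail(x$trace$objective, 1L),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Grid search over GP-prior hyperparameters via held-out co-smoothing
#'
#' For each grid point `{L, kappa, sigma2}`, fits the model on a random 80%
#' of trials and scores the held-out 20% by mean co-smoothing R-squared;
#' returns the best configuration (ties broken by grid order) with the full
#' score table. Held-out marginal log-likelihood is reported alongside.
#'
#' @param trialset A [trial_set()] with at least 5 trials.
#' @param grid A data frame with columns among `L`, `kappa`, `sigma2`
#'   (missing columns keep the domain's values).
#' @param D Latent dimension.
#' @param seed Integer seed controlling the trial split and fits.
#' @param split Training fraction of trials.
#' @param top_k Number of held-out neurons scored per grid point.
#' @param ... Further arguments passed to [fit_em()] (e.g. frozen `C`).
#' @return A list with `best` (the selected grid row), `table` (grid plus
#'   `cosmoothing` and `test_loglik` columns), and `split` indices.
#' @export
select_hyperparameters <- function(trialset, grid, D, seed = 1L, split = 0.8,
                                   top_k = 5L, ...) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L) stop("hyperparameter grid is empty")
  K <- n_trials(trialset)
  if (K < 5L) stop("hyperparameter selection needs at least 5 trials")
  idx_train <- with_local_seed(seed, sort(sample.int(K, max(1L, round(split * K)))))
  idx_test <- setdiff(seq_len(K), idx_train)
  train <- trial_set(trialset$trials[idx_train], trialset$domain, trialset$metadata)
  test <- trial_set(trialset$trials[idx_test], trialset$domain, trialset$metadata)
  score <- numeric(nrow(grid)); tll <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    dims <- lapply(trialset$domain$dims, function(dm) {
      condition_dim(dm$kind, dm$lower, dm$upper,
                    lengthscale = if ("kappa" %in% names(grid)) grid$kappa[g] else dm$lengthscale,
                    variance = if ("sigma2" %in% names(grid)) grid$sigma2[g] else dm$variance,
                    levels = dm$levels)
    })
    dom <- condition_domain(dims)
    Lg <- if ("L" %in% names(grid)) grid$L[g] else 15L
    basis <- build_basis(dom, Lg)
    ts_train <- trial_set(train$trials, dom, train$metadata)
    ts_test <- trial_set(test$trials, dom, test$metadata)
    fit <- fit_em(ts_train, basis, D, seed = seed, ...)
    cs <- cosmoothing(fit$model, ts_test, top_k = top_k)
    score[g] <- cs$mean
    tll[g] <- sum(vapply(ts_test$trials, function(tr)
      kalman_filter(fit$model, tr)$loglik, numeric(1)))
  }
  table <- cbind(grid, cosmoothing = score, test_loglik = tll)
  best <- which.max(score)
  list(best = grid[best, , drop = FALSE], table = table,
       split = list(train = idx_train, test = idx_test))
}
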