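#' Wrap an analytic (closed-form) parameter function
#'
#' Parameter functions of a CLDS model are usually weight-parameterized
#' ([function_weights()]), but ground-truth simulators and frozen parameters
#' may instead supply an exact closed-form function of the covariate.
#'
#' @param fn A function taking one covariate point (numeric vector) and
#'   returning a `D1 x D2` numeric matrix.
#' @param D1,D2 Output dimensions.
#' @param label Parameter name.
#' @return An object of class `clds_analytic_fn`.
#' @export
analytic_fn <- function(fn, D1, D2 = 1L, label = "M") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, D1 = as.integer(D1), D2 = as.integer(D2), label = label),
            class = "clds_analytic_fn")
}

zero_fn <- function(D1, D2 = 1L, label = "d") {
  analytic_fn(function(u) matrix(0, D1, D2), D1, D2, label)
}

param_dims <- function(pf) c(pf$D1, pf$D2)

eval_param <- function(pf, basis, u) {
  if (inherits(pf, "clds_weights")) {
    evaluate_function(pf, basis, u)
  } else if (inherits(pf, "clds_analytic_fn")) {
    u <- drop(check_covariates(basis$domain, u))
    M <- pf$fn(u)
    matrix(as.numeric(M), pf$D1, pf$D2)
  } else stop("not a parameter function")
}

eval_param_seq <- function(pf, basis, u, Phi = NULL) {
  if (inherits(pf, "clds_weights")) return(evaluate_function_seq(pf, basis, u, Phi))
  U <- check_covariates(basis$domain, u)
  out <- array(0, c(pf$D1, pf$D2, nrow(U)))
  for (t in seq_len(nrow(U)))
    out[, , t] <- matrix(as.numeric(pf$fn(drop(U[t, ]))), pf$D1, pf$D2)
  out
}

#' Construct a conditionally linear dynamical system model
#'
#' The generative model, conditioned on a covariate sequence `u_{1:T}`, is the
#' time-varying linear-Gaussian state-space model
#' \deqn{x_1 \sim N(m(u_1), Q_1), \quad
#'       x_{t+1} = A(u_t) x_t + b(u_t) + \epsilon_t, \quad \epsilon_t \sim N(0, Q),}
#' \deqn{y_t = C(u_t) x_t + d(u_t) + \omega_t, \quad \omega_t \sim N(0, R),}
#' where every parameter is a function of the observed covariate, represented
#' either by basis weights or analytically.
#'
#' @param basis A [build_basis()] object shared by all parameter functions.
#' @param D Latent dimension.
#' @param N Observation (neuron) dimension.
#' @param A,b,C,d,m Parameter functions ([function_weights()] or
#'   [analytic_fn()]) with shapes `D x D`, `D x 1`, `N x D`, `N x 1`, `D x 1`.
#'   `d` defaults to the zero function (and is frozen by default).
#' @param Q1,Q,R Symmetric positive-definite covariances (`D x D`, `D x D`,
#'   `N x N`).
#' @param fixed Character vector naming frozen parameter functions (subset of
#'   `c("A","b","C","d","m")`); frozen functions are not updated by EM.
#' @return An object of class `clds_model`.
#' @export
clds_model <- function(basis, D, N, A, b, C, d = NULL, m, Q1, Q, R,
                       fixed = "d") {
  D <- as.integer(D); N <- as.integer(N)
  if (is.null(d)) d <- zero_fn(N, 1L, "d")
  expect_shape <- function(pf, D1, D2, nm) {
    if (!identical(param_dims(pf), c(as.integer(D1), as.integer(D2))))
      stop(sprintf("parameter %s must be %d x %d", nm, D1, D2))
  }
  expect_shape(A, D, D, "A"); expect_shape(b, D, 1L, "b")
  expect_shape(C, N, D, "C"); expect_shape(d, N, 1L, "d")
  expect_shape(m, D, 1L, "m")
  Q1 <- check_spd(Q1, D, "Q1"); Q <- check_spd(Q, D, "Q"); R <- check_spd(R, N, "R")
  structure(list(basis = basis, D = D, N = N,
                 A = A, b = b, C = C, d = d, m = m,
                 Q1 = Q1, Q = Q, R = R,
                 fixed = intersect(fixed, c("A", "b", "C", "d", "m"))),
            class = "clds_model")
}

#' @export
print.clds_model <- function(x, ...) {
  wts <- vapply(c("A", "b", "C", "d", "m"),
                function(nm) inherits(x[[nm]], "clds_weights"), logical(1))
  cat(sprintf("<clds_model> D = %d latent, N = %d observed, basis L = %d\n",
              x$D, x$N, x$basis$L))
  cat("  parameter functions:",
      paste(sprintf("%s[%s]", c("A", "b", "C", "d", "m"),
                    ifelse(wts, "weights", "analytic")), collapse = " "), "\n")
  if (length(x$fixed)) cat("  frozen:", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

check_spd <- function(M, n, nm) {
  M <- as.matrix(M)
  if (!identical(dim(M), c(as.integer(n), as.integer(n))))
    stop(sprintf("%s must be %d x %d", nm, n, n))
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop(sprintf("%s must be positive definite (min eigenvalue %g)",
                                 nm, min(ev)))
  M
}

#' Evaluate all model parameter functions at a covariate point
#'
#' @param model A [clds_model()].
#' @param u A single covariate point.
#' @return A list with matrices `A` (`D x D`), `b` (`D`-vector), `C` (`N x D`),
#'   `d` (`N`-vector), and `m` (`D`-vector).
#' @export
evaluate_params <- function(model, u) {
  list(A = eval_param(model$A, model$basis, u),
       b = drop(eval_param(model$b, model$basis, u)),
       C = eval_param(model$C, model$basis, u),
       d = drop(eval_param(model$d, model$basis, u)),
       m = drop(eval_param(model$m, model$basis, u)))
}

# Evaluate parameter functions along a whole covariate sequence; returns
# arrays A (D,D,T), C (N,D,T) and matrices b (T,D), d (T,N), plus m(u_1).
evaluate_params_seq <- function(model, u, Phi = NULL) {
  if (is.null(dim(u))) u <- matrix(u, ncol = domain_ndim(model$basis$domain))
  if (is.null(Phi)) Phi <- evaluate_basis_matrix(model$basis, u)
  as_rows <- function(arr) t(matrix(arr, nrow = dim(arr)[1L]))  # (D1,1,T) -> T x D1
  list(A = eval_param_seq(model$A, model$basis, u, Phi),
       b = as_rows(eval_param_seq(model$b, model$basis, u, Phi)),
       C = eval_param_seq(model$C, model$basis, u, Phi),
       d = as_rows(eval_param_seq(model$d, model$basis, u, Phi)),
       m = drop(eval_param(model$m, model$basis, drop(u[1L, , drop = FALSE]))))
}

#' Construct a single trial
#'
#' @param y `T x N` observation matrix (firing rates).
#' @param u `T x d` covariate matrix (a vector is treated as one column).
#' @param x Optional `T x D` latent matrix (known for simulated data).
#' @return An object of class `clds_trial`.
#' @export
clds_trial <- function(y, u, x = NULL) {
  y <- as.matrix(y)
  if (is.null(dim(u))) u <- matrix(as.numeric(u), ncol = 1L)
  u <- as.matrix(u)
  if (nrow(y) != nrow(u)) stop("y and u must share the number of time steps T")
  if (anyNA(y) || anyNA(u)) stop("trials must not contain missing values")
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (nrow(x) != nrow(y)) stop("x must share T with y")
  }
  structure(list(y = y, u = u, x = x), class = "clds_trial")
}

#' Bundle trials into a trial set
#'
#' The universal data container: `K >= 1` trials of (observations, covariates)
#' sharing the neuron count and covariate dimensionality, plus the condition
#' domain and free-form metadata.
#'
#' @param trials A list of [clds_trial()] objects.
#' @param domain The [condition_domain()] of the covariates.
#' @param metadata Optional named list.
#' @return An object of class `clds_trialset`.
#' @export
trial_set <- function(trials, domain, metadata = list()) {
  if (length(trials) < 1L) stop("a trial set needs at least one trial")
  trials <- lapply(trials, function(tr) {
    if (!inherits(tr, "clds_trial")) tr <- clds_trial(tr$y, tr$u, tr$x)
    tr
  })
  N <- ncol(trials[[1L]]$y); d <- ncol(trials[[1L]]$u)
  for (tr in trials) {
    if (ncol(tr$y) != N) stop("all trials must share the neuron count N")
    if (ncol(tr$u) != d) stop("all trials must share the covariate dimensionality")
    check_covariates(domain, tr$u)
  }
  structure(list(trials = trials, domain = domain, metadata = metadata),
            class = "clds_trialset")
}

#' @export
print.clds_trialset <- function(x, ...) {
  Ts <- vapply(x$trials, function(tr) nrow(tr$y), integer(1))
  cat(sprintf("<clds_trialset> K = %d trials, N = %d neurons, T in [%d, %d]\n",
              length(x$trials), ncol(x$trials[[1L]]$y), min(Ts), max(Ts)))
  invisible(x)
}

n_trials <- function(ts) length(ts$trials)

#' Sample a trial from the generative model
#'
#' Simulates latents and observations along a given covariate sequence:
#' `x_1 ~ N(m(u_1), Q1)`, `x_{t+1} = A(u_t) x_t + b(u_t) + eps_t`,
#' `y_t = C(u_t) x_t + d(u_t) + omega_t`.
#'
#' @param model A [clds_model()].
#' @param u_seq `T x d` covariate matrix (or vector for scalar covariates).
#' @param seed Optional integer for reproducible draws.
#' @return A [clds_trial()] with latents `x` attached.
#' @export
sample_trial <- function(model, u_seq, seed = NULL) {
  if (is.null(dim(u_seq))) u_seq <- matrix(as.numeric(u_seq), ncol = 1L)
  u_seq <- check_covariates(model$basis$domain, u_seq)
  Tn <- nrow(u_seq)
  pars <- evaluate_params_seq(model, u_seq)
  cQ1 <- chol(model$Q1); cQ <- chol(model$Q); cR <- chol(model$R)
  with_local_seed(seed, {
    x <- matrix(0, Tn, model$D); y <- matrix(0, Tn, model$N)
    x[1L, ] <- pars$m + drop(crossprod(cQ1, stats::rnorm(model$D)))
    for (t in seq_len(Tn)) {
      Ct <- matrix(pars$C[, , t], model$N, model$D)
      y[t, ] <- Ct %*% x[t, ] + pars$d[t, ] +
        drop(crossprod(cR, stats::rnorm(model$N)))
      if (t < Tn) {
        At <- matrix(pars$A[, , t], model$D, model$D)
        x[t + 1L, ] <- At %*% x[t, ] + pars$b[t, ] +
          drop(crossprod(cQ, stats::rnorm(model$D)))
      }
    }
    clds_trial(y, u_seq, x)
  })
}
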