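#' Expand regressors into the Kronecker feature space
#'
#' The conditionally linear regression `y_n = M(u_n) x_n + eps_n` with a
#' weight-parameterized `M` is an ordinary Bayesian linear regression in the
#' expanded features `z_n = phi(u_n) (x) x_n`, so that `y_n = W^T z_n + eps_n`.
#'
#' @param phi_u Length-`L` basis evaluation at the condition.
#' @param x Length-`D2` regressor vector.
#' @return Length `D2*L` feature vector (standard Kronecker element order).
#' @export
expand_features <- function(phi_u, x) {
  as.numeric(kronecker(as.numeric(phi_u), as.numeric(x)))
}

#' Assemble a conditionally linear regression problem
#'
#' Either raw design/target matrices (`Z`, `Y`) or pre-accumulated moment
#' matrices (`StS = sum E[z z^T]`, `StY = sum E[z] y^T`) may be supplied;
#' EM always supplies moments, so the raw design never needs materializing.
#'
#' @param Sigma `D1 x D1` SPD noise covariance of the regression residuals.
#' @param Z Optional `n x (D2*L)` design matrix of expanded features.
#' @param Y Optional `n x D1` target matrix.
#' @param StS,StY Optional moment matrices, `(D2*L) x (D2*L)` and
#'   `(D2*L) x D1`; computed from `Z`, `Y` when omitted.
#' @return An object of class `clds_regression`.
#' @export
clr_problem <- function(Sigma, Z = NULL, Y = NULL, StS = NULL, StY = NULL) {
  Sigma <- check_spd(Sigma, nrow(as.matrix(Sigma)), "Sigma")
  if (is.null(StS)) {
    if (is.null(Z) || is.null(Y)) stop("supply either (Z, Y) or (StS, StY)")
    Z <- as.matrix(Z); Y <- as.matrix(Y)
    if (nrow(Z) != nrow(Y)) stop("Z and Y must have matching rows")
    StS <- crossprod(Z); StY <- crossprod(Z, Y)
  }
  StS <- as.matrix(StS); StY <- as.matrix(StY)
  if (nrow(StY) != nrow(StS) || ncol(StY) != nrow(Sigma))
    stop("moment matrices have inconsistent shapes")
  if (!all(is.finite(StS)) || !all(is.finite(StY))) stop("moments must be finite")
  structure(list(StS = (StS + t(StS)) / 2, StY = StY, Sigma = Sigma),
            class = "clds_regression")
}

#' MAP weights of a conditionally linear regression
#'
#' Maximizes the penalized Gaussian log-likelihood
#' \deqn{\log p(Y | W, Z) - \tfrac12 \|W\|_F^2,}
#' whose stationarity condition is the Sylvester equation
#' \deqn{Z^\top Z\, W + W\, \Sigma = Z^\top Y.}
#' Because `Sigma` is symmetric positive definite it is solved exactly by
#' diagonalizing `Sigma`: with `Sigma = V diag(lambda) V^T`, each column of
#' `W V` solves an SPD shifted system `(Z^T Z + lambda_j I) w = (Z^T Y V)_j`.
#' When `Sigma = sigma^2 I` this reduces to the ridge estimate
#' `(Z^T Z + sigma^2 I)^{-1} Z^T Y`.
#'
#' @param problem A [clr_problem()].
#' @return A `(D2*L) x D1` weight matrix with attribute `"residual"`, the
#'   Frobenius norm of the Sylvester residual relative to `||Z^T Y||_F`.
#' @export
solve_map_weights <- function(problem) {
  stopifnot(inherits(problem, "clds_regression"))
  W <- sylvester_spd(problem$StS, problem$Sigma, problem$StY)
  bnorm <- sqrt(sum(problem$StY^2))
  resid <- sqrt(sum((problem$StS %*% W + W %*% problem$Sigma - problem$StY)^2))
  rel <- if (bnorm > 0) resid / bnorm else 0
  if (rel > 1e-6)
    stop(sprintf("Sylvester solve failed: relative residual %g", rel))
  attr(W, "residual") <- rel
  W
}

# Solve S W + W Sigma = B for symmetric PSD S and SPD Sigma.
sylvester_spd <- function(S, Sigma, B) {
  eg <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(eg$values) <= 0) stop("Sigma must be positive definite")
  Bt <- B %*% eg$vectors
  Wt <- matrix(0, nrow(B), ncol(B))
  n <- nrow(S); In <- diag(n)
  for (j in seq_len(ncol(B)))
    Wt[, j] <- solve(S + eg$values[j] * In, Bt[, j])
  Wt %*% t(eg$vectors)
}
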