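#' Build a truncated Fourier-feature basis approximating a GP prior
#'
#' Constructs, per domain dimension, a fixed set of scaled trigonometric basis
#' functions \eqn{\phi_\ell} such that the finite expansion
#' \eqn{M(u) = \sum_\ell w_\ell \phi_\ell(u)} with i.i.d. standard-normal
#' weights approximates a zero-mean GP with a squared-exponential kernel
#' (periodic squared-exponential on periodic dimensions) of variance
#' \eqn{\sigma^2} and length-scale \eqn{\kappa}. The prior variance is
#' absorbed into the basis scales so weights are always standard normal.
#'
#' Periodic dimensions use the exact Fourier series of the periodic SE kernel
#' \eqn{k(\tau) = \sigma^2 \exp(-2\sin^2(\pi\tau/P)/\kappa_a^2)} (with
#' \eqn{\kappa_a = 2\pi\kappa/P} the length-scale in angular units), whose
#' coefficients are modified Bessel functions; truncation keeps the leading
#' `L` functions of `1, cos, sin, cos(2.), sin(2.), ...`. Interval and
#' discrete-embedded dimensions use regular (equi-spaced-frequency) Fourier
#' features on a padded interval, scaled by the SE spectral density, which is
#' the Fourier series of the periodized SE kernel; the padding (a quarter of
#' the interval width or three length-scales, whichever is larger) keeps the
#' wrap-around image of the kernel negligible over observable distances.
#'
#' Multi-dimensional domains combine per-dimension bases by tensor product
#' (total `L` is the product), which realizes the product SE kernel.
#'
#' @param domain A [condition_domain()].
#' @param L Truncation level(s): one positive integer per dimension (recycled).
#' @return An object of class `clds_basis` with total length `prod(L)`.
#' @export
build_basis <- function(domain, L) {
  stopifnot(inherits(domain, "clds_domain"))
  nd <- domain_ndim(domain)
  L <- as.integer(rep_len(L, nd))
  if (any(L < 1L)) stop("truncation level L must be >= 1 per dimension")
  per_dim <- vector("list", nd)
  for (j in seq_len(nd)) {
    dm <- domain$dims[[j]]
    Lj <- L[j]
    npairs <- ceiling((Lj - 1L) / 2L)
    harmonics <- if (npairs > 0L) seq_len(npairs) else integer(0)
    if (Lj == 1L) {
      # degenerate constant basis: the kappa -> Inf limit, k = sigma^2
      per_dim[[j]] <- list(freq = 0, trig = "const", scale = sqrt(dm$variance),
                           omega = 0, origin = dm$lower, L = 1L)
      next
    }
    if (dm$kind == "periodic") {
      period <- dm$upper - dm$lower
      kappa_ang <- 2 * pi * dm$lengthscale / period
      # k(psi) = sigma^2 exp((cos(psi) - 1) / kappa_ang^2)
      xarg <- 1 / kappa_ang^2
      # Fourier coefficients of the periodic SE kernel; exponentially scaled
      # Bessel ratios avoid overflow for small kappa.
      coef0 <- dm$variance * besselI(xarg, 0, expon.scaled = TRUE)
      coefs <- if (npairs > 0L)
        2 * dm$variance * besselI(xarg, harmonics, expon.scaled = TRUE) else numeric(0)
      omega <- 2 * pi / period
    } else {
      width <- dm$upper - dm$lower
      pad <- max(0.25 * width, 3 * dm$lengthscale)
      period <- width + 2 * pad
      omega <- 2 * pi / period
      spec <- function(w) dm$variance * dm$lengthscale * sqrt(2 * pi) *
        exp(-0.5 * dm$lengthscale^2 * w^2)
      coef0 <- spec(0) / period
      coefs <- if (npairs > 0L) 2 * spec(omega * harmonics) / period else numeric(0)
    }
    # basis order: constant, cos(1), sin(1), cos(2), sin(2), ... truncated at Lj
    freq <- c(0, rep(harmonics, each = 2L))[seq_len(Lj)]
    trig <- c("const", rep(c("cos", "sin"), npairs))[seq_len(Lj)]
    amp2 <- c(coef0, rep(coefs, each = 2L))[seq_len(Lj)]
    per_dim[[j]] <- list(freq = freq, trig = trig, scale = sqrt(pmax(amp2, 0)),
                         omega = omega, origin = dm$lower, L = Lj)
  }
  structure(list(domain = domain, L_per_dim = L, L = prod(L), per_dim = per_dim),
            class = "clds_basis")
}

#' @export
print.clds_basis <- function(x, ...) {
  cat("<clds_basis> L =", x$L,
      if (domain_ndim(x$domain) > 1L)
        paste0("(", paste(x$L_per_dim, collapse = " x "), ")") else "", "\n")
  invisible(x)
}

eval_basis_dim <- function(pd, uj) {
  ang <- (uj - pd$origin) * pd$omega
  out <- matrix(0, length(uj), pd$L)
  for (l in seq_len(pd$L)) {
    out[, l] <- switch(pd$trig[l],
      const = pd$scale[l],
      cos   = pd$scale[l] * cos(pd$freq[l] * ang),
      sin   = pd$scale[l] * sin(pd$freq[l] * ang))
  }
  out
}

#' Evaluate the basis at covariate points
#'
#' @param basis A [build_basis()] object.
#' @param u A covariate point (length-`d` vector) or `T x d` matrix.
#' @return For a vector `u`, a length-`L` vector; for a matrix, a `T x L`
#'   matrix with row `t` equal to \eqn{\phi(u_t)}.
#' @export
evaluate_basis <- function(basis, u) {
  single <- is.null(dim(u))
  Phi <- evaluate_basis_matrix(basis, u)
  if (single) drop(Phi) else Phi
}

evaluate_basis_matrix <- function(basis, u) {
  U <- check_covariates(basis$domain, u)
  Phi <- eval_basis_dim(basis$per_dim[[1L]], U[, 1L])
  nd <- domain_ndim(basis$domain)
  if (nd > 1L) {
    for (j in 2:nd) {
      Pj <- eval_basis_dim(basis$per_dim[[j]], U[, j])
      L1 <- ncol(Phi); L2 <- ncol(Pj)
      # row-wise Kronecker: matches kronecker(phi_1, phi_2) element order
      Phi <- Phi[, rep(seq_len(L1), each = L2), drop = FALSE] *
        Pj[, rep(seq_len(L2), times = L1), drop = FALSE]
    }
  }
  Phi
}

#' Implied (approximate) prior kernel of a basis
#'
#' Returns the Gram matrix \eqn{\hat k(u, u') = \phi(u)^\top \phi(u')} of the
#' finite-feature kernel, which approximates the target squared-exponential
#' kernel and is positive semidefinite by construction.
#'
#' @param basis A [build_basis()] object.
#' @param u,u2 Covariate points (vectors or matrices); `u2` defaults to `u`.
#' @return A `nrow(u) x nrow(u2)` kernel matrix.
#' @export
basis_kernel <- function(basis, u, u2 = u) {
  P1 <- evaluate_basis_matrix(basis, u)
  P2 <- evaluate_basis_matrix(basis, u2)
  tcrossprod(P1, P2)
}

#' Weights of a matrix-valued parameter function
#'
#' Wraps a `(D2*L) x D1` weight matrix `W` so that the function value is
#' \eqn{M(u) = W^\top (\phi(u) \otimes I_{D2})}, a `D1 x D2` matrix. Row
#' `(l-1)*D2 + j` of `W` holds the weights \eqn{w_\ell^{(ij)}} pairing basis
#' function `l` with regressor coordinate `j` (standard Kronecker order).
#'
#' @param W Numeric matrix of shape `(D2*L) x D1`.
#' @param D1,D2 Output dimensions of the function value.
#' @param L Basis truncation length.
#' @param label Which parameter this is (`"A"`, `"b"`, `"C"`, `"d"`, `"m"`, or free-form).
#' @return An object of class `clds_weights`.
#' @export
function_weights <- function(W, D1, D2, L, label = "M") {
  W <- as.matrix(W)
  if (nrow(W) != D2 * L || ncol(W) != D1)
    stop(sprintf("weight matrix must be (D2*L) x D1 = %d x %d, got %d x %d",
                 D2 * L, D1, nrow(W), ncol(W)))
  if (!all(is.finite(W))) stop("weights must be finite")
  structure(list(W = W, D1 = as.integer(D1), D2 = as.integer(D2),
                 L = as.integer(L), label = label),
            class = "clds_weights")
}

#' Sample a parameter function from its GP prior
#'
#' Draws all weights i.i.d. standard normal, which (through the scaled basis)
#' realizes an approximate GP prior with the kernel of [basis_kernel()] on
#' every entry of the function.
#'
#' @param basis A [build_basis()] object.
#' @param D1,D2 Output dimensions.
#' @param label Passed to [function_weights()].
#' @param seed Optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is left untouched.
#' @return A `clds_weights` object.
#' @export
sample_function <- function(basis, D1, D2 = 1L, label = "M", seed = NULL) {
  W <- with_local_seed(seed, matrix(stats::rnorm(D2 * basis$L * D1),
                                    nrow = D2 * basis$L, ncol = D1))
  function_weights(W, D1, D2, basis$L, label)
}

#' Evaluate a weight-parameterized function at one covariate point
#'
#' @param weights A [function_weights()] object.
#' @param basis The basis the weights were built against.
#' @param u A single covariate point.
#' @return A `D1 x D2` numeric matrix.
#' @export
evaluate_function <- function(weights, basis, u) {
  if (weights$L != basis$L)
    stop("weights were built for L = ", weights$L, ", basis has L = ", basis$L)
  phi <- evaluate_basis(basis, u)
  # M(u) = W^T (phi(u) (x) I_D2)
  crossprod(weights$W, kronecker(matrix(phi, ncol = 1L), diag(weights$D2)))
}

#' Evaluate a weight-parameterized function along a covariate sequence
#'
#' @param weights A [function_weights()] object.
#' @param basis The matching basis.
#' @param u A `T x d` covariate matrix (or vector of T scalar covariates).
#' @param Phi Optional precomputed `T x L` basis matrix for `u`.
#' @return A `D1 x D2 x T` array.
#' @export
evaluate_function_seq <- function(weights, basis, u, Phi = NULL) {
  if (is.null(Phi)) {
    if (is.null(dim(u))) u <- matrix(u, ncol = domain_ndim(basis$domain))
    Phi <- evaluate_basis_matrix(basis, u)
  }
  if (ncol(Phi) != weights$L) stop("basis length mismatch")
  Wm <- weights_as_L_matrix(weights)          # L x (D2*D1)
  Mb <- Phi %*% Wm                            # T x (D2*D1), [t, j + (i-1)*D2]
  arr <- array(t(Mb), c(weights$D2, weights$D1, nrow(Phi)))
  aperm(arr, c(2L, 1L, 3L))
}

# reshape W ((D2*L) x D1, rows (l-1)*D2+j) into L x (D2*D1), cols j + (i-1)*D2
weights_as_L_matrix <- function(weights) {
  W3 <- array(weights$W, c(weights$D2, weights$L, weights$D1))
  matrix(aperm(W3, c(2L, 1L, 3L)), nrow = weights$L)
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
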