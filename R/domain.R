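#' Describe one dimension of the covariate (condition) space
#'
#' A condition domain is built from one or more dimensions, each carrying the
#' squared-exponential prior hyperparameters for parameter functions of that
#' covariate: a length-scale `lengthscale` (in covariate units) controlling how
#' fast the linear-system parameters change with the covariate, and a prior
#' `variance` controlling their magnitude.
#'
#' @param kind One of `"periodic"` (e.g. an angle on `[0, 2*pi)`),
#'   `"interval"` (a bounded continuous covariate), or `"discrete_embedded"`
#'   (a discrete covariate such as a task epoch indicator, embedded on a
#'   continuous interval so that correlation between levels is governed by
#'   `lengthscale`).
#' @param lower,upper Domain bounds in covariate units (`lower < upper`). For
#'   periodic dimensions the period is `upper - lower` and values are wrapped.
#'   For `discrete_embedded` the bounds default to the range of `levels`.
#' @param lengthscale Positive squared-exponential length-scale.
#' @param variance Positive prior variance of each parameter-function entry.
#' @param levels For `discrete_embedded` only: the admissible covariate values.
#' @return An object of class `clds_dim`.
#' @export
condition_dim <- function(kind = c("periodic", "interval", "discrete_embedded"),
                          lower = NULL, upper = NULL,
                          lengthscale = 1, variance = 1, levels = NULL) {
  kind <- match.arg(kind)
  if (kind == "discrete_embedded") {
    if (is.null(levels) || length(levels) < 2L)
      stop("discrete_embedded dimensions need at least two 'levels'")
    levels <- sort(unique(as.numeric(levels)))
    if (is.null(lower)) lower <- min(levels)
    if (is.null(upper)) upper <- max(levels)
  }
  if (is.null(lower) || is.null(upper))
    stop("'lower' and 'upper' bounds are required")
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("invalid domain: need finite bounds with lower < upper")
  if (!is.finite(lengthscale) || lengthscale <= 0)
    stop("invalid domain: lengthscale must be > 0")
  if (!is.finite(variance) || variance <= 0)
    stop("invalid domain: variance must be > 0")
  structure(
    list(kind = kind, lower = as.numeric(lower), upper = as.numeric(upper),
         lengthscale = as.numeric(lengthscale), variance = as.numeric(variance),
         levels = levels),
    class = "clds_dim")
}

#' Build a condition domain from per-dimension descriptors
#'
#' @param ... One or more [condition_dim()] objects (or a single list of them).
#' @return An object of class `clds_domain`.
#' @export
condition_domain <- function(...) {
  dims <- list(...)
  if (length(dims) == 1L && !inherits(dims[[1L]], "clds_dim")) dims <- dims[[1L]]
  if (length(dims) == 0L) stop("a condition domain needs at least one dimension")
  ok <- vapply(dims, inherits, logical(1), "clds_dim")
  if (!all(ok)) stop("all arguments must be condition_dim() objects")
  structure(list(dims = dims), class = "clds_domain")
}

#' @export
print.clds_domain <- function(x, ...) {
  cat("<clds_domain> with", length(x$dims), "dimension(s)\n")
  for (i in seq_along(x$dims)) {
    d <- x$dims[[i]]
    cat(sprintf("  [%d] %s on [%g, %g), kappa = %g, sigma2 = %g\n",
                i, d$kind, d$lower, d$upper, d$lengthscale, d$variance))
  }
  invisible(x)
}

domain_ndim <- function(domain) length(domain$dims)

#' Validate and canonicalize covariate values against a domain
#'
#' Periodic dimensions are wrapped into `[lower, upper)`. Values outside a
#' non-periodic interval, or not among the admissible levels of a
#' discrete-embedded dimension, raise an error (no silent extrapolation).
#'
#' @param domain A [condition_domain()].
#' @param u A numeric vector (one covariate point) or a `T x d` matrix.
#' @return A matrix of the same shape as `u` (vectors become `1 x d`).
#' @export
check_covariates <- function(domain, u) {
  d <- domain_ndim(domain)
  if (is.null(dim(u))) u <- matrix(as.numeric(u), ncol = d)
  u <- as.matrix(u)
  if (ncol(u) != d)
    stop(sprintf("covariates have %d column(s); domain has %d dimension(s)",
                 ncol(u), d))
  if (anyNA(u) || !all(is.finite(u))) stop("covariates contain NA/non-finite values")
  tol <- 1e-8
  for (j in seq_len(d)) {
    dm <- domain$dims[[j]]
    if (dm$kind == "periodic") {
      period <- dm$upper - dm$lower
      u[, j] <- dm$lower + ((u[, j] - dm$lower) %% period)
    } else if (dm$kind == "discrete_embedded") {
      match_tol <- vapply(u[, j], function(v) any(abs(v - dm$levels) <= tol), logical(1))
      if (!all(match_tol))
        stop(sprintf("dimension %d: value not among admissible discrete levels", j))
    } else {
      if (any(u[, j] < dm$lower - tol | u[, j] > dm$upper + tol))
        stop(sprintf("dimension %d: covariate outside domain [%g, %g]",
                     j, dm$lower, dm$upper))
    }
  }
  u
}
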