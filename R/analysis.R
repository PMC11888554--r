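#' Analytic fixed points of the condition-indexed linear systems
#'
#' At each grid condition `u` solves `(I - A(u)) x* = b(u)` exactly, and
#' records the spectrum of `A(u)`. Conditions where `I - A(u)` is numerically
#' singular (an eigenvalue of `A` at 1, i.e. a line attractor) are flagged
#' per point rather than failing globally.
#'
#' @param model A [clds_model()].
#' @param u_grid Vector (scalar conditions) or matrix of grid conditions.
#' @return An object of class `clds_fixed_points`: list with `u_grid`,
#'   `points` (`n x D`), `eigvals` (`n x D` complex), `eig_angles` (`n x D`,
#'   eigenvector orientation in radians; `D = 2` only, else `NA`),
#'   `residual` (per-point solve residual) and `singular` (logical flags).
#' @export
fixed_points <- function(model, u_grid) {
  if (is.null(dim(u_grid))) u_grid <- matrix(u_grid, ncol = 1L)
  n <- nrow(u_grid); D <- model$D
  pts <- matrix(NA_real_, n, D)
  resid <- rep(NA_real_, n); singular <- rep(FALSE, n)
  spec <- dynamics_spectrum(model, u_grid)
  for (g in seq_len(n)) {
    pars <- evaluate_params(model, drop(u_grid[g, , drop = FALSE]))
    IA <- diag(D) - pars$A
    if (rcond(IA) < 1e-12) {
      singular[g] <- TRUE
      next
    }
    x <- solve(IA, pars$b)
    pts[g, ] <- x
    resid[g] <- sqrt(sum((IA %*% x - pars$b)^2))
  }
  structure(list(u_grid = u_grid, points = pts, eigvals = spec$eigvals,
                 eig_angles = spec$eig_angles, residual = resid,
                 singular = singular),
            class = "clds_fixed_points")
}

#' Spectrum of the dynamics matrix along a condition grid
#'
#' Dense eigendecomposition of `A(u)` at each grid point, with deterministic
#' ordering by descending modulus (ties by argument).
#'
#' @inheritParams fixed_points
#' @return A list with `u_grid`, `eigvals` (`n x D` complex matrix) and
#'   `eig_angles` (`n x D`; for `D = 2`, the orientation of each eigenvector
#'   in `[0, pi)`; `NA` for complex pairs or `D != 2`).
#' @export
dynamics_spectrum <- function(model, u_grid) {
  if (is.null(dim(u_grid))) u_grid <- matrix(u_grid, ncol = 1L)
  n <- nrow(u_grid); D <- model$D
  vals <- matrix(NA_complex_, n, D)
  angs <- matrix(NA_real_, n, D)
  for (g in seq_len(n)) {
    A <- evaluate_params(model, drop(u_grid[g, , drop = FALSE]))$A
    eg <- eigen(A)
    ord <- order(-Mod(eg$values), Arg(eg$values))
    vals[g, ] <- eg$values[ord]
    if (D == 2L) {
      for (j in seq_len(D)) {
        v <- eg$vectors[, ord[j]]
        if (max(abs(Im(v))) < 1e-10)
          angs[g, j] <- atan2(Re(v[2L]), Re(v[1L])) %% pi
      }
    }
  }
  list(u_grid = u_grid, eigvals = vals, eig_angles = angs)
}

#' Composite (condition-marginalized) dynamics field
#'
#' The condition-indexed linear fields are averaged over the empirical
#' distribution of the condition given latent position, estimated by pooling
#' the smoothed posterior modes `(x_t, u_t)` across trials and binning latent
#' space: within each bin the displacement `g(x) - x` is the average of
#' `A(u) x + b(u) - x` over the pooled conditions, with `x` taken at the bin
#' center. Occupancy per bin is recorded (the fraction of pooled posterior
#' points), matching the gray-scale convention of flow-field plots.
#'
#' @param model A fitted [clds_model()] with `D = 2`.
#' @param trialset Data whose posterior modes define the pooling.
#' @param n_bins Bins per latent dimension (default 25).
#' @return An object of class `clds_composite_field`: `centers_x`,
#'   `centers_y` (bin centers), `vectors` (`n_bins x n_bins x 2` displacement
#'   `g(x) - x`, `NA` where unoccupied), and `occupancy` (counts).
#' @export
composite_field <- function(model, trialset, n_bins = 25L) {
  if (model$D != 2L) stop("composite_field supports D = 2 latent spaces")
  xs <- NULL; As <- NULL; bs <- NULL
  for (trial in trialset$trials) {
    xh <- posterior_mode(model, trial)
    pars <- evaluate_params_seq(model, trial$u)
    xs <- rbind(xs, xh)
    As <- rbind(As, t(matrix(pars$A, 4L)))    # n x 4, col-major per point
    bs <- rbind(bs, pars$b)
  }
  if (is.null(xs) || nrow(xs) == 0L) {
    return(structure(list(centers_x = numeric(0), centers_y = numeric(0),
                          vectors = array(NA_real_, c(0L, 0L, 2L)),
                          occupancy = matrix(0L, 0L, 0L)),
                     class = "clds_composite_field"))
  }
  rng_x <- range(xs[, 1L]); rng_y <- range(xs[, 2L])
  brk_x <- seq(rng_x[1L], rng_x[2L], length.out = n_bins + 1L)
  brk_y <- seq(rng_y[1L], rng_y[2L], length.out = n_bins + 1L)
  ix <- pmin(pmax(findInterval(xs[, 1L], brk_x, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(xs[, 2L], brk_y, rightmost.closed = TRUE), 1L), n_bins)
  centers_x <- (brk_x[-1L] + brk_x[-(n_bins + 1L)]) / 2
  centers_y <- (brk_y[-1L] + brk_y[-(n_bins + 1L)]) / 2
  occupancy <- matrix(0L, n_bins, n_bins)
  vectors <- array(NA_real_, c(n_bins, n_bins, 2L))
  bin_id <- (iy - 1L) * n_bins + ix
  for (bid in unique(bin_id)) {
    sel <- which(bin_id == bid)
    bx <- ((bid - 1L) %% n_bins) + 1L
    by <- ((bid - 1L) %/% n_bins) + 1L
    occupancy[bx, by] <- length(sel)
    Abar <- matrix(colMeans(As[sel, , drop = FALSE]), 2L, 2L)
    bbar <- colMeans(bs[sel, , drop = FALSE])
    xc <- c(centers_x[bx], centers_y[by])
    vectors[bx, by, ] <- drop(Abar %*% xc) + bbar - xc
  }
  structure(list(centers_x = centers_x, centers_y = centers_y,
                 vectors = vectors, occupancy = occupancy),
            class = "clds_composite_field")
}

#' Model tuning curves over a scalar condition
#'
#' By the law of total expectation the model's expected firing rate of neuron
#' `i` at condition `theta` is `C_{i,:}(theta) E[x | theta]` (plus
#' `d_i(theta)` when active). `E[x | theta]` is estimated by averaging
#' smoothed posterior trajectories within condition bins.
#'
#' @param model A fitted [clds_model()].
#' @param trialset Data pooled for the conditional latent average.
#' @param n_bins Number of equal-width condition bins (default 64).
#' @return An object of class `clds_tuning`: `centers` (bin centers),
#'   `curves` (`n_bins x N`, `NA` rows for empty bins), `latent_mean`
#'   (`n_bins x D`), and `counts`.
#' @export
tuning_curves <- function(model, trialset, n_bins = 64L) {
  if (domain_ndim(trialset$domain) != 1L)
    stop("tuning_curves supports scalar (1-D) conditions")
  dm <- trialset$domain$dims[[1L]]
  us <- NULL; xs <- NULL
  for (trial in trialset$trials) {
    xh <- posterior_mode(model, trial)
    us <- c(us, drop(check_covariates(trialset$domain, trial$u)))
    xs <- rbind(xs, xh)
  }
  brk <- seq(dm$lower, dm$upper, length.out = n_bins + 1L)
  centers <- (brk[-1L] + brk[-(n_bins + 1L)]) / 2
  bin <- pmin(pmax(findInterval(us, brk, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  latent_mean <- matrix(NA_real_, n_bins, model$D)
  curves <- matrix(NA_real_, n_bins, model$N)
  for (g in which(counts > 0L)) {
    latent_mean[g, ] <- colMeans(xs[bin == g, , drop = FALSE])
    pars <- evaluate_params(model, centers[g])
    curves[g, ] <- drop(pars$C %*% latent_mean[g, ]) + pars$d
  }
  structure(list(centers = centers, curves = curves,
                 latent_mean = latent_mean, counts = counts),
            class = "clds_tuning")
}
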