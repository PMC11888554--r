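#' Configuration for the synthetic head-direction ring attractor
#'
#' The synthetic experiment conceptualizes head-direction dynamics as a family
#' of leaky line attractors indexed by the heading angle `theta`: at heading
#' `theta` the latent state is attracted to a stable fixed point at the unit
#' vector `e1(theta) = (cos theta, sin theta)`, while the tangent direction
#' `e2(theta)` integrates leakily. The data-generating process is itself a
#' conditionally linear model, which makes recovery exactly assessable.
#'
#' @param epsilon Leak of the line attractor, in (0, 1): the tangent-direction
#'   eigenvalue of `A(theta)` is `1 - epsilon`.
#' @param n_neurons Number of observed neurons.
#' @param T Trial length (time steps).
#' @param K Number of trials.
#' @param heading_step_sd Standard deviation (radians) of the heading
#'   random-walk increments.
#' @param obs_noise_sd Observation noise standard deviation (`R = sd^2 I`).
#' @param dyn_noise_sd Dynamics noise standard deviation (`Q = sd^2 I`).
#' @param bump_sharpness Exponent of the raised-cosine tuning bump.
#' @param preferred_angles Per-neuron preferred headings; default equi-spaced
#'   on `[0, 2*pi)`.
#' @param basis_L,basis_kappa,basis_sigma2 Hyperparameters of the default
#'   fitting basis attached to the ground-truth model.
#' @param seed Integer seed for dataset generation.
#' @return An object of class `ring_config`.
#' @export
ring_config <- function(epsilon = 0.1, n_neurons = 10L, T = 100L, K = 20L,
                        heading_step_sd = 0.5, obs_noise_sd = 0.1,
                        dyn_noise_sd = 0.05, bump_sharpness = 2,
                        preferred_angles = NULL,
                        basis_L = 15L, basis_kappa = 1, basis_sigma2 = 1,
                        seed = 1L) {
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must lie in (0, 1)")
  if (heading_step_sd < 0 || obs_noise_sd < 0 || dyn_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (is.null(preferred_angles))
    preferred_angles <- 2 * pi * (seq_len(n_neurons) - 1L) / n_neurons
  preferred_angles <- preferred_angles %% (2 * pi)
  structure(list(epsilon = epsilon, n_neurons = as.integer(n_neurons),
                 T = as.integer(T), K = as.integer(K),
                 heading_step_sd = heading_step_sd,
                 obs_noise_sd = obs_noise_sd, dyn_noise_sd = dyn_noise_sd,
                 bump_sharpness = bump_sharpness,
                 preferred_angles = preferred_angles,
                 basis_L = as.integer(basis_L), basis_kappa = basis_kappa,
                 basis_sigma2 = basis_sigma2, seed = as.integer(seed)),
            class = "ring_config")
}

ring_e1 <- function(theta) c(cos(theta), sin(theta))
ring_e2 <- function(theta) c(-sin(theta), cos(theta))

#' Ground-truth CLDS model of the ring attractor
#'
#' Builds the analytic (noise-free in parameters) two-dimensional model
#' \deqn{A(\theta) = (1-\epsilon)\, e_2(\theta) e_2(\theta)^\top, \quad
#'       b(\theta) = e_1(\theta), \quad d \equiv 0, \quad m \equiv 0,
#'       \quad Q_1 = I,}
#' with emission row `i` equal to a raised-cosine bump
#' `max(0, cos(theta - theta_i))^p` times `e1(theta)^T`, so each neuron reads
#' out the ring position with bump-shaped heading tuning. The fixed point at
#' each heading is exactly `e1(theta)`, a unit ring, and the eigenvalues of
#' `A(theta)` are `{1 - epsilon, 0}` everywhere.
#'
#' @param cfg A [ring_config()].
#' @return A [clds_model()] with analytic parameter functions (and a Fourier
#'   basis attached for downstream fitting).
#' @export
make_ring_model <- function(cfg) {
  stopifnot(inherits(cfg, "ring_config"))
  domain <- condition_domain(condition_dim("periodic", 0, 2 * pi,
                                           lengthscale = cfg$basis_kappa,
                                           variance = cfg$basis_sigma2))
  basis <- build_basis(domain, cfg$basis_L)
  eps <- cfg$epsilon
  pref <- cfg$preferred_angles; p <- cfg$bump_sharpness
  A_fn <- function(u) (1 - eps) * tcrossprod(ring_e2(u))
  b_fn <- function(u) matrix(ring_e1(u), 2L, 1L)
  C_fn <- function(u) {
    rates <- pmax(0, cos(u - pref))^p
    rates %o% ring_e1(u)
  }
  clds_model(basis, D = 2L, N = cfg$n_neurons,
             A = analytic_fn(A_fn, 2L, 2L, "A"),
             b = analytic_fn(b_fn, 2L, 1L, "b"),
             C = analytic_fn(C_fn, cfg$n_neurons, 2L, "C"),
             d = zero_fn(cfg$n_neurons),
             m = analytic_fn(function(u) matrix(0, 2L, 1L), 2L, 1L, "m"),
             Q1 = diag(2L),
             Q = max(cfg$dyn_noise_sd^2, 1e-10) * diag(2L),
             R = max(cfg$obs_noise_sd^2, 1e-10) * diag(cfg$n_neurons),
             fixed = c("C", "d"))
}

#' Simulate a heading-direction random walk
#'
#' `theta_1` uniform on `[0, 2*pi)`, then `theta_t ~ N(theta_{t-1}, step_sd^2)`
#' wrapped modulo `2*pi`.
#'
#' @param T Number of time steps.
#' @param step_sd Increment standard deviation in radians.
#' @param seed Optional integer seed.
#' @return Numeric vector of headings in `[0, 2*pi)`.
#' @export
simulate_heading <- function(T, step_sd = 0.5, seed = NULL) {
  with_local_seed(seed, {
    steps <- c(stats::runif(1L, 0, 2 * pi), stats::rnorm(T - 1L, 0, step_sd))
    cumsum(steps) %% (2 * pi)
  })
}

#' Generate a synthetic ring-attractor dataset
#'
#' Simulates `K` independent trials from the analytic ground-truth model:
#' per trial a heading random walk and a latent/observation rollout.
#'
#' @param cfg A [ring_config()].
#' @return A list with `trialset` (a [trial_set()]; trials carry their true
#'   latents in `x`), `model` (the ground-truth [clds_model()]), and `cfg`.
#' @export
generate_dataset <- function(cfg = ring_config()) {
  model <- make_ring_model(cfg)
  trials <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    theta <- simulate_heading(cfg$T, cfg$heading_step_sd,
                              seed = cfg$seed + 7919L * k)
    trials[[k]] <- sample_trial(model, theta, seed = cfg$seed + 104729L + k)
  }
  ts <- trial_set(trials, model$basis$domain,
                  metadata = list(generator = "ring_attractor",
                                  epsilon = cfg$epsilon, seed = cfg$seed))
  list(trialset = ts, model = model, cfg = cfg)
}
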