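---
title: "Conditionally linear dynamical systems: model, inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditionally linear dynamical systems: model, inference, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clds)
```

# The model

Neural population recordings typically come with measured covariates — a
heading angle, a reach target, a task epoch — that strongly shape the
population dynamics. `clds` models the data as a latent linear-Gaussian
state-space model whose parameters are smooth functions of those covariates:

$$x_1 \sim N(m(u_1), Q_1), \qquad
  x_{t+1} = A(u_t)\,x_t + b(u_t) + \epsilon_t, \qquad
  y_t = C(u_t)\,x_t + d(u_t) + \omega_t,$$

with $\epsilon_t \sim N(0, Q)$ and $\omega_t \sim N(0, R)$ i.i.d. over time.
Conditioned on the covariate sequence the model is an exact time-varying
linear dynamical system; all nonlinearity lives in the covariate dependence
of the parameter functions. The central assumption is therefore that the
covariate explains the *changes* in local linear dynamics: when latent state
and covariate co-determine each other tightly, analyses that marginalize the
covariate (the composite field below) approximate the underlying nonlinear
system well; when they are only loosely coupled, conditional linearity is a
real restriction and the composite summary degrades.

## The approximate GP prior

Each entry of each parameter function carries a Gaussian-process prior with
a squared-exponential kernel (variance $\sigma^2$, length-scale $\kappa$),
realized approximately by a *fixed* truncated basis with random i.i.d.
standard-normal weights:
$M_{ij}(u) = \sum_{\ell=1}^{L} w_\ell^{(ij)} \phi_\ell(u)$. The implied
kernel is the finite-feature kernel
$\hat k(u, u') = \phi(u)^\top \phi(u')$, positive semidefinite by
construction, converging to the target kernel as $L \to \infty$. The prior
variance is absorbed into the basis scales so weights are always unit
normal; as a result the MAP objective's weight penalty is always
$\tfrac12\lVert W\rVert_F^2$ with no extra regularization constants.

Per-dimension construction:

- **Periodic dimensions** (angles): the periodic squared-exponential kernel
  $k(\tau) = \sigma^2 \exp(-2\sin^2(\psi/2)/\kappa_a^2)$ (with $\psi$ the
  angle difference and $\kappa_a$ the length-scale in angular units) has an
  exact Fourier series whose coefficients are exponentially scaled modified
  Bessel functions, $a_\ell \propto I_\ell(1/\kappa_a^2)$. The basis is
  $\{\sqrt{a_0},\ \sqrt{a_\ell}\cos(\ell\psi),\ \sqrt{a_\ell}\sin(\ell\psi)\}$
  truncated at length $L$; truncation error is the (exponentially small)
  series tail. With $L$ even the last pair is incomplete and exact
  stationarity on the circle is mildly broken, so odd $L$ is recommended and
  used throughout.
- **Interval and discrete-embedded dimensions**: regular equi-spaced-frequency
  Fourier features on a padded interval, scaled by the square root of the
  SE spectral density — equivalently the Fourier series of the *periodized*
  SE kernel. The padding per side is $\max(0.25\,W,\ 3\kappa)$ for interval
  width $W$: the first term suppresses boundary artifacts, and the
  $3\kappa$ floor keeps the wrap-around kernel image below
  $e^{-18}\sigma^2$ at any observable distance. The floor matters precisely
  for discrete covariates embedded on short intervals (e.g. a binary task
  epoch with $\kappa$ comparable to the level spacing), where a
  width-proportional pad alone would let the periodization inflate
  between-level correlations.
- **$L = 1$** is treated as the degenerate constant basis with scale
  $\sigma$ — the $\kappa \to \infty$ limit in which the model collapses to a
  time-invariant LDS.
- **Multi-dimensional covariates** take the tensor product of per-dimension
  bases (total $L$ is the product), realizing the product SE kernel.

Discrete covariates are *embedded on a continuous support*: the correlation
between levels at distance $\Delta$ is $\exp(-\Delta^2/2\kappa^2)$, so
$\kappa$ interpolates between independent per-level dynamics
($\kappa \to 0$) and shared dynamics ($\kappa \to \infty$).

## Tunable parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| $D$ | latent dimension | — | task-dependent (2 for the ring) |
| $L$ | basis truncation per covariate dimension | — | 15 |
| $\kappa$ | prior length-scale of parameter functions | covariate units | 1 |
| $\sigma^2$ | prior variance of parameter-function entries | — | 1 |
| `max_iter`, `tol` | EM stopping | — | 200, $10^{-6}$ (relative) |
| covariance floor | eigenvalue floor on $Q_1, Q, R$ | variance units | $10^{-6}$ |

$\{L, \kappa, \sigma\}$ are best selected by held-out performance;
`select_hyperparameters()` fits each grid point on a random 80% of trials
and scores the rest by co-smoothing $R^2$ (held-out marginal log-likelihood
is reported alongside). Co-smoothing was chosen as the selection score
because it is the package's primary evaluation metric; ties break by grid
order.

# Inference and learning

**E-step.** Kalman filtering with per-step parameters
$\{A(u_t), b(u_t), C(u_t), d(u_t)\}$ computes filtered moments and the exact
marginal log-likelihood from the innovation densities; the
Rauch–Tung–Striebel backward pass yields smoothed means, covariances, and
the adjacent cross-moments $E[x_{t+1} x_t^\top \mid y_{1:T}]$ consumed by
the dynamics update. Covariance updates use the Joseph form plus
symmetrization each step. The backward gain solves against the one-step
predictive covariance through a Cholesky path with an eigenvalue
pseudo-inverse fallback, so rank-deficient predictive covariances (exactly
the near-noise-free, low-rank-dynamics regime of the ring simulator) degrade
gracefully rather than failing.

**M-steps.** Writing $z_t = \phi(u_t) \otimes x_t$, each parameter-function
update is a multi-output Bayesian regression whose MAP weights solve the
Sylvester equation $Z^\top Z\,W + W\Sigma = Z^\top Y$ with the expected
moments substituted for $Z^\top Z$ and $Z^\top Y$. Because $\Sigma$ is
symmetric positive definite, the equation is solved exactly by
diagonalizing $\Sigma$ and solving one SPD shifted system per output
column — no general Schur decomposition is needed, and the identity matrix
in the isotropic-noise ridge special case
$(Z^\top Z + \sigma^2 I)^{-1} Z^\top Y$ has the weight-row dimension
$D_2 L$ (this follows from the stationarity condition of the penalized
objective). $A$ and $b$ are updated jointly by augmenting the latent with a
constant 1 before feature expansion ($C$ and $d$ likewise when both are
learned), keeping every M-step a single regression solve. $Q_1, Q, R$ are
updated from expected residual outer products with the freshly updated
weights, then eigenvalue-floored at $10^{-6}$.

The sequence E-step, weight updates (given old covariances), covariance
updates (given new weights) is an expectation–conditional-maximization
scheme: every step increases the penalized marginal log-likelihood, so the
recorded objective trace is non-decreasing (asserted in the tests with
$10^{-8}$ slack for floating-point accumulation).

**Initialization** draws all learned weight functions from their GP priors,
with identity $Q_1$ and $0.1\,I$ for $Q$ and $R$; `max_iter = 0` returns
the initialization untouched, which makes the initialization itself
testable. **Identifiability:** when $C$ is learned no gauge is fixed, so
latent coordinates are only identified up to an invertible transform;
comparisons against ground-truth parameters therefore always freeze $C$.
$Q_1$ is learned by default, but its update averages a single datum per
trial; with few trials `learn_Q1 = FALSE` keeps the identity.

# Evaluation and analysis

- **Data reconstruction** maps the posterior mode (equal to the smoothed
  mean in the Gaussian model) through the emission:
  $\hat y_t = C(u_t)\hat x_t + d(u_t)$; the offset is included whenever a
  nonzero $d$ is active.
- **Co-smoothing** hides one neuron, smooths latents from the remaining
  neurons with the corresponding row of $C$, entry of $d$, and row/column of
  $R$ deleted, and scores the hidden neuron's predicted rate by $R^2$.
  Deleting the $R$ row/column (conditioning only on held-in noise structure)
  is the standard construction; scored neurons are the top-`k` by test-set
  variance, ties broken by index, and time points are concatenated across
  test trials before forming sums of squares (robust to short trials).
- **Fixed points** solve $(I - A(u))x^* = b(u)$ exactly per grid condition,
  with per-point singularity flags (an eigenvalue of $A$ at 1 — a line
  attractor — makes the system singular at that condition only).
- **Composite dynamics** estimate
  $g(x) - x = E_{p(u \mid x)}[A(u)x + b(u)] - x$ by pooling smoothed
  posterior modes $(\hat x_t, u_t)$ across trials, binning latent space
  (default $25 \times 25$ equal-width bins), and averaging the linear fields
  over the covariates pooled in each bin, with the field evaluated at bin
  centers. Bin occupancy is reported for shading. Evaluating at bin centers
  rather than at each pooled point is a deliberate approximation matching
  the field-on-a-grid presentation; resolution sensitivity is left to the
  user.
- **Tuning curves** use the law of total expectation:
  $E[y_i \mid \theta] = C_{i,:}(\theta)\,E[x \mid \theta]$, with
  $E[x \mid \theta]$ estimated by averaging smoothed trajectories within
  (default 64) covariate bins; empty bins yield flagged gaps.

# The synthetic ring-attractor generator

The simulator emulates a head-direction system: with heading
$\theta \in [0, 2\pi)$ as the covariate, the ground truth is
$A(\theta) = (1-\epsilon)\,e_2(\theta)e_2(\theta)^\top$,
$b(\theta) = e_1(\theta)$, $d \equiv 0$, $m \equiv 0$, $Q_1 = I$, where
$e_1(\theta) = (\cos\theta, \sin\theta)^\top$ is the ring position and
$e_2(\theta)$ its tangent: a leaky line attractor per heading whose fixed
point $x^*(\theta) = e_1(\theta)$ traces the unit circle and whose spectrum
is $\{1-\epsilon, 0\}$ everywhere. Headings follow a wrapped Gaussian random
walk with per-step s.d. 0.5 rad and a uniform start. Emission row $i$ is a
raised-cosine bump $\max(0, \cos(\theta - \theta_i^{\mathrm{pref}}))^p$
(equi-spaced preferred angles, sharpness $p = 2$) times $e_1(\theta)^\top$,
giving bump-shaped heading tuning through the ring readout. The parameter
functions are encoded analytically, so the ground truth is exact rather than
a basis approximation; serialization projects them onto a Fourier basis with
a reported projection error (below $10^{-3}$ on a heading grid at $L = 41$;
the raised-cosine bump's kinks dominate the truncation error).

Defaults: trials of length $T = 100$ with $N = 10$ neurons and $K = 20$
trials; $\epsilon = 0.1$, observation noise s.d. 0.1, dynamics noise s.d.
0.05. The step s.d., trial length, and neuron count define the study
conditions; the leak and noise magnitudes are generator design choices fixed
once — strong enough that recovery is nontrivial (the latent wanders off the
ring and neurons are noisy), weak enough that the heading-conditioned
structure is identifiable from a 16-trial training split.

What the simulator does *not* emulate about real recordings: spiking
(observations are Gaussian rates, not counts), heterogeneous per-neuron
noise, non-stationarity across trials, misspecified covariates (the
generative covariate is observed exactly), and model mismatch (the truth is
itself conditionally linear). Passing the end-to-end tests therefore
demonstrates correct inference and recovery *under the model class*, not
robustness to the ways real data violate it.

# Numerical choices

- Innovation covariances, predictive covariances, and the Sylvester shifted
  systems are handled via Cholesky factorizations; covariances are
  symmetrized after every update.
- The smoother's backward solve falls back to an eigenvalue pseudo-inverse
  (tolerance $10^{-12}$ relative to the largest eigenvalue) when the
  predictive covariance is numerically singular.
- Covariance M-step outputs are eigenvalue-floored at $10^{-6}$; the ring
  generator floors exactly-zero requested noise at $10^{-10}$ so that
  degenerate simulations remain filterable.
- EM stops on relative objective change below `tol` (default $10^{-6}$) or
  `max_iter`; a non-finite objective aborts with a diagnostic rather than
  continuing silently.
- Containers serialize doubles with 17 significant digits, so write/read
  round trips are bitwise exact.
- Sufficient statistics are accumulated through one flattened cross-product
  per trial rather than per-step Kronecker products; the two computations
  are verified against each other in the tests.

# Problem sizes used in the test suite

Unit oracles run at tiny sizes ($D \le 3$, $N \le 4$, $T \le 5$) where dense
joint-Gaussian conditioning is exact. End-to-end checks use the generator's
study conditions ($K = 20$, $T = 100$, $N = 10$) with EM capped at 60
iterations at tolerance $10^{-5}$, which is past the objective plateau for
this problem; monotonicity sweeps use reduced sizes ($K \le 4$, $T \le 50$,
12 iterations) since monotonicity must hold per iteration regardless of
problem size.

# Known limitations

- Gaussian emissions only; count-noise models (Poisson and relatives) are
  out of scope, though the E-step seam is the natural extension point.
- Covariates must be fully observed at every time step; there is no
  forecasting or partial-covariate handling.
- With learned $C$ the latent basis is not identified; all
  parameter-recovery claims require a frozen emission.
- The composite field is a binned estimator of a conditional expectation; in
  regimes where the covariate poorly determines the latent state it is not a
  faithful summary of the dynamics, and its bin-resolution sensitivity is
  not corrected for.
- Fixed points inherit a $1/\epsilon$-type sensitivity near marginally
  stable directions: small errors in $A$ and $b$ along a weakly contracting
  eigendirection are amplified by $(I - A)^{-1}$, so fixed-point accuracy is
  intrinsically noisier than parameter accuracy.
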