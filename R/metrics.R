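#' Data reconstruction: mean emission from the posterior mode
#'
#' Smooths the latent trajectory given the full observation sequence and maps
#' it through the emission function: `yhat_t = C(u_t) xhat_t + d(u_t)` (the
#' offset contributes only when a nonzero `d` is active).
#'
#' @param model A fitted [clds_model()].
#' @param trial A [clds_trial()].
#' @return A `T x N` matrix of reconstructed firing rates.
#' @export
reconstruct <- function(model, trial) {
  xhat <- posterior_mode(model, trial)
  pars <- evaluate_params_seq(model, trial$u)
  Tn <- nrow(xhat)
  yhat <- matrix(0, Tn, model$N)
  for (t in seq_len(Tn))
    yhat[t, ] <- matrix(pars$C[, , t], model$N, model$D) %*% xhat[t, ] + pars$d[t, ]
  yhat
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, at most 1; undefined (an error) when the
#' reference series has zero variance.
#'
#' @param y_true,y_pred Numeric vectors of equal length (at least 2).
#' @return A scalar, at most 1 (unbounded below).
#' @export
r_squared <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) < 2L || length(y_true) != length(y_pred))
    stop("r_squared needs two equal-length series with T >= 2")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot <= 0) stop("r_squared undefined: zero variance in y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

# model with neuron i removed from the emission side
drop_neuron_model <- function(model, i) {
  keep <- setdiff(seq_len(model$N), i)
  sub_rows <- function(pf, rows) {
    if (inherits(pf, "clds_weights")) {
      # column i of W carries output row i of the function value
      function_weights(pf$W[, rows, drop = FALSE], length(rows), pf$D2, pf$L, pf$label)
    } else {
      analytic_fn(function(u) {
        M <- matrix(as.numeric(pf$fn(u)), pf$D1, pf$D2)
        M[rows, , drop = FALSE]
      }, length(rows), pf$D2, pf$label)
    }
  }
  clds_model(model$basis, model$D, length(keep),
             A = model$A, b = model$b,
             C = sub_rows(model$C, keep), d = sub_rows(model$d, keep),
             m = model$m, Q1 = model$Q1, Q = model$Q,
             R = model$R[keep, keep, drop = FALSE],
             fixed = model$fixed)
}

#' Co-smoothing: predict held-out neurons from the rest
#'
#' For each of the `top_k` neurons with highest variance in the test set
#' (computed on observed data only, ties broken by neuron index), the
#' neuron's observations are hidden, latents are smoothed from the remaining
#' neurons (with the corresponding row of `C`, entry of `d`, and row/column
#' of `R` removed), and the hidden neuron's rate is predicted as
#' `C_{i,:}(u_t) xhat_t + d_i(u_t)`. The coefficient of determination is
#' computed against the hidden data, with time points concatenated across
#' test trials before forming the sums of squares.
#'
#' @param model A fitted [clds_model()].
#' @param test_trials A [trial_set()] (or list of trials) held out from
#'   fitting.
#' @param top_k Number of held-out neurons to score.
#' @return A list with `per_neuron` (named R-squared vector), `mean`, and
#'   `neurons` (the selected indices).
#' @export
cosmoothing <- function(model, test_trials, top_k = 5L) {
  trials <- if (inherits(test_trials, "clds_trialset")) test_trials$trials
            else test_trials
  if (model$N < 2L) stop("co-smoothing needs at least 2 neurons")
  Y <- do.call(rbind, lapply(trials, function(tr) tr$y))
  vars <- apply(Y, 2L, stats::var)
  neurons <- order(-vars, seq_along(vars))[seq_len(min(top_k, model$N))]
  r2 <- numeric(length(neurons))
  for (j in seq_along(neurons)) {
    i <- neurons[j]
    sub <- drop_neuron_model(model, i)
    truth <- NULL; pred <- NULL
    for (tr in trials) {
      tr_sub <- clds_trial(tr$y[, -i, drop = FALSE], tr$u)
      xhat <- posterior_mode(sub, tr_sub)
      pars <- evaluate_params_seq(model, tr$u)
      yh <- vapply(seq_len(nrow(xhat)), function(t)
        sum(pars$C[i, , t] * xhat[t, ]) + pars$d[t, i], numeric(1))
      truth <- c(truth, tr$y[, i]); pred <- c(pred, yh)
    }
    r2[j] <- r_squared(truth, pred)
  }
  names(r2) <- paste0("neuron_", neurons)
  list(per_neuron = r2, mean = mean(r2), neurons = neurons)
}
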