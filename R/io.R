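# Container format: versioned JSON documents (doubles serialized at full
# precision so write -> read round-trips are bitwise exact). Trials are ragged
# across T, so a hierarchical document rather than a flat table.

FORMAT_VERSION <- 1L

serialize_domain <- function(domain) {
  lapply(domain$dims, function(dm)
    list(kind = dm$kind, lower = dm$lower, upper = dm$upper,
         lengthscale = dm$lengthscale, variance = dm$variance,
         levels = dm$levels))
}

deserialize_domain <- function(x) {
  condition_domain(lapply(x, function(dm)
    condition_dim(dm$kind, dm$lower, dm$upper, dm$lengthscale, dm$variance,
                  levels = dm$levels)))
}

write_json_doc <- function(doc, path) {
  # I(17) significant digits: doubles survive the round trip bit-for-bit
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       always_decimal = FALSE, null = "null", na = "null")
}

#' Write a trial set to a JSON container
#'
#' The document stores, per trial, `y` (`T x N`), `u` (`T x d`) and optional
#' latents `x`, plus the condition domain and metadata. Doubles are written
#' at full precision, so a write/read round trip reproduces the trial set
#' exactly.
#'
#' @param trialset A [trial_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(trialset, path) {
  stopifnot(inherits(trialset, "clds_trialset"))
  doc <- list(
    format = "clds_trialset", version = FORMAT_VERSION,
    domain = serialize_domain(trialset$domain),
    metadata = trialset$metadata,
    trials = lapply(trialset$trials, function(tr) {
      out <- list(y = tr$y, u = tr$u)
      if (!is.null(tr$x)) out$x <- tr$x
      out
    }))
  write_json_doc(doc, path)
  invisible(path)
}

#' Read a trial set from a JSON container
#'
#' @param path File written by [write_trialset()].
#' @return A [trial_set()].
#' @export
read_trialset <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "clds_trialset"))
    stop("not a clds_trialset container: ", path)
  if (doc$version > FORMAT_VERSION)
    stop("container version ", doc$version, " is newer than supported")
  trials <- lapply(doc$trials, function(tr)
    clds_trial(tr$y, tr$u, x = tr$x))
  trial_set(trials, deserialize_domain(doc$domain),
            metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}

#' Import trials from a long-format CSV table
#'
#' Expected columns: `trial` (integer id), `t` (time step within trial),
#' neuron columns `y1 ... yN`, and covariate columns `u1 ... ud`. Rows are
#' ordered by `t` within each trial on import.
#'
#' @param path CSV file path.
#' @param domain The [condition_domain()] of the covariates.
#' @return A [trial_set()].
#' @export
read_trialset_csv <- function(path, domain) {
  df <- utils::read.csv(path)
  need <- c("trial", "t")
  if (!all(need %in% names(df))) stop("CSV must have 'trial' and 't' columns")
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  ucols <- grep("^u[0-9]+$", names(df), value = TRUE)
  if (length(ycols) == 0L || length(ucols) == 0L)
    stop("CSV must have neuron columns y1..yN and covariate columns u1..ud")
  ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
  ucols <- ucols[order(as.integer(sub("^u", "", ucols)))]
  trials <- lapply(split(df, df$trial), function(blk) {
    blk <- blk[order(blk$t), , drop = FALSE]
    clds_trial(as.matrix(blk[, ycols, drop = FALSE]),
               as.matrix(blk[, ucols, drop = FALSE]))
  })
  trial_set(unname(trials), domain)
}

serialize_param <- function(pf, basis, nm) {
  if (inherits(pf, "clds_analytic_fn"))
    pf <- project_to_weights(pf, basis)
  list(W = pf$W, D1 = pf$D1, D2 = pf$D2, L = pf$L, label = pf$label)
}

#' Project an analytic parameter function onto the basis
#'
#' Least-squares projection of the function's values on a dense condition
#' grid onto the basis expansion; used when serializing models whose
#' ground-truth functions are closed-form. The projection residual on the
#' grid is attached as attribute `"projection_error"` (for smooth functions
#' and an adequate basis it is small; callers can assert it).
#'
#' @param pf An [analytic_fn()].
#' @param basis The target [build_basis()].
#' @param n_grid Grid points per domain dimension.
#' @return A [function_weights()] approximation.
#' @export
project_to_weights <- function(pf, basis, n_grid = 256L) {
  dom <- basis$domain
  grids <- lapply(dom$dims, function(dm) {
    if (dm$kind == "periodic")
      seq(dm$lower, dm$upper, length.out = n_grid + 1L)[-(n_grid + 1L)]
    else if (dm$kind == "discrete_embedded") dm$levels
    else seq(dm$lower, dm$upper, length.out = n_grid)
  })
  U <- as.matrix(expand.grid(grids))
  Phi <- evaluate_basis_matrix(basis, U)
  Yv <- t(vapply(seq_len(nrow(U)),
                 function(g) as.numeric(pf$fn(drop(U[g, , drop = FALSE]))),
                 numeric(pf$D1 * pf$D2)))            # n x (D1*D2), col i+(j-1)D1
  coef <- qr.solve(Phi, Yv)                          # L x (D1*D2)
  err <- max(abs(Phi %*% coef - Yv))
  # reorder into W rows (l-1)*D2 + j, columns i
  W <- matrix(0, pf$D2 * basis$L, pf$D1)
  for (i in seq_len(pf$D1)) for (j in seq_len(pf$D2))
    W[(seq_len(basis$L) - 1L) * pf$D2 + j, i] <- coef[, i + (j - 1L) * pf$D1]
  out <- function_weights(W, pf$D1, pf$D2, basis$L, pf$label)
  attr(out, "projection_error") <- err
  out
}

#' Write a CLDS model to a JSON container
#'
#' Stores the basis configuration (domain and truncation), all weight
#' matrices, the covariances, and the frozen-parameter flags. Analytic
#' parameter functions are projected onto the basis first (see
#' [project_to_weights()]); weight-parameterized models round-trip exactly.
#'
#' @param model A [clds_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "clds_model"))
  doc <- list(
    format = "clds_model", version = FORMAT_VERSION,
    D = model$D, N = model$N,
    domain = serialize_domain(model$basis$domain),
    L_per_dim = model$basis$L_per_dim,
    params = lapply(stats::setNames(nm = c("A", "b", "C", "d", "m")),
                    function(nm) serialize_param(model[[nm]], model$basis, nm)),
    Q1 = model$Q1, Q = model$Q, R = model$R,
    fixed = model$fixed)
  write_json_doc(doc, path)
  invisible(path)
}

#' Read a CLDS model from a JSON container
#'
#' @param path File written by [write_model()].
#' @return A [clds_model()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "clds_model")) stop("not a clds_model container: ", path)
  if (doc$version > FORMAT_VERSION)
    stop("container version ", doc$version, " is newer than supported")
  basis <- build_basis(deserialize_domain(doc$domain), doc$L_per_dim)
  pf <- lapply(doc$params, function(p)
    function_weights(matrix(p$W, nrow = p$D2 * p$L, ncol = p$D1),
                     p$D1, p$D2, p$L, p$label))
  clds_model(basis, doc$D, doc$N, pf$A, pf$b, pf$C, pf$d, pf$m,
             Q1 = matrix(doc$Q1, doc$D, doc$D),
             Q = matrix(doc$Q, doc$D, doc$D),
             R = matrix(doc$R, doc$N, doc$N),
             fixed = doc$fixed %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a YAML run configuration
#'
#' Strictly validated sections: `model` (latent dimension `D`, per-dimension
#' basis descriptors, frozen flags), `em` (`max_iter`, `tol`, `seed`), `data`
#' (a `simulate` spec or file `path`), and `eval` (`top_k`, `split`,
#' `split_seed`). Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c("model", "em", "data", "eval")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s': %s", where, paste(extra, collapse = ", ")))
  }
  if (!is.null(cfg$model)) {
    check_keys(cfg$model, c("D", "basis", "fix_C", "fix_d"), "model")
    for (bd in cfg$model$basis)
      check_keys(bd, c("kind", "lower", "upper", "lengthscale", "variance",
                       "L", "levels"), "model.basis")
  }
  if (!is.null(cfg$em))
    check_keys(cfg$em, c("max_iter", "tol", "seed", "learn_Q1"), "em")
  if (!is.null(cfg$data))
    check_keys(cfg$data, c("path", "simulate"), "data")
  if (!is.null(cfg$eval))
    check_keys(cfg$eval, c("top_k", "split", "split_seed"), "eval")
  cfg
}
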