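# Model registry: every goal-valuation agent known to the package, keyed by
# model_id, so that simulation, fitting and the recovery studies can enumerate
# models uniformly.

.model_registry <- list(
  momentum = list(
    code = 1L, fitted = TRUE,
    free = c("alpha", "gamma", "cost", "beta_g", "beta_a", "alpha_ck")
  ),
  prospective = list(
    code = 2L, fitted = TRUE,
    free = c("alpha", "gamma", "cost", "beta_g", "beta_a", "alpha_ck")
  ),
  retrospective = list(
    code = 3L, fitted = FALSE,  # benchmark agent, simulated but not fitted
    free = c("gamma", "cost", "beta_g", "beta_a", "alpha_ck")
  ),
  td_persistence = list(
    code = 4L, fitted = TRUE,
    free = c("alpha", "cost", "beta_g", "beta_a", "alpha_ck")
  ),
  hybrid = list(
    code = 5L, fitted = TRUE,
    free = c("alpha", "gamma", "cost", "beta_g", "beta_a", "alpha_ck", "w")
  ),
  rw_ck = list(
    code = 6L, fitted = TRUE,
    free = c("alpha", "alpha_ck", "beta", "beta_ck")
  )
)

# Fitting/recovery box per parameter (the recovery ranges used throughout)
.param_box <- list(
  alpha    = c(0, 1),
  gamma    = c(0.6, 1),
  cost     = c(-1, 1),
  beta_g   = c(0, 10),
  beta_a   = c(0, 10),
  alpha_ck = c(0, 1),
  w        = c(0, 1),
  k        = c(0, 1),
  beta     = c(0, 10),
  beta_ck  = c(0, 10)
)

#' Registered goal-valuation models
#'
#' @return Character vector of model identifiers.
#' @export
model_ids <- function() names(.model_registry)

#' Model metadata
#'
#' Free-parameter names, free-parameter count (as fitted), and whether the
#' model is part of the fitted set (the retrospective agent is a simulation
#' benchmark only).
#'
#' @param model_id One of [model_ids()].
#' @return A list with elements `model_id`, `free`, `n_free`, `fitted`,
#'   and `box` (named list of lower/upper bounds for each free parameter).
#' @export
model_info <- function(model_id) {
  info <- .model_registry[[match.arg(model_id, names(.model_registry))]]
  list(
    model_id = model_id,
    free = info$free,
    n_free = length(info$free),
    fitted = info$fitted,
    box = .param_box[info$free]
  )
}

#' Construct a full parameter set for a model
#'
#' All models share one parameter vocabulary; each model reads the subset it
#' needs. `alpha` is the belief/value learning rate (the delta-rule rate for
#' prospective-family beliefs, the momentum gradient step, or the
#' Rescorla-Wagner rate), `gamma` the discount factor, `cost` the switch cost
#' entering the stay logistic, `beta_g`/`beta_a` the goal- and action-level
#' softmax temperatures, `alpha_ck` the choice-kernel learning rate, `w` the
#' hybrid prospective weight, `beta`/`beta_ck` the Rescorla-Wagner value and
#' kernel temperatures, `k` the hyperbolic discount rate, and `reward` the
#' terminal payoff of a completed suit (normalized to 1; softmax temperatures
#' absorb scale).
#'
#' @param model_id One of [model_ids()].
#' @param ... Named parameter values overriding the defaults.
#' @return An object of class `model_params`.
#' @export
model_params <- function(model_id, ...) {
  model_id <- match.arg(model_id, names(.model_registry))
  p <- list(
    model_id = model_id,
    alpha = 0.3, gamma = 0.95, cost = 0.2, beta_g = 5, beta_a = 5,
    alpha_ck = 0.1, w = 0.5, k = 0.2, beta = 5, beta_ck = 1,
    reward = 1, horizon = 20L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$alpha >= 0, p$alpha <= 1, p$gamma >= 0, p$gamma <= 1,
            p$w >= 0, p$w <= 1, p$beta_g >= 0, p$beta_a >= 0)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  free <- model_info(x$model_id)$free
  cat("<model_params> ", x$model_id, " (", length(free), " free)\n", sep = "")
  vals <- vapply(free, function(nm) x[[nm]], numeric(1))
  print(round(vals, 4))
  invisible(x)
}

# Fixed-position parameter vector consumed by the C++ core.
pack_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  c(params$alpha, params$gamma, params$cost, params$beta_g, params$beta_a,
    params$alpha_ck, params$w, params$reward, params$beta, params$beta_ck,
    params$horizon)
}

model_code <- function(model_id) .model_registry[[model_id]]$code
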