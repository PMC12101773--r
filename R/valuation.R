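# Goal-valuation operations. Every agent assigns each suit a scalar value Q
# from its internal state; the shared policy layer (R/policy.R) turns values
# into stay/switch decisions. Only the chosen suit's internal state is updated
# each round: token outcomes are observed only for the flipped card.

#' Delta-rule belief update
#'
#' `M' = M + alpha * (token - M)`. With `alpha_neg` supplied, the learning
#' rate is asymmetric: `alpha` applies to positive prediction errors
#' (`token > M`), `alpha_neg` to negative ones.
#'
#' @param M Current belief in `[0, 1]` (vectorized).
#' @param token Token outcome, 0 or 1.
#' @param alpha Learning rate in `[0, 1]`.
#' @param alpha_neg Optional learning rate for negative prediction errors.
#' @return Updated belief.
#' @export
belief_update <- function(M, token, alpha, alpha_neg = NULL) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]")
  pe <- token - M
  a <- if (is.null(alpha_neg)) alpha else ifelse(pe > 0, alpha, alpha_neg)
  M + a * pe
}

#' Prospective goal value by discounted belief rollout
#'
#' Dynamic-programming evaluation of
#' `Q(s, h) = M * gamma * Q(s + 1, h - 1) + (1 - M) * gamma * Q(s, h - 1)`
#' with boundary conditions `Q(T, .) = reward` and `Q(., 0) = 0`: the expected
#' discounted terminal reward of pursuing a suit that needs `T - s` more
#' tokens, each arriving with believed probability `M`, evaluated to a finite
#' horizon.
#'
#' @param M Believed per-round token probability.
#' @param s Tokens collected so far (`0 <= s <= T`).
#' @param T Target token count.
#' @param gamma Discount factor per round.
#' @param horizon Rollout horizon in rounds (default 20).
#' @param reward Terminal reward (default 1).
#' @return The goal value.
#' @export
prospective_value <- function(M, s, T, gamma, horizon = 20L, reward = 1) {
  if (s > T) stop("s must not exceed the target T")
  if (horizon < 0) stop("horizon must be non-negative")
  cpp_prospective_value(M, gamma, as.integer(s), as.integer(T),
                        as.integer(horizon), reward)
}

#' Retrospective goal value
#'
#' `Q = gamma^(T - s) * reward`: pure proximity-to-target discounting with no
#' belief about token probabilities, so the suit with greatest accrued
#' progress is always most valuable.
#'
#' @inheritParams prospective_value
#' @return The goal value.
#' @export
retrospective_value <- function(s, T, gamma, reward = 1) {
  gamma^(T - s) * reward
}

#' Momentum goal value
#'
#' `Q = v * m + b`: accrued fractional progress `m` times the learned speed of
#' progress `v`, plus a goal-specific bias `b`.
#'
#' @param v Speed of progress.
#' @param m Fractional progress in `[0, 1)`.
#' @param b Goal bias.
#' @return The goal value.
#' @export
momentum_value <- function(v, m, b) v * m + b

#' TD update of the momentum parameters
#'
#' The TD error `delta = gamma * Q(m_after) - Q(m_before)` drives gradient
#' steps on the linear-in-progress value function:
#' `v' = v + alpha * delta * m_before`, `b' = b + alpha * delta`. On suit
#' completion the update is applied with `m_after = 1` and the progress then
#' resets to zero; `v` and `b` persist across completions.
#'
#' @param v,b Current speed and bias.
#' @param m_before,m_after Fractional progress before/after the round.
#' @param gamma Discount factor.
#' @param alpha Learning rate.
#' @return List with updated `v`, `b` and the TD error `delta`.
#' @export
momentum_update <- function(v, b, m_before, m_after, gamma, alpha) {
  delta <- gamma * momentum_value(v, m_after, b) -
    momentum_value(v, m_before, b)
  list(v = v + alpha * delta * m_before, b = b + alpha * delta, delta = delta)
}

#' Sign of the momentum TD error under unit progress
#'
#' With a step of unit progress `eta` and no bias contribution, the TD error
#' is non-negative iff `gamma >= m / (m + eta)`: close to the target, a unit
#' of progress can decrease momentum (diminishing marginal utility). The
#' boundary `gamma = m / (m + eta)` gives a TD error of exactly zero and is
#' counted as favorable.
#'
#' @param m Fractional progress (`>= 0`).
#' @param eta Unit progress step (`> 0`).
#' @param gamma Discount factor.
#' @return Logical: `TRUE` iff a unit of progress does not decrease the
#'   momentum value.
#' @export
momentum_sign_condition <- function(m, eta, gamma) {
  stopifnot(all(m >= 0), all(eta > 0))
  gamma >= m / (m + eta)
}

#' TD-persistence goal value
#'
#' The value is the token-outcome belief itself; persistence arises entirely
#' from the policy layer (switch cost and choice kernel).
#'
#' @param M Token-outcome belief.
#' @return `M` unchanged.
#' @export
td_persistence_value <- function(M) M

#' Hybrid goal value
#'
#' Convex combination `w * Q_pros + (1 - w) * Q_retro`.
#'
#' @param q_pros,q_retro Prospective and retrospective values.
#' @param w Prospective weight in `[0, 1]`.
#' @return The combined value.
#' @export
hybrid_value <- function(q_pros, q_retro, w) {
  if (any(w < 0 | w > 1)) stop("w must be in [0, 1]")
  w * q_pros + (1 - w) * q_retro
}

#' Hyperbolically discounted prospective value
#'
#' The expected delay to completion is estimated as `D = (T - s) / max(M, eps)`
#' rounds and the terminal reward discounted hyperbolically:
#' `value = reward / (1 + k * D)`.
#'
#' @inheritParams prospective_value
#' @param k Hyperbolic discount rate in `[0, 1]`.
#' @param eps Floor on the belief to keep the delay finite (default 1e-3).
#' @return The goal value.
#' @export
hyperbolic_prospective_value <- function(M, s, T, k, reward = 1, eps = 1e-3) {
  D <- (T - s) / pmax(M, eps)
  reward / (1 + k * D)
}

#' Rescorla-Wagner + choice-kernel update
#'
#' The chosen suit's value moves toward the binary token reward,
#' `Q' = Q + eta * (r - Q)`; every suit's kernel moves toward its chosen
#' indicator, `c' = c + alpha_ck * (I - c)`.
#'
#' @param Q Named value vector over suits.
#' @param kernels Named kernel vector over suits.
#' @param chosen Chosen suit.
#' @param token Token outcome, 0 or 1.
#' @param eta Value learning rate.
#' @param alpha_ck Kernel learning rate.
#' @return List with updated `Q` and `kernels`.
#' @export
rw_ck_update <- function(Q, kernels, chosen, token, eta, alpha_ck) {
  Q[chosen] <- Q[chosen] + eta * (token - Q[chosen])
  I <- as.numeric(names(kernels) == chosen)
  list(Q = Q, kernels = kernels + alpha_ck * (I - kernels))
}

#' Rescorla-Wagner + choice-kernel selection probabilities
#'
#' Softmax over `beta * Q + beta_ck * c` across the three suits.
#'
#' @inheritParams rw_ck_update
#' @param beta,beta_ck Value and kernel temperatures.
#' @return Named probability vector summing to 1.
#' @export
rw_ck_probs <- function(Q, kernels, beta, beta_ck) {
  x <- beta * Q + beta_ck * kernels
  e <- exp(x - max(x))
  e / sum(e)
}

#' Initial valuation state for a model
#'
#' Beliefs start at 1/3 (uninformative over "some suit is likely"), momentum
#' speed at 0.5 and bias at 0.1 (fixed initialization), Rescorla-Wagner values
#' and choice kernels at 0.
#'
#' @param config A `game_config` or `drift_config`.
#' @return A list with named vectors `M`, `v`, `b`, `rwq`, `kernels` and the
#'   slot `counts`.
#' @export
init_valuation_state <- function(config) {
  z <- setNames(rep(0, 3), SUITS)
  list(M = z + 1 / 3, v = z + 0.5, b = z + 0.1, rwq = z, kernels = z,
       counts = setNames(rep(0L, 3), SUITS))
}

#' Goal values of all suits under a model
#'
#' @param model_id One of [model_ids()].
#' @param state A valuation state as from [init_valuation_state()].
#' @param params A [model_params()] object.
#' @param config The task configuration (for targets).
#' @return Named numeric value vector over suits.
#' @export
goal_values <- function(model_id, state, params, config) {
  targets <- config_targets(config)
  m <- state$counts / targets
  switch(model_id,
    momentum = momentum_value(state$v, m, state$b),
    prospective = vapply(SUITS, function(g) prospective_value(
      state$M[[g]], state$counts[[g]], targets[[g]], params$gamma,
      params$horizon, params$reward), numeric(1)),
    retrospective = retrospective_value(state$counts, targets, params$gamma,
                                        params$reward),
    td_persistence = td_persistence_value(state$M),
    hybrid = hybrid_value(
      vapply(SUITS, function(g) prospective_value(
        state$M[[g]], state$counts[[g]], targets[[g]], params$gamma,
        params$horizon, params$reward), numeric(1)),
      retrospective_value(state$counts, targets, params$gamma, params$reward),
      params$w),
    rw_ck = state$rwq,
    stop("unknown model_id: ", model_id)
  )
}
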