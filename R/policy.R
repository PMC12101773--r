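# Hierarchical goal-then-action selection shared by all valuation models
# except the flat Rescorla-Wagner + choice-kernel agent. Each round the agent
# first decides whether to stay with its current goal (a logistic in the
# goal's advantage, switch cost and choice kernel), re-selecting among the
# alternatives by softmax on a switch; it then decides whether to act on the
# goal or explore, with a separate action temperature.

#' Advantage of the current goal
#'
#' `A_G = Q_G - max_{g != G} Q_g`.
#'
#' @param values Named value vector over the three suits.
#' @param current_goal The current goal suit.
#' @return Scalar advantage.
#' @export
advantage <- function(values, current_goal) {
  if (is.null(current_goal) || is.na(current_goal))
    stop("current_goal is unset")
  values[[current_goal]] - max(values[names(values) != current_goal])
}

#' Stay probability
#'
#' `p_stay = logistic(cost + kernel + beta * A)`. The same form serves the
#' goal level (with `beta_g`) and the action level (with `beta_a`).
#'
#' @param A Advantage of the current goal.
#' @param cost Switch cost.
#' @param kernel Choice kernel of the current goal.
#' @param beta Softmax temperature (`>= 0`).
#' @return Probability in (0, 1).
#' @export
p_stay <- function(A, cost, kernel, beta) {
  stopifnot(all(beta >= 0))
  plogis(cost + kernel + beta * A)
}

softmax <- function(x, beta = 1) {
  e <- exp(beta * x - max(beta * x))
  e / sum(e)
}

#' Select the round's goal
#'
#' With probability `p_stay` the current goal is kept; otherwise a new goal is
#' sampled among the two alternatives by softmax at temperature `beta_g` over
#' their values. At game start (`current_goal = NULL`) the goal is sampled
#' among all three suits by softmax `beta_g`.
#'
#' @param current_goal Current goal suit or `NULL`.
#' @param values Named value vector.
#' @param params A [model_params()] object.
#' @param kernels Named choice-kernel vector.
#' @return The selected goal suit.
#' @export
choose_goal <- function(current_goal, values, params, kernels) {
  nm <- names(values)
  if (is.null(current_goal)) {
    return(sample(nm, 1, prob = softmax(values, params$beta_g)))
  }
  A <- advantage(values, current_goal)
  if (runif(1) <= p_stay(A, params$cost, kernels[[current_goal]],
                         params$beta_g)) {
    return(current_goal)
  }
  alts <- nm[nm != current_goal]
  sample(alts, 1, prob = softmax(values[alts], params$beta_g))
}

#' Select the round's action (card suit)
#'
#' With probability `p_stay` (action temperature `beta_a`, same goal
#' advantage) the goal-congruent card is flipped; otherwise one of the other
#' two suits is sampled by softmax `beta_a` over their values, so actions may
#' diverge from the reported goal.
#'
#' @param values Named value vector.
#' @param goal Goal selected this round.
#' @param params A [model_params()] object.
#' @param kernels Named choice-kernel vector.
#' @return The acted-on suit.
#' @export
choose_action <- function(values, goal, params, kernels) {
  A <- advantage(values, goal)
  if (runif(1) <= p_stay(A, params$cost, kernels[[goal]], params$beta_a)) {
    return(goal)
  }
  alts <- names(values)[names(values) != goal]
  sample(alts, 1, prob = softmax(values[alts], params$beta_a))
}

#' Delta-rule choice-kernel update
#'
#' For every suit `g`: `c_g' = c_g + alpha_ck * (I_g - c_g)` with `I_g = 1`
#' iff `g` is the chosen goal, so the kernel increments each time a goal is
#' selected and decays each time it is not.
#'
#' @param kernels Named kernel vector.
#' @param chosen_goal The goal selected this round.
#' @param alpha_ck Kernel learning rate in `[0, 1]`.
#' @return Updated kernel vector.
#' @export
update_kernel <- function(kernels, chosen_goal, alpha_ck) {
  stopifnot(alpha_ck >= 0, alpha_ck <= 1)
  I <- as.numeric(names(kernels) == chosen_goal)
  kernels + alpha_ck * (I - kernels)
}

#' Goal stay/switch transition matrix
#'
#' Row `G` gives the distribution of the next goal when the previous goal is
#' `G`: the diagonal holds `p_stay`, the off-diagonal entries
#' `(1 - p_stay) * softmax_beta_g` over the two alternative values.
#'
#' @param values Named value vector.
#' @param params A [model_params()] object.
#' @param kernels Named choice-kernel vector.
#' @return 3 x 3 matrix with rows summing to 1.
#' @export
goal_transition_matrix <- function(values, params, kernels) {
  nm <- names(values)
  M <- matrix(0, 3, 3, dimnames = list(nm, nm))
  for (G in nm) {
    A <- advantage(values, G)
    ps <- p_stay(A, params$cost, kernels[[G]], params$beta_g)
    alts <- nm[nm != G]
    M[G, G] <- ps
    M[G, alts] <- (1 - ps) * softmax(values[alts], params$beta_g)
  }
  M
}

#' Conditional action probabilities given each possible goal
#'
#' Row `g` is the distribution over acted-on suits when the round's goal is
#' `g` (stay on the congruent card with the action-level stay probability,
#' otherwise softmax `beta_a` over the alternatives).
#'
#' @inheritParams goal_transition_matrix
#' @return 3 x 3 matrix (rows = goal, columns = action) with rows summing
#'   to 1.
#' @export
action_prob_matrix <- function(values, params, kernels) {
  nm <- names(values)
  M <- matrix(0, 3, 3, dimnames = list(nm, nm))
  for (g in nm) {
    A <- advantage(values, g)
    ps <- p_stay(A, params$cost, kernels[[g]], params$beta_a)
    alts <- nm[nm != g]
    M[g, g] <- ps
    M[g, alts] <- (1 - ps) * softmax(values[alts], params$beta_a)
  }
  M
}
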