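# Likelihood of a participant dataset under any registered model: a forward
# pass that updates valuation state from the observed actions and outcomes,
# scores the observed card choice every round by marginalizing over the
# latent goal, scores the reported goal on probe rounds, and collapses the
# latent-goal belief to the report (probes are treated as noiseless). Between
# probes the belief is propagated through the stay/switch transition chain
# without conditioning on observed actions; a Bayes-filtered variant is
# available behind `bayes_filter = TRUE` for sensitivity analysis.

dataset_arrays <- function(dataset) {
  r <- dataset$rounds
  probes <- ifelse(is.na(r$probe_response), 0L,
                   ifelse(r$probe_response == "undecided", -1L,
                          match(r$probe_response, SUITS)))
  list(actions = match(r$chosen_suit, SUITS),
       tokens = as.integer(r$token_received),
       probes = as.integer(probes),
       targets = as.integer(config_targets(dataset$config)))
}

#' Negative log-likelihood of a dataset under a model
#'
#' Accumulates `-log` action likelihood every round and `-log` goal
#' likelihood on probe rounds (the Rescorla-Wagner + choice-kernel model is
#' scored on actions only). Per-term probabilities are floored at 1e-12.
#'
#' @param dataset A `participant_dataset`.
#' @param model_id One of [model_ids()].
#' @param params A [model_params()] object for that model.
#' @param score Optional logical vector (one per round) restricting which
#'   rounds contribute likelihood terms; the forward pass always runs from
#'   the game start.
#' @param bayes_filter If `TRUE`, condition the latent-goal belief on each
#'   observed action between probes.
#' @param by_term If `TRUE`, return the per-round action and goal terms.
#' @return Total negative log-likelihood, with attribute `n_terms` (number of
#'   scored action plus probe terms); or a list of per-round terms.
#' @export
dataset_nll <- function(dataset, model_id, params, score = NULL,
                        bayes_filter = FALSE, by_term = FALSE) {
  arr <- dataset_arrays(dataset)
  res <- cpp_nll(arr$actions, arr$tokens, arr$probes, arr$targets,
                 model_code(model_id), pack_params(params), bayes_filter)
  if (by_term) return(res)
  if (is.null(score)) score <- rep(TRUE, length(arr$actions))
  nll <- sum(res$nll_action[score]) + sum(res$nll_goal[score])
  n_goal <- sum(arr$probes > 0 & score) * (model_id != "rw_ck")
  structure(nll, n_terms = sum(score) + n_goal)
}

#' Propagate the latent-goal belief one round
#'
#' Matrix-vector product with the stay/switch transition matrix,
#' renormalized.
#'
#' @param belief Named probability vector over suits (sums to 1).
#' @param transition 3 x 3 transition matrix, rows = previous goal.
#' @return Updated belief.
#' @export
propagate_latent_goal <- function(belief, transition) {
  if (abs(sum(belief) - 1) > 1e-9) stop("belief must sum to 1")
  out <- as.vector(belief %*% transition)
  names(out) <- colnames(transition)
  out / sum(out)
}

#' Marginal likelihood of an observed action
#'
#' `Pr(action) = sum_g Pr(action | goal = g) * Pr(goal = g)`.
#'
#' @param belief Named latent-goal probability vector.
#' @param action_probs 3 x 3 matrix of action probabilities given each goal
#'   (rows = goal), as from [action_prob_matrix()].
#' @param observed_action The observed suit.
#' @return Probability, floored at 1e-12 (with a warning at the floor).
#' @export
action_likelihood <- function(belief, action_probs, observed_action) {
  p <- sum(belief * action_probs[, observed_action])
  if (p < 1e-12) {
    warning("action likelihood floored at 1e-12")
    p <- 1e-12
  }
  p
}

#' AIC and BIC from a fitted likelihood
#'
#' `AIC = 2k + 2 nll`; `BIC = k log(n) + 2 nll` with `n` the number of summed
#' likelihood terms (actions plus probes).
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @param n Number of likelihood terms.
#' @return Numeric.
#' @export
compute_aic <- function(nll, k) 2 * k + 2 * nll

#' @rdname compute_aic
#' @export
compute_bic <- function(nll, k, n) k * log(n) + 2 * nll

# map a point in [0,1]^k to the parameter box
.box_transform <- function(u, box) {
  mapply(function(ui, r) r[1] + ui * (r[2] - r[1]), u, box)
}

.nll_objective <- function(dataset, model_id, box, score = NULL) {
  free <- names(box)
  arr <- dataset_arrays(dataset)
  code <- model_code(model_id)
  if (is.null(score)) score <- rep(TRUE, length(arr$actions))
  goal_scored <- sum(arr$probes > 0 & score) * (model_id != "rw_ck")
  function(theta) {
    pl <- as.list(theta)
    names(pl) <- free
    params <- do.call(model_params, c(list(model_id = model_id), pl))
    res <- cpp_nll(arr$actions, arr$tokens, arr$probes, arr$targets,
                   code, pack_params(params), FALSE)
    sum(res$nll_action[score]) + sum(res$nll_goal[score])
  }
}

#' Maximum-likelihood fit of a model to one dataset
#'
#' Global derivative-free search over the model's parameter box: a maximin
#' Latin-hypercube sample of `n_starts` candidate vectors is scored, and the
#' best `refine_top` candidates are polished by Nelder-Mead in a logistic
#' reparameterization of the box. Reproducible under `seed`.
#'
#' @param dataset A `participant_dataset`.
#' @param model_id One of the fitted models (see [model_info()]).
#' @param n_starts Number of random starts (default 100).
#' @param refine_top Number of top starts polished by Nelder-Mead.
#' @param seed Optimizer seed.
#' @param score Optional per-round scoring mask (used by cross-validation).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `fit_result`: list with `model_id`, `params`, `nll`, `aic`,
#'   `bic`, `k`, `n`, `n_starts`, `seed`.
#' @export
fit_model <- function(dataset, model_id, n_starts = 100L, refine_top = 3L,
                      seed = 1L, score = NULL, maxit = 300L) {
  info <- model_info(model_id)
  box <- info$box
  k <- length(box)
  obj <- .nll_objective(dataset, model_id, box, score)

  set.seed(seed)
  U <- lhs::maximinLHS(n_starts, k)
  cand <- t(apply(U, 1, .box_transform, box = box))
  vals <- apply(cand, 1, obj)
  ord <- order(vals)

  # Nelder-Mead in unconstrained coordinates z, theta = lo + (hi-lo)*plogis(z)
  lo <- vapply(box, `[`, numeric(1), 1)
  hi <- vapply(box, `[`, numeric(1), 2)
  to_z <- function(theta) qlogis(pmin(pmax((theta - lo) / (hi - lo),
                                           1e-6), 1 - 1e-6))
  from_z <- function(z) lo + (hi - lo) * plogis(z)
  best_val <- vals[ord[1]]
  best_theta <- cand[ord[1], ]
  for (i in head(ord, refine_top)) {
    fit <- optim(to_z(cand[i, ]), function(z) obj(from_z(z)),
                 method = "Nelder-Mead", control = list(maxit = maxit))
    if (fit$value < best_val) {
      best_val <- fit$value
      best_theta <- from_z(fit$par)
    }
  }

  pl <- as.list(best_theta)
  names(pl) <- names(box)
  params <- do.call(model_params, c(list(model_id = model_id), pl))
  full <- dataset_nll(dataset, model_id, params, score = score)
  n <- attr(full, "n_terms")
  structure(
    list(model_id = model_id, params = params, nll = best_val,
         aic = compute_aic(best_val, k), bic = compute_bic(best_val, k, n),
         k = k, n = n, n_starts = n_starts, seed = seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model_id, ": nll = ", round(x$nll, 2),
      ", AIC = ", round(x$aic, 2), ", BIC = ", round(x$bic, 2),
      " (k = ", x$k, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Block-wise cross-validated negative log-likelihood
#'
#' Blocks are partitioned at random into `n_splits` folds; for each fold the
#' model is fitted on the remaining blocks (the forward pass always runs from
#' the game start, only the training rounds contribute likelihood) and the
#' held-out rounds are scored at the fitted parameters. The metric is the
#' mean held-out negative log-likelihood over folds, averaged over
#' `n_repeats` random splits.
#'
#' @param dataset A `participant_dataset` with at least `n_splits` blocks.
#' @param model_id One of the fitted models.
#' @param n_splits Number of folds (default 3).
#' @param n_repeats Number of random splits averaged (default 30).
#' @param seed Seed for the splits and the optimizer.
#' @param n_starts Random starts per fold fit.
#' @return Mean held-out NLL, with attribute `per_repeat`.
#' @export
cross_validate <- function(dataset, model_id, n_splits = 3L,
                           n_repeats = 30L, seed = 1L, n_starts = 50L) {
  blocks <- dataset$rounds$block_index
  ub <- unique(blocks)
  if (length(ub) < n_splits) stop("dataset has fewer blocks than folds")
  per_repeat <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + 1000L * r)
    fold_of <- setNames(sample(rep(seq_len(n_splits), length.out =
                                     length(ub))), ub)
    held <- numeric(n_splits)
    for (f in seq_len(n_splits)) {
      test_rounds <- fold_of[as.character(blocks)] == f
      ft <- fit_model(dataset, model_id, n_starts = n_starts,
                      seed = seed + 1000L * r + f, score = !test_rounds)
      held[f] <- as.numeric(dataset_nll(dataset, model_id, ft$params,
                                        score = test_rounds))
    }
    per_repeat[r] <- mean(held)
  }
  structure(mean(per_repeat), per_repeat = per_repeat)
}
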