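# Synthetic-participant generation: closes the loop between the task
# environment, the valuation models and the shared policy. The human cohorts
# are not deposited; these generators stand in for them.

#' Simulate one participant
#'
#' Runs the full round loop (value computation, goal stay/switch, action
#' stay/explore, outcome, state updates) for a registered model. The agent's
#' current goal is recorded as the probe response every `probe_interval`-th
#' round; synthetic agents always have a current goal, so "undecided" is never
#' generated.
#'
#' @param config A `game_config` or `drift_config`.
#' @param params A [model_params()] object.
#' @param seed Integer seed; the whole trajectory is reproducible under it.
#' @param participant_id Optional identifier stored in the dataset.
#' @return A `participant_dataset`: list with `participant_id`,
#'   `experiment_id`, `rounds` (one row per round), `config` and `metadata`.
#' @export
simulate_participant <- function(config, params, seed = 1L,
                                 participant_id = "sim_1") {
  stopifnot(inherits(params, "model_params"))
  probs <- round_probs(config)
  targets <- config_targets(config)
  set.seed(seed)
  m <- cpp_simulate(probs, as.integer(targets), config$probe_interval,
                    model_code(params$model_id), pack_params(params))

  n <- nrow(m)
  suits <- config$suits
  offered <- matrix("", n, 3, dimnames = list(NULL, SUITS))
  for (g in 1:3) {
    offered[, g] <- ifelse(m[, g] == 1, suits$card1[g], suits$card2[g])
  }
  chosen_suit <- SUITS[m[, 4]]
  chosen_card <- offered[cbind(seq_len(n), m[, 4])]
  probe <- ifelse(m[, 14] == 1, SUITS[m[, 13]], NA_character_)

  rounds <- data.frame(
    round_index = seq_len(n),
    block_index = round_blocks(config),
    offered_cat = offered[, "cat"],
    offered_hat = offered[, "hat"],
    offered_car = offered[, "car"],
    chosen_suit = chosen_suit,
    chosen_card = chosen_card,
    token_received = as.integer(m[, 5]),
    s_cat_before = as.integer(m[, 6]),
    s_hat_before = as.integer(m[, 7]),
    s_car_before = as.integer(m[, 8]),
    s_cat_after = as.integer(m[, 9]),
    s_hat_after = as.integer(m[, 10]),
    s_car_after = as.integer(m[, 11]),
    suit_completed = as.integer(m[, 12]),
    goal = SUITS[m[, 13]],
    probe_response = probe,
    stringsAsFactors = FALSE
  )

  structure(
    list(
      participant_id = participant_id,
      experiment_id = if (inherits(config, "game_config"))
        config$experiment_id else config$kind,
      rounds = rounds,
      config = config,
      metadata = list(model_id = params$model_id,
                      params = unclass(params)[setdiff(names(params),
                                                       "model_id")],
                      seed = seed)
    ),
    class = "participant_dataset"
  )
}

#' @export
print.participant_dataset <- function(x, ...) {
  cat("<participant_dataset> ", x$participant_id, " (", x$experiment_id,
      "): ", nrow(x$rounds), " rounds, ",
      sum(x$rounds$suit_completed), " suits completed",
      if (!is.null(x$metadata$model_id))
        paste0(", model ", x$metadata$model_id), "\n", sep = "")
  invisible(x)
}

#' Recovery sampling box for a model
#'
#' The uniform ranges used for parameter and model recovery: alpha in
#' `[0, 1]`, cost in `[-1, 1]`, beta_g and beta_a in `[0, 10]`, gamma in
#' `[0.6, 1]`, alpha_ck in `[0, 1]`; model-specific extras (w, k) in `[0, 1]`.
#'
#' @param model_id One of [model_ids()].
#' @return Named list of `c(lower, upper)` ranges over the free parameters.
#' @export
recovery_ranges <- function(model_id) model_info(model_id)$box

#' Human-plausible sampling ranges
#'
#' Narrower ranges emulating the spread of individual participant fits
#' (discount factors concentrated above 0.9, moderate temperatures and
#' learning rates); used to build cohorts for the behavioral-signature and
#' model-recovery studies.
#'
#' @param model_id One of [model_ids()].
#' @return Named list of `c(lower, upper)` ranges over the free parameters.
#' @export
human_plausible_ranges <- function(model_id) {
  plausible <- list(
    alpha = c(0.1, 0.8), gamma = c(0.85, 1), cost = c(-0.2, 1),
    beta_g = c(1, 8), beta_a = c(1, 8), alpha_ck = c(0, 0.5),
    w = c(0.2, 0.8), beta = c(1, 8), beta_ck = c(0, 3), k = c(0.05, 0.5)
  )
  plausible[model_info(model_id)$free]
}

#' Sample a parameter vector uniformly from a box
#'
#' @param model_id One of [model_ids()].
#' @param ranges Named list of `c(lower, upper)` ranges (default the recovery
#'   box).
#' @return A [model_params()] object.
#' @export
sample_params <- function(model_id, ranges = recovery_ranges(model_id)) {
  draws <- lapply(ranges, function(r) runif(1, r[1], r[2]))
  do.call(model_params, c(list(model_id = model_id), draws))
}

# deterministic per-participant seed derived from the master seed
participant_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 104729 + i * 7919) %% 2147483629)
}

#' Generate a synthetic cohort
#'
#' One dataset per participant, each with its own schedule shuffle and
#' outcome stream derived deterministically from the master seed. Parameters
#' are either shared (`params`) or drawn per participant from `ranges`.
#'
#' @param n_participants Number of participants.
#' @param experiment_id Experiment to simulate (`"exp1"` ... `"exp4"`).
#' @param model_id Generating model.
#' @param params Optional fixed [model_params()]; if `NULL`, parameters are
#'   sampled per participant from `ranges`.
#' @param ranges Sampling box when `params` is `NULL` (default
#'   [human_plausible_ranges()]).
#' @param master_seed Master seed for the cohort.
#' @return List of `participant_dataset` objects.
#' @export
generate_cohort <- function(n_participants, experiment_id = "exp1",
                            model_id = "momentum", params = NULL,
                            ranges = human_plausible_ranges(model_id),
                            master_seed = 1L) {
  if (n_participants == 0) return(list())
  lapply(seq_len(n_participants), function(i) {
    s <- participant_seed(master_seed, i)
    config <- make_experiment_config(experiment_id, seed = s)
    set.seed(s + 1L)
    p <- if (is.null(params)) {
      do.call(model_params,
              c(list(model_id = model_id),
                lapply(ranges, function(r) runif(1, r[1], r[2]))))
    } else params
    simulate_participant(config, p, seed = s + 2L,
                         participant_id = sprintf("sim_%03d", i))
  })
}

#' Mean goal-action congruence of a dataset
#'
#' Proportion of rounds where the acted-on suit equals the agent's current
#' goal.
#'
#' @param dataset A `participant_dataset` with a `goal` column.
#' @return Proportion in `[0, 1]`.
#' @export
goal_action_congruence <- function(dataset) {
  mean(dataset$rounds$chosen_suit == dataset$rounds$goal)
}
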