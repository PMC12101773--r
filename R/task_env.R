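# The suits task: three extended goals (cat, hat, car), each a set of
# target_tokens identical tokens collected one at a time by flipping a
# suit-congruent card. A completed suit pays 10 points and its slots empty.
# Play is organised into 30-round blocks with fixed token probabilities; each
# block has one dominant suit, flipped across adjacent blocks.

.block_probs <- list(
  "80-20" = c(0.8, 0.2), "70-30" = c(0.7, 0.3), "60-40" = c(0.6, 0.4),
  "75-25" = c(0.75, 0.25), "55-45" = c(0.55, 0.45)
)

suit_table <- function(experiment_id = "exp1") {
  targets <- if (identical(experiment_id, "exp4")) c(4L, 6L, 8L) else
    c(7L, 7L, 7L)
  data.frame(
    suit_id = SUITS,
    target_tokens = targets,
    reward_points = 10L,
    card1 = c("basket", "wardrobe", "key"),
    card2 = c("mat", "table", "baggage"),
    stringsAsFactors = FALSE
  )
}

# Counterbalanced block schedule by rejection sampling: shuffle the block-type
# multiset and a per-type balanced multiset of dominant suits until no two
# adjacent blocks share a dominant suit.
.schedule_blocks <- function(types, n_per_type, max_tries = 200L) {
  type_seq <- rep(names(types), times = unlist(types))
  n_blocks <- length(type_seq)
  idx_of <- function(ord) lapply(names(types), function(ty) ord == ty)
  balanced <- lapply(unlist(types), function(k)
    rep.int(seq_along(SUITS), rep.int(k %/% 3L, 3L)))
  for (outer in seq_len(max_tries)) {
    ord <- sample(type_seq)
    idx <- idx_of(ord)
    # the type order fixed, re-draw only the dominant assignment
    for (inner in seq_len(2000L)) {
      dom <- integer(n_blocks)
      for (j in seq_along(idx))
        dom[idx[[j]]] <- balanced[[j]][sample.int(length(balanced[[j]]))]
      if (!any(dom[-1L] == dom[-n_blocks])) {
        return(data.frame(block_type = ord, dominant_suit = SUITS[dom],
                          stringsAsFactors = FALSE))
      }
    }
  }
  stop("could not construct a counterbalanced block schedule")
}

#' Build an experiment configuration
#'
#' Experiment 1: 18 blocks (6 each of 80-20/70-30/60-40), 540 rounds, targets
#' of 7. Experiment 2: 12 blocks (6 each of 75-25/55-45), 360 rounds.
#' Experiment 3 is structurally identical to experiment 1 (the instruction
#' manipulation has no simulator-side effect). Experiment 4: 12 blocks (6 each
#' of high/low disparity), targets (4, 6, 8) for (cat, hat, car), with token
#' probabilities set by the expected-rounds identity p = target / E(rounds):
#' 8 expected rounds for the dominant suit, 15 (high disparity) or 12 (low
#' disparity) for the inferior suits. Block order is shuffled under `seed`;
#' the dominant suit flips across adjacent blocks and is balanced across suit
#' types within each block type.
#'
#' @param experiment_id `"exp1"`, `"exp2"`, `"exp3"` or `"exp4"`.
#' @param seed Integer seed for the schedule shuffle.
#' @return A `game_config` list with elements `experiment_id`, `suits`,
#'   `blocks`, `probe_interval` (3) and `rng_seed`.
#' @export
make_experiment_config <- function(experiment_id, seed = 1L) {
  if (!experiment_id %in% c("exp1", "exp2", "exp3", "exp4"))
    stop("unknown experiment_id: ", experiment_id)
  set.seed(seed)
  suits <- suit_table(experiment_id)

  if (experiment_id %in% c("exp1", "exp3")) {
    sched <- .schedule_blocks(list(`80-20` = 6L, `70-30` = 6L, `60-40` = 6L))
  } else if (experiment_id == "exp2") {
    sched <- .schedule_blocks(list(`75-25` = 6L, `55-45` = 6L))
  } else {
    sched <- .schedule_blocks(list(`H disp` = 6L, `L disp` = 6L))
  }

  n_blocks <- nrow(sched)
  pm <- matrix(NA_real_, n_blocks, 3, dimnames = list(NULL, SUITS))
  for (i in seq_len(n_blocks)) {
    ty <- sched$block_type[i]
    dom <- sched$dominant_suit[i]
    if (experiment_id == "exp4") {
      e_rounds <- ifelse(SUITS == dom, 8,
                         if (ty == "H disp") 15 else 12)
      pm[i, ] <- pmin(1, suits$target_tokens / e_rounds)
    } else {
      pr <- .block_probs[[ty]]
      pm[i, ] <- ifelse(SUITS == dom, pr[1], pr[2])
    }
  }

  blocks <- data.frame(
    block_index = seq_len(n_blocks),
    block_type = sched$block_type,
    n_rounds = 30L,
    dominant_suit = sched$dominant_suit,
    stringsAsFactors = FALSE
  )
  blocks$p_cat <- pm[, "cat"]; blocks$p_hat <- pm[, "hat"]
  blocks$p_car <- pm[, "car"]

  structure(
    list(experiment_id = experiment_id, suits = suits, blocks = blocks,
         probe_interval = 3L, rng_seed = seed),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config> ", x$experiment_id, ": ", nrow(x$blocks), " blocks, ",
      sum(x$blocks$n_rounds), " rounds, targets (",
      paste(x$suits$target_tokens, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Drifting-probability environments for the normative simulations
#'
#' Initial token probabilities are drawn U(0.2, 0.3), U(0.2, 0.3) and
#' U(0.7, 0.8) for the three suits. Under `"random_walk"` each probability
#' takes an additive Gaussian step of sd 0.025 every round, clipped to
#' (0.001, 0.999); under `"reversal"` the probability vector is shuffled among
#' the suits every 30 rounds.
#'
#' @param kind `"random_walk"` or `"reversal"`.
#' @param n_rounds Number of rounds.
#' @param seed Integer seed.
#' @return A `drift_config` with a per-round probability matrix.
#' @export
make_drift_environment <- function(kind = c("random_walk", "reversal"),
                                   n_rounds = 270L, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  p <- c(runif(1, 0.2, 0.3), runif(1, 0.2, 0.3), runif(1, 0.7, 0.8))
  probs <- matrix(NA_real_, n_rounds, 3, dimnames = list(NULL, SUITS))
  for (t in seq_len(n_rounds)) {
    if (kind == "random_walk") {
      if (t > 1) p <- pmin(pmax(p + rnorm(3, 0, 0.025), 0.001), 0.999)
    } else {
      if (t > 1 && (t - 1) %% 30 == 0) p <- p[sample(3)]
    }
    probs[t, ] <- p
  }
  structure(
    list(kind = kind, suits = suit_table("exp1"), probs = probs,
         probe_interval = 3L, rng_seed = seed),
    class = "drift_config"
  )
}

#' Per-round token probability matrix of a configuration
#'
#' @param config A `game_config` or `drift_config`.
#' @return Numeric matrix (rounds x 3 suits) of token probabilities.
#' @export
round_probs <- function(config) {
  if (inherits(config, "drift_config")) return(config$probs)
  stopifnot(inherits(config, "game_config"))
  b <- config$blocks
  pm <- as.matrix(b[, c("p_cat", "p_hat", "p_car")])
  out <- pm[rep(seq_len(nrow(b)), b$n_rounds), , drop = FALSE]
  colnames(out) <- SUITS
  out
}

#' Block index of every round
#' @param config A `game_config` or `drift_config`.
#' @return Integer vector, one element per round.
#' @export
round_blocks <- function(config) {
  if (inherits(config, "drift_config"))
    return(as.integer(ceiling(seq_len(nrow(config$probs)) / 30)))
  rep(config$blocks$block_index, config$blocks$n_rounds)
}

config_targets <- function(config) {
  setNames(config$suits$target_tokens, config$suits$suit_id)
}

#' Empty slot state
#' @param config A `game_config` or `drift_config`.
#' @return A `slot_state` list with per-suit token `counts` and `points`.
#' @export
new_slot_state <- function(config) {
  structure(list(counts = setNames(rep(0L, 3), SUITS), points = 0L),
            class = "slot_state")
}

#' Fractional progress m of every suit
#' @param state A `slot_state`.
#' @param config The configuration the state belongs to.
#' @return Named numeric vector in `[0, 1)`.
#' @export
fractional_progress <- function(state, config) {
  state$counts / config_targets(config)
}

#' Offer one card per suit
#'
#' Each suit owns two cards; one is shown per round, chosen uniformly. The
#' card identity never affects token probabilities.
#'
#' @param config A `game_config`.
#' @return Named character vector, suit -> offered card.
#' @export
deal_cards <- function(config) {
  s <- config$suits
  pick <- runif(3) < 0.5
  setNames(ifelse(pick, s$card1, s$card2), s$suit_id)
}

#' Resolve a single round of the task
#'
#' A token for the chosen suit is drawn Bernoulli(p) with p taken from the
#' block; cross-suit token probability is exactly zero. When a suit's count
#' reaches its target, the count resets to zero within the same round and the
#' suit's reward points are banked.
#'
#' @param config A `game_config`.
#' @param state Current `slot_state`.
#' @param block One row of `config$blocks` (or a block index).
#' @param chosen_suit Suit whose card was flipped.
#' @return List with `token_received` (0/1), `new_state`, `suit_completed`
#'   (0/1).
#' @export
resolve_round <- function(config, state, block, chosen_suit) {
  stopifnot(chosen_suit %in% SUITS)
  if (is.numeric(block)) block <- config$blocks[block, ]
  p <- block[[paste0("p_", chosen_suit)]]
  token <- as.integer(runif(1) < p)
  completed <- 0L
  if (token == 1L) {
    state$counts[chosen_suit] <- state$counts[chosen_suit] + 1L
    tgt <- config_targets(config)[chosen_suit]
    if (state$counts[chosen_suit] >= tgt) {
      state$counts[chosen_suit] <- 0L
      rw <- config$suits$reward_points[config$suits$suit_id == chosen_suit]
      state$points <- state$points + rw
      completed <- 1L
    }
  }
  list(token_received = token, new_state = state, suit_completed = completed)
}
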