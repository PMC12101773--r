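# Small hand-built configurations and an outcome-enumeration oracle used
# across the suite.

# single-block toy configuration with arbitrary probabilities and length
toy_config <- function(p = c(cat = 0.8, hat = 0.2, car = 0.2),
                       n_rounds = 30L, targets = c(7L, 7L, 7L),
                       dominant = names(p)[which.max(p)]) {
  suits <- data.frame(
    suit_id = c("cat", "hat", "car"),
    target_tokens = targets,
    reward_points = 10L,
    card1 = c("basket", "wardrobe", "key"),
    card2 = c("mat", "table", "baggage"),
    stringsAsFactors = FALSE
  )
  blocks <- data.frame(
    block_index = 1L, block_type = "toy", n_rounds = as.integer(n_rounds),
    dominant_suit = dominant, p_cat = unname(p["cat"]),
    p_hat = unname(p["hat"]), p_car = unname(p["car"]),
    stringsAsFactors = FALSE
  )
  structure(list(experiment_id = "toy", suits = suits, blocks = blocks,
                 probe_interval = 3L, rng_seed = NA_integer_),
            class = "game_config")
}

# hand-built participant dataset from explicit choices/outcomes
manual_dataset <- function(config, chosen_suit, token, probe_response) {
  n <- length(chosen_suit)
  targets <- setNames(config$suits$target_tokens, config$suits$suit_id)
  s <- setNames(rep(0L, 3), c("cat", "hat", "car"))
  sb <- sa <- matrix(0L, n, 3, dimnames = list(NULL, names(s)))
  completed <- integer(n)
  for (t in seq_len(n)) {
    sb[t, ] <- s
    if (token[t] == 1L) {
      s[chosen_suit[t]] <- s[chosen_suit[t]] + 1L
      if (s[chosen_suit[t]] >= targets[chosen_suit[t]]) {
        s[chosen_suit[t]] <- 0L
        completed[t] <- 1L
      }
    }
    sa[t, ] <- s
  }
  rounds <- data.frame(
    round_index = seq_len(n),
    block_index = rep(config$blocks$block_index,
                      config$blocks$n_rounds)[seq_len(n)],
    offered_cat = "basket", offered_hat = "wardrobe", offered_car = "key",
    chosen_suit = chosen_suit, chosen_card = "x",
    token_received = as.integer(token),
    s_cat_before = sb[, 1], s_hat_before = sb[, 2], s_car_before = sb[, 3],
    s_cat_after = sa[, 1], s_hat_after = sa[, 2], s_car_after = sa[, 3],
    suit_completed = completed,
    goal = NA_character_, probe_response = probe_response,
    stringsAsFactors = FALSE
  )
  structure(list(participant_id = "manual", experiment_id = "toy",
                 rounds = rounds, config = config, metadata = list()),
            class = "participant_dataset")
}

# Independent oracle for the discounted belief rollout: enumerate every
# binary outcome sequence of length `horizon` and accumulate the discounted
# terminal reward of the first round where `togo` successes are reached.
enumeration_rollout <- function(M, gamma, togo, horizon, reward = 1) {
  if (togo == 0) return(reward)
  if (horizon == 0) return(0)
  grid <- as.matrix(expand.grid(rep(list(0:1), horizon)))
  val <- 0
  for (i in seq_len(nrow(grid))) {
    sq <- grid[i, ]
    pr <- prod(ifelse(sq == 1, M, 1 - M))
    hit <- unname(which(cumsum(sq) >= togo))[1]
    if (!is.na(hit)) val <- val + pr * gamma^hit * reward
  }
  unname(val)
}

suit_names <- c("cat", "hat", "car")
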