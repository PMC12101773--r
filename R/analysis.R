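# Behavioral-signature computation, task-performance optimization, and the
# recovery / normative simulation studies.

#' Classify every round of a dataset
#'
#' Labels each round with the block's dominant suit, the max-progress
#' (retrospective) suit, and the prospective suit: the deterministic greedy
#' choice of a discounted belief-rollout agent whose beliefs are the true
#' block probabilities. Ties in max progress yield `NA` (no unique
#' retrospective suit) and are excluded from conflict analyses; prospective
#' ties break toward the dominant suit.
#'
#' @param dataset A `participant_dataset` simulated on a `game_config`.
#' @param gamma Discount factor of the classifying prospective agent
#'   (default 0.95, the task-optimized value for the 18-block experiment).
#' @param horizon Rollout horizon (default 20).
#' @return Data frame with one row per round: `block_type`, `dominant_suit`,
#'   `max_progress_suit`, `prospective_suit`, `retrospective_suit`,
#'   `conflict`, and the fractional progress of the dominant and max-progress
#'   suits.
#' @export
classify_rounds <- function(dataset, gamma = 0.95, horizon = 20L) {
  config <- dataset$config
  stopifnot(inherits(config, "game_config"))
  r <- dataset$rounds
  targets <- config_targets(config)
  blocks <- config$blocks
  bt <- blocks$block_type[r$block_index]
  dom <- blocks$dominant_suit[r$block_index]
  probs <- round_probs(config)

  sb <- as.matrix(r[, c("s_cat_before", "s_hat_before", "s_car_before")])
  colnames(sb) <- SUITS
  m <- sweep(sb, 2, targets, "/")

  n <- nrow(r)
  maxprog <- character(n)
  prosp <- character(n)
  for (t in seq_len(n)) {
    mx <- m[t, ]
    top <- which(mx >= max(mx) - 1e-12)
    maxprog[t] <- if (length(top) == 1) SUITS[top] else NA_character_
    q <- vapply(1:3, function(g) cpp_prospective_value(
      probs[t, g], gamma, sb[t, g], targets[[g]], horizon, 1), numeric(1))
    best <- which(q >= max(q) - 1e-9)
    di <- match(dom[t], SUITS)
    prosp[t] <- if (di %in% best) dom[t] else SUITS[best[1]]
  }

  data.frame(
    round_index = r$round_index,
    block_index = r$block_index,
    block_type = bt,
    dominant_suit = dom,
    max_progress_suit = maxprog,
    prospective_suit = prosp,
    retrospective_suit = maxprog,
    conflict = !is.na(maxprog) & prosp != maxprog,
    m_dominant = m[cbind(seq_len(n), match(dom, SUITS))],
    m_max_progress = apply(m, 1, max),
    stringsAsFactors = FALSE
  )
}

.mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

#' Behavioral signature tables of a cohort
#'
#' Pools rounds across datasets and computes the aggregates that
#' characterize retrospective bias: choice shares among
#' dominant / max-progress / third suit on conflict rounds by block type;
#' max-progress preference by fractional progress-difference bin; switch-away
#' rates by suit class (prospective vs retrospective), token outcome and
#' block type, and split by high/low (>50%) progress difference; dominant
#' choice by block half; and suits completed per block by block type. Empty
#' cells are reported as missing.
#'
#' @param datasets List of `participant_dataset` objects.
#' @param classifications Optional list of [classify_rounds()] outputs
#'   (computed with `gamma` if omitted).
#' @param gamma Discount factor for the prospective classification.
#' @return A `signature_table` list of tidy data frames.
#' @export
signature_table <- function(datasets, classifications = NULL, gamma = 0.95) {
  if (!length(datasets)) stop("need at least one dataset")
  if (is.null(classifications))
    classifications <- lapply(datasets, classify_rounds, gamma = gamma)

  pooled <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    cl <- classifications[[i]]
    r <- datasets[[i]]$rounds
    cl$chosen_suit <- r$chosen_suit
    cl$token_received <- r$token_received
    cl$suit_completed <- r$suit_completed
    cl$within_block_round <- r$round_index -
      30L * (r$block_index - 1L)
    nr <- nrow(r)
    cl$next_chosen <- c(r$chosen_suit[-1], NA)
    cl$next_in_same_game <- c(rep(TRUE, nr - 1), FALSE)
    cl$participant <- datasets[[i]]$participant_id
    cl
  }))

  # conflict between accrued progress and current rate of progress
  dm_conflict <- !is.na(pooled$max_progress_suit) &
    pooled$max_progress_suit != pooled$dominant_suit
  dmc <- pooled[dm_conflict, ]
  choice_shares <- do.call(rbind, lapply(split(dmc, dmc$block_type),
    function(d) data.frame(
      block_type = d$block_type[1],
      n = nrow(d),
      p_dominant = mean(d$chosen_suit == d$dominant_suit),
      p_max_progress = mean(d$chosen_suit == d$max_progress_suit),
      p_third = mean(d$chosen_suit != d$dominant_suit &
                       d$chosen_suit != d$max_progress_suit),
      stringsAsFactors = FALSE)))
  rownames(choice_shares) <- NULL

  # max-progress preference vs fractional progress difference
  dmc$prog_diff <- dmc$m_max_progress - dmc$m_dominant
  brk <- seq(0, 1, by = 1 / 7)
  dmc$diff_bin <- cut(pmin(dmc$prog_diff, 1 - 1e-9), breaks = brk,
                      include.lowest = TRUE)
  prog_diff_pref <- do.call(rbind, lapply(split(dmc, dmc$diff_bin),
    function(d) data.frame(
      diff_bin = if (nrow(d)) as.character(d$diff_bin[1]) else NA,
      bin_mid = if (nrow(d)) mean(d$prog_diff) else NA_real_,
      n = nrow(d),
      p_max_progress = .mean_or_na(d$chosen_suit == d$max_progress_suit),
      stringsAsFactors = FALSE)))
  prog_diff_pref <- prog_diff_pref[prog_diff_pref$n > 0, ]
  rownames(prog_diff_pref) <- NULL

  # switches away from the prospective vs the retrospective suit
  pr_conflict <- pooled$conflict & pooled$next_in_same_game
  sw <- pooled[pr_conflict, ]
  sw$suit_class <- ifelse(sw$chosen_suit == sw$prospective_suit,
                          "prospective",
                   ifelse(sw$chosen_suit == sw$retrospective_suit,
                          "retrospective", NA))
  sw <- sw[!is.na(sw$suit_class), ]
  sw$switched <- sw$next_chosen != sw$chosen_suit
  key <- interaction(sw$suit_class, sw$token_received, sw$block_type,
                     drop = TRUE)
  switch_rates <- do.call(rbind, lapply(split(sw, key), function(d)
    data.frame(
      suit_class = d$suit_class[1], token = d$token_received[1],
      block_type = d$block_type[1], n = nrow(d),
      p_switch = mean(d$switched), stringsAsFactors = FALSE)))
  rownames(switch_rates) <- NULL

  sw$diff_split <- ifelse(abs(sw$m_max_progress - sw$m_dominant) > 0.5,
                          "high", "low")
  key2 <- interaction(sw$suit_class, sw$diff_split, drop = TRUE)
  switch_by_diff <- do.call(rbind, lapply(split(sw, key2), function(d)
    data.frame(
      suit_class = d$suit_class[1], diff_split = d$diff_split[1],
      n = nrow(d), p_switch = mean(d$switched), stringsAsFactors = FALSE)))
  rownames(switch_by_diff) <- NULL

  # dominant choice by block half (learning within blocks)
  pooled$block_half <- ifelse(pooled$within_block_round <= 15L,
                              "first", "second")
  key3 <- interaction(pooled$block_type, pooled$block_half, drop = TRUE)
  block_half <- do.call(rbind, lapply(split(pooled, key3), function(d)
    data.frame(
      block_type = d$block_type[1], block_half = d$block_half[1],
      n = nrow(d), p_dominant = mean(d$chosen_suit == d$dominant_suit),
      stringsAsFactors = FALSE)))
  rownames(block_half) <- NULL

  # suits completed per block, by block type
  key4 <- interaction(pooled$participant, pooled$block_index, drop = TRUE)
  per_block <- do.call(rbind, lapply(split(pooled, key4), function(d)
    data.frame(block_type = d$block_type[1],
               completed = sum(d$suit_completed),
               stringsAsFactors = FALSE)))
  performance <- do.call(rbind, lapply(split(per_block,
                                             per_block$block_type),
    function(d) data.frame(block_type = d$block_type[1],
                           n_blocks = nrow(d),
                           mean_completed = mean(d$completed),
                           stringsAsFactors = FALSE)))
  rownames(performance) <- NULL

  structure(
    list(choice_shares = choice_shares, prog_diff_pref = prog_diff_pref,
         switch_rates = switch_rates, switch_by_diff = switch_by_diff,
         block_half = block_half, performance = performance),
    class = "signature_table"
  )
}

#' @export
print.signature_table <- function(x, ...) {
  cat("<signature_table>\n\nChoice shares on conflict rounds:\n")
  print(x$choice_shares)
  cat("\nMax-progress preference by progress-difference bin:\n")
  print(x$prog_diff_pref)
  invisible(x)
}

#' Mean task performance of a parameterized agent
#'
#' Simulates `length(game_seeds)` games and returns the mean number of suits
#' completed. For an experiment identifier the block schedule is re-shuffled
#' per game seed; for a fixed (`game_config` or `drift_config`) environment
#' only the outcome stream varies.
#'
#' @param params A [model_params()] object.
#' @param experiment Experiment id (`"exp1"` ...) or a configuration object.
#' @param game_seeds Integer vector of game seeds.
#' @return Mean suits completed.
#' @export
evaluate_performance <- function(params, experiment, game_seeds) {
  mean(vapply(game_seeds, function(s) {
    config <- if (is.character(experiment))
      make_experiment_config(experiment, seed = s) else experiment
    set.seed(s)
    m <- cpp_simulate(round_probs(config),
                      as.integer(config_targets(config)),
                      config$probe_interval, model_code(params$model_id),
                      pack_params(params))
    sum(m[, 12])
  }, numeric(1)))
}

# parameter box used when optimizing for task performance (discounting is
# allowed below the fitting range so the optimum is interior)
.performance_box <- function(model_id) {
  box <- model_info(model_id)$box
  if ("gamma" %in% names(box)) box$gamma <- c(0.5, 1)
  box
}

#' Optimize a model's parameters for task performance
#'
#' Maximizes the mean number of suits completed over simulated games with
#' common random numbers: a maximin Latin-hypercube exploration of the
#' parameter box (`budget` candidates, `n_seeds` games each), Nelder-Mead
#' refinement of the best candidate on doubled seeds, and — for discounting
#' models — a two-pass profile of the discount factor with the other
#' parameters held at their refined optimum: a coarse pass (step 0.01 over a
#' +/- 0.12 window, 6 x `n_seeds` games per point) followed by a
#' high-precision fine pass (step 0.005 over +/- 0.05 around the coarse
#' peak, 24 x `n_seeds` games per point) whose local quadratic vertex is the
#' reported discount factor.
#'
#' @param model_id One of [model_ids()].
#' @param experiment Experiment id or a configuration object.
#' @param budget Number of exploration candidates (default 100).
#' @param n_seeds Games per candidate in the exploration stage (default 50).
#' @param seed Optimizer seed.
#' @param gamma_profile Whether to run the discount-factor profiling stage.
#' @return List with `params` (the optimized [model_params()]), `score`
#'   (mean suits completed at the optimum), and `gamma_curve` (the profiled
#'   discount trace, when run).
#' @export
optimize_performance <- function(model_id, experiment, budget = 100L,
                                 n_seeds = 50L, seed = 1L,
                                 gamma_profile = TRUE) {
  box <- .performance_box(model_id)
  k <- length(box)
  seeds1 <- participant_seed(seed, seq_len(n_seeds))
  seeds2 <- participant_seed(seed + 1L, seq_len(2L * n_seeds))

  mk_params <- function(theta) {
    pl <- as.list(theta)
    names(pl) <- names(box)
    do.call(model_params, c(list(model_id = model_id), pl))
  }

  set.seed(seed)
  U <- lhs::maximinLHS(budget, k)
  cand <- t(apply(U, 1, .box_transform, box = box))
  vals <- apply(cand, 1, function(th)
    evaluate_performance(mk_params(th), experiment, seeds1))
  best <- cand[which.max(vals), ]

  lo <- vapply(box, `[`, numeric(1), 1)
  hi <- vapply(box, `[`, numeric(1), 2)
  from_z <- function(z) lo + (hi - lo) * plogis(z)
  to_z <- function(th) qlogis(pmin(pmax((th - lo) / (hi - lo), 1e-6),
                                   1 - 1e-6))
  ref <- optim(to_z(best), function(z)
    -evaluate_performance(mk_params(from_z(z)), experiment, seeds2),
    method = "Nelder-Mead", control = list(maxit = 60L))
  theta <- from_z(ref$par)

  gamma_curve <- NULL
  if (gamma_profile && "gamma" %in% names(box)) {
    score_at <- function(g, seeds) {
      th <- theta
      th[["gamma"]] <- g
      evaluate_performance(mk_params(th), experiment, seeds)
    }
    # coarse pass over a window around the refined value
    seeds3 <- participant_seed(seed + 2L, seq_len(6L * n_seeds))
    g_hat <- theta[["gamma"]]
    coarse <- seq(max(box$gamma[1], g_hat - 0.12),
                  min(box$gamma[2], g_hat + 0.12), by = 0.01)
    prof_c <- vapply(coarse, score_at, numeric(1), seeds = seeds3)
    g0 <- coarse[which.max(prof_c)]
    # fine pass at high precision; the local quadratic vertex is a less
    # biased peak estimate than global smoothing on an asymmetric profile
    seeds4 <- participant_seed(seed + 3L, seq_len(24L * n_seeds))
    fine <- seq(max(box$gamma[1], g0 - 0.05),
                min(box$gamma[2], g0 + 0.05), by = 0.005)
    prof_f <- vapply(fine, score_at, numeric(1), seeds = seeds4)
    qf <- stats::lm(prof_f ~ fine + I(fine^2))
    cf <- stats::coef(qf)
    vertex <- if (is.finite(cf[3]) && cf[3] < 0)
      -cf[2] / (2 * cf[3]) else fine[which.max(prof_f)]
    if (vertex < min(fine) || vertex > max(fine))
      vertex <- fine[which.max(prof_f)]
    theta[["gamma"]] <- min(max(vertex, box$gamma[1]), box$gamma[2])
    gamma_curve <- list(coarse = data.frame(gamma = coarse, score = prof_c),
                        fine = data.frame(gamma = fine, score = prof_f))
  }

  params <- mk_params(theta)
  list(model_id = model_id, params = params,
       score = evaluate_performance(params, experiment, seeds2),
       gamma_curve = gamma_curve)
}

#' Parameter recovery study
#'
#' Samples `n_vectors` parameter vectors from the recovery box, simulates a
#' participant per vector, refits the generating model, and correlates
#' fitted with true values per free parameter.
#'
#' @param model_id Generating model (default `"momentum"`).
#' @param n_vectors Number of parameter vectors.
#' @param experiment_id Experiment simulated (default `"exp1"`).
#' @param seed Master seed.
#' @param n_starts Random starts per fit.
#' @return List with `correlations` (named vector over free parameters),
#'   `true` and `fitted` data frames.
#' @export
parameter_recovery_study <- function(model_id = "momentum",
                                     n_vectors = 100L,
                                     experiment_id = "exp1", seed = 1L,
                                     n_starts = 100L) {
  free <- model_info(model_id)$free
  if (n_vectors == 0)
    return(list(correlations = setNames(numeric(0), character(0)),
                true = NULL, fitted = NULL))
  true_m <- matrix(NA_real_, n_vectors, length(free),
                   dimnames = list(NULL, free))
  fit_m <- true_m
  for (i in seq_len(n_vectors)) {
    s <- participant_seed(seed, i)
    config <- make_experiment_config(experiment_id, seed = s)
    set.seed(s + 1L)
    tp <- sample_params(model_id)
    ds <- simulate_participant(config, tp, seed = s + 2L,
                               participant_id = sprintf("rec_%03d", i))
    ft <- fit_model(ds, model_id, n_starts = n_starts, seed = s + 3L)
    true_m[i, ] <- vapply(free, function(nm) tp[[nm]], numeric(1))
    fit_m[i, ] <- vapply(free, function(nm) ft$params[[nm]], numeric(1))
  }
  corrs <- vapply(free, function(nm) cor(true_m[, nm], fit_m[, nm]),
                  numeric(1))
  list(correlations = corrs, true = as.data.frame(true_m),
       fitted = as.data.frame(fit_m))
}

#' Model recovery study
#'
#' Simulates `n_vectors` participants from each generating model (parameters
#' sampled from the human-plausible ranges), fits every candidate model to
#' every dataset, and tabulates BIC winners as confusion matrices under both
#' normalizations.
#'
#' @param model_ids Models entering the study (default the four fitted
#'   goal-valuation models).
#' @param n_vectors Parameter vectors per generating model.
#' @param experiment_id Experiment simulated.
#' @param seed Master seed.
#' @param n_starts Random starts per fit.
#' @param ... Further arguments passed to [fit_model()] (e.g. `refine_top`,
#'   `maxit`).
#' @return List with `p_fit_given_sim` (rows sum to 1), `p_sim_given_fit`
#'   (columns of the count matrix normalized), `counts`, and `bic` (the full
#'   generating-model x dataset x fitted-model BIC array).
#' @export
model_recovery_study <- function(model_ids = c("momentum", "prospective",
                                               "td_persistence", "hybrid"),
                                 n_vectors = 20L, experiment_id = "exp1",
                                 seed = 1L, n_starts = 60L, ...) {
  stopifnot(length(model_ids) >= 2)
  nm <- length(model_ids)
  counts <- matrix(0L, nm, nm, dimnames = list(sim = model_ids,
                                               fit = model_ids))
  bic <- array(NA_real_, c(nm, n_vectors, nm),
               dimnames = list(model_ids, NULL, model_ids))
  for (gi in seq_len(nm)) {
    gen <- model_ids[gi]
    rng <- human_plausible_ranges(gen)
    for (i in seq_len(n_vectors)) {
      s <- participant_seed(seed + 17L * gi, i)
      config <- make_experiment_config(experiment_id, seed = s)
      set.seed(s + 1L)
      tp <- do.call(model_params,
                    c(list(model_id = gen),
                      lapply(rng, function(r) runif(1, r[1], r[2]))))
      ds <- simulate_participant(config, tp, seed = s + 2L)
      for (fi in seq_len(nm)) {
        ft <- fit_model(ds, model_ids[fi], n_starts = n_starts,
                        seed = s + 3L + fi, ...)
        bic[gi, i, fi] <- ft$bic
      }
      win <- which.min(bic[gi, i, ])
      counts[gi, win] <- counts[gi, win] + 1L
    }
  }
  p_fit_given_sim <- counts / rowSums(counts)
  csum <- colSums(counts)
  p_sim_given_fit <- sweep(counts, 2, ifelse(csum > 0, csum, 1), "/")
  list(p_fit_given_sim = p_fit_given_sim,
       p_sim_given_fit = p_sim_given_fit, counts = counts, bic = bic)
}

#' Normative comparison of momentum and prospection
#'
#' For each drifting environment, optimizes the TD-momentum and prospective
#' agents independently for task performance and records their mean suits
#' completed, pairing the two scores per environment.
#'
#' @param kinds Environment kinds (default both `"random_walk"` and
#'   `"reversal"`).
#' @param n_environments Environments per kind.
#' @param budget Exploration candidates per optimization.
#' @param n_seeds Games per candidate.
#' @param seed Master seed.
#' @param n_rounds Rounds per environment (default 270, nine 30-round
#'   segments).
#' @return Data frame with one row per (kind, environment, model) and the
#'   optimized mean performance.
#' @export
normative_comparison <- function(kinds = c("random_walk", "reversal"),
                                 n_environments = 20L, budget = 40L,
                                 n_seeds = 10L, seed = 1L,
                                 n_rounds = 270L) {
  out <- list()
  for (ki in seq_along(kinds)) {
    kind <- kinds[ki]
    for (i in seq_len(n_environments)) {
      env <- make_drift_environment(kind, n_rounds = n_rounds,
                                    seed = participant_seed(seed + ki, i))
      for (model in c("momentum", "prospective")) {
        opt <- optimize_performance(model, env, budget = budget,
                                    n_seeds = n_seeds,
                                    seed = participant_seed(seed + 7L * ki,
                                                            i),
                                    gamma_profile = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          kind = kind, environment = i, model = model, score = opt$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
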