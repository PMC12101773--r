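# R-side sum-product forward pass mirroring the documented likelihood
# algorithm, built from the exported policy/valuation operations; used to
# cross-check the compiled forward pass.
r_forward_nll <- function(dataset, model_id, params) {
  cfg <- dataset$config
  r <- dataset$rounds
  st <- init_valuation_state(cfg)
  targets <- setNames(cfg$suits$target_tokens, cfg$suits$suit_id)
  bel <- NULL
  nll <- 0
  for (t in seq_len(nrow(r))) {
    Q <- goal_values(model_id, st, params, cfg)
    a <- r$chosen_suit[t]
    if (model_id == "rw_ck") {
      pr <- rw_ck_probs(st$rwq, st$kernels, params$beta, params$beta_ck)
      nll <- nll - log(max(pr[[a]], 1e-12))
      st$kernels <- update_kernel(st$kernels, a, params$alpha_ck)
    } else {
      if (is.null(bel)) {
        bel <- exp(params$beta_g * Q) / sum(exp(params$beta_g * Q))
      } else {
        trans <- goal_transition_matrix(Q, params, st$kernels)
        bel <- propagate_latent_goal(bel, trans)
      }
      pg <- r$probe_response[t]
      if (!is.na(pg) && pg != "undecided") {
        nll <- nll - log(max(bel[[pg]], 1e-12))
        bel <- setNames(as.numeric(names(bel) == pg), names(bel))
      }
      st$kernels <- st$kernels + params$alpha_ck * (bel - st$kernels)
      ap <- action_prob_matrix(Q, params, st$kernels)
      nll <- nll - log(max(sum(bel * ap[, a]), 1e-12))
    }
    tok <- r$token_received[t]
    if (model_id %in% c("prospective", "td_persistence", "hybrid")) {
      st$M[a] <- belief_update(st$M[[a]], tok, params$alpha)
    } else if (model_id == "momentum") {
      m0 <- st$counts[[a]] / targets[[a]]
      m1 <- (st$counts[[a]] + tok) / targets[[a]]
      up <- momentum_update(st$v[[a]], st$b[[a]], m0, m1, params$gamma,
                            params$alpha)
      st$v[a] <- up$v; st$b[a] <- up$b
    } else if (model_id == "rw_ck") {
      st$rwq[a] <- st$rwq[[a]] + params$alpha * (tok - st$rwq[[a]])
    }
    if (tok == 1) {
      st$counts[a] <- st$counts[[a]] + 1L
      if (st$counts[[a]] >= targets[[a]]) st$counts[a] <- 0L
    }
  }
  nll
}

test_that("latent-goal propagation obeys the Markov-chain identities", {
  bel <- c(cat = 1, hat = 0, car = 0)
  expect_equal(propagate_latent_goal(bel, diag(3)), bel, ignore_attr = TRUE)

  # doubly stochastic transition preserves the uniform belief
  Tm <- matrix(c(0.6, 0.2, 0.2, 0.2, 0.6, 0.2, 0.2, 0.2, 0.6), 3, 3,
               byrow = TRUE, dimnames = list(suit_names, suit_names))
  u <- setNames(rep(1 / 3, 3), suit_names)
  expect_equal(propagate_latent_goal(u, Tm), u)

  # two one-step propagations equal one two-step propagation
  v <- vals3 <- c(cat = 0.7, hat = 0.4, car = 0.2)
  p <- model_params("momentum", beta_g = 3, cost = 0.1)
  k <- c(cat = 0.2, hat = 0, car = 0.4)
  Tr <- goal_transition_matrix(v, p, k)
  b0 <- c(cat = 0.5, hat = 0.3, car = 0.2)
  one_one <- propagate_latent_goal(propagate_latent_goal(b0, Tr), Tr)
  two <- propagate_latent_goal(b0, Tr %*% Tr)
  expect_equal(one_one, two, tolerance = 1e-12)

  expect_error(propagate_latent_goal(c(cat = 1, hat = 1, car = 0), Tm),
               "sum to 1")
})

test_that("marginal action likelihood integrates over the latent goal", {
  ap <- matrix(1 / 3, 3, 3, dimnames = list(suit_names, suit_names))
  u <- setNames(rep(1 / 3, 3), suit_names)
  expect_equal(action_likelihood(u, ap, "hat"), 1 / 3)

  # point-mass belief reduces to the conditional probability
  v <- c(cat = 0.9, hat = 0.2, car = 0.1)
  p <- model_params("momentum", beta_a = 4, cost = 0.5)
  apm <- action_prob_matrix(v, p, c(cat = 0, hat = 0, car = 0))
  pm <- c(cat = 0, hat = 1, car = 0)
  expect_equal(action_likelihood(pm, apm, "car"), apm["hat", "car"],
               ignore_attr = TRUE)
  expect_warning(
    expect_equal(action_likelihood(c(cat = 1, hat = 0, car = 0),
                                   matrix(c(0, 1, 1, 0, 0, 0, 1, 0, 0), 3,
                                          dimnames = list(suit_names,
                                                          suit_names)),
                                   "cat"), 1e-12),
    "floored")
})

test_that("the forward pass equals exhaustive latent-path enumeration", {
  # 3-round hand-built dataset; alpha_ck = 0 keeps the per-round transition
  # matrices path-independent so the path sum is exact
  cfg <- toy_config(p = c(cat = 0.8, hat = 0.2, car = 0.2), n_rounds = 3L)
  ds <- manual_dataset(cfg, chosen_suit = c("cat", "cat", "hat"),
                       token = c(1L, 0L, 1L),
                       probe_response = c(NA, NA, "cat"))

  for (model_id in c("momentum", "td_persistence")) {
    params <- model_params(model_id, alpha = 0.35, gamma = 0.9, cost = 0.3,
                           beta_g = 2.5, beta_a = 3.5, alpha_ck = 0)

    # per-round values from an R-side state evolved on observed data
    st <- init_valuation_state(cfg)
    Qs <- vector("list", 3)
    for (t in 1:3) {
      Qs[[t]] <- goal_values(model_id, st, params, cfg)
      a <- ds$rounds$chosen_suit[t]
      tok <- ds$rounds$token_received[t]
      if (model_id == "momentum") {
        m0 <- st$counts[[a]] / 7
        up <- momentum_update(st$v[[a]], st$b[[a]], m0, m0 + tok / 7,
                              params$gamma, params$alpha)
        st$v[a] <- up$v; st$b[a] <- up$b
      } else {
        st$M[a] <- belief_update(st$M[[a]], tok, params$alpha)
      }
      if (tok) st$counts[a] <- st$counts[[a]] + 1L
    }
    k0 <- setNames(rep(0, 3), suit_names)
    trans <- lapply(2:3, function(t)
      goal_transition_matrix(Qs[[t]], params, k0))
    aps <- lapply(1:3, function(t)
      action_prob_matrix(Qs[[t]], params, k0))
    p1 <- exp(params$beta_g * Qs[[1]]) / sum(exp(params$beta_g * Qs[[1]]))

    # enumerate all 27 latent goal paths to get the marginal beliefs
    paths <- expand.grid(g1 = suit_names, g2 = suit_names, g3 = suit_names,
                         stringsAsFactors = FALSE)
    wts <- apply(paths, 1, function(g)
      p1[[g[1]]] * trans[[1]][g[1], g[2]] * trans[[2]][g[2], g[3]])
    bel <- function(t) {
      vapply(suit_names,
             function(s) sum(wts[paths[[paste0("g", t)]] == s]),
             numeric(1))
    }
    acts <- ds$rounds$chosen_suit
    oracle <- -log(sum(bel(1) * aps[[1]][, acts[1]])) -
      log(sum(bel(2) * aps[[2]][, acts[2]])) -
      log(bel(3)[["cat"]]) -                       # probe term, round 3
      log(aps[[3]]["cat", acts[3]])                # belief collapsed

    impl <- dataset_nll(ds, model_id, params)
    expect_equal(as.numeric(impl), oracle, tolerance = 1e-10)
    expect_equal(attr(impl, "n_terms"), 4L)  # 3 actions + 1 probe
  }
})

test_that("the compiled forward pass matches an R-side replication", {
  cfg <- make_experiment_config("exp2", seed = 19)
  gen <- model_params("momentum", alpha = 0.4, gamma = 0.92, cost = 0.4,
                      beta_g = 4, beta_a = 4, alpha_ck = 0.25)
  ds <- simulate_participant(cfg, gen, seed = 23)
  for (model_id in c("momentum", "prospective", "td_persistence",
                     "hybrid", "rw_ck")) {
    params <- model_params(model_id, alpha = 0.3, gamma = 0.9, cost = 0.2,
                           beta_g = 3, beta_a = 5, alpha_ck = 0.15,
                           w = 0.6, beta = 4, beta_ck = 1.5)
    expect_equal(as.numeric(dataset_nll(ds, model_id, params)),
                 r_forward_nll(ds, model_id, params), tolerance = 1e-8,
                 label = model_id)
  }
})

test_that("rw_ck is scored on actions only", {
  cfg <- toy_config(n_rounds = 30L)
  ds <- simulate_participant(cfg, model_params("rw_ck"), seed = 1)
  nll <- dataset_nll(ds, "rw_ck", model_params("rw_ck"))
  expect_equal(attr(nll, "n_terms"), 30L)
  terms <- dataset_nll(ds, "rw_ck", model_params("rw_ck"), by_term = TRUE)
  expect_true(all(terms$nll_goal == 0))

  nll2 <- dataset_nll(ds, "momentum", model_params("momentum"))
  expect_equal(attr(nll2, "n_terms"), 40L)  # 30 actions + 10 probes
})

test_that("the generating parameters dominate perturbed ones in likelihood", {
  true_p <- model_params("momentum", alpha = 0.4, gamma = 0.95, cost = 0.3,
                         beta_g = 5, beta_a = 5, alpha_ck = 0.1)
  pert_p <- model_params("momentum", alpha = 0.9, gamma = 0.65, cost = -0.8,
                         beta_g = 0.5, beta_a = 9, alpha_ck = 0.9)
  diffs <- vapply(1:20, function(i) {
    cfg <- make_experiment_config("exp1", seed = 400 + i)
    ds <- simulate_participant(cfg, true_p, seed = 500 + i)
    as.numeric(dataset_nll(ds, "momentum", pert_p)) -
      as.numeric(dataset_nll(ds, "momentum", true_p))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("information criteria follow their definitions", {
  expect_equal(compute_aic(0, 6), 12)            # L = 1
  expect_equal(compute_bic(0, 2, 100), 2 * log(100))
  ft <- list(nll = 123.4, k = 6, n = 720)
  expect_equal(compute_aic(ft$nll, ft$k), 2 * 6 + 2 * 123.4)
  expect_equal(compute_bic(ft$nll, ft$k, ft$n), 6 * log(720) + 2 * 123.4)
})

test_that("maximum-likelihood fitting is reproducible and effective", {
  cfg <- make_experiment_config("exp2", seed = 29)
  true_p <- model_params("momentum", alpha = 0.45, gamma = 0.93, cost = 0.5,
                         beta_g = 5, beta_a = 6, alpha_ck = 0.15)
  ds <- simulate_participant(cfg, true_p, seed = 31)
  f1 <- fit_model(ds, "momentum", n_starts = 60, seed = 3)
  f2 <- fit_model(ds, "momentum", n_starts = 60, seed = 3)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$params, f2$params)
  # the optimum is at least as good as the generating parameters
  expect_lte(f1$nll, as.numeric(dataset_nll(ds, "momentum", true_p)) + 1e-6)
  expect_equal(f1$aic, 2 * 6 + 2 * f1$nll)
  expect_equal(f1$bic, 6 * log(f1$n) + 2 * f1$nll)
})

test_that("block-wise cross-validation scores held-out thirds", {
  cfg <- make_experiment_config("exp2", seed = 37)
  ds <- simulate_participant(cfg, model_params("momentum"), seed = 41)
  cv <- cross_validate(ds, "momentum", n_repeats = 2, seed = 5,
                       n_starts = 20)
  expect_gte(as.numeric(cv), 0)
  cv2 <- cross_validate(ds, "momentum", n_repeats = 2, seed = 5,
                        n_starts = 20)
  expect_equal(as.numeric(cv), as.numeric(cv2))
  expect_length(attr(cv, "per_repeat"), 2)

  one_block <- ds
  one_block$rounds <- ds$rounds[ds$rounds$block_index <= 2, ]
  expect_error(cross_validate(one_block, "momentum"), "fewer blocks")
})

test_that("cross-validation favors the generating model family", {
  # compare against td_persistence, which scores the same terms (actions +
  # probes); rw_ck omits goal terms so its held-out NLL is not commensurate
  deltas <- vapply(1:3, function(i) {
    cfg <- make_experiment_config("exp2", seed = 600 + i)
    ds <- simulate_participant(cfg, model_params("momentum", alpha = 0.5,
                                                 cost = 0.5, beta_g = 5,
                                                 beta_a = 5,
                                                 alpha_ck = 0.1),
                               seed = 700 + i)
    cv_true <- cross_validate(ds, "momentum", n_repeats = 1, seed = i,
                              n_starts = 25)
    cv_mis <- cross_validate(ds, "td_persistence", n_repeats = 1, seed = i,
                             n_starts = 25)
    as.numeric(cv_mis) - as.numeric(cv_true)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
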