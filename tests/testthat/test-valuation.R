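test_that("delta-rule belief updates behave as specified", {
  expect_equal(belief_update(0.5, 1, 1), 1.0)
  expect_equal(belief_update(0.5, 0, 0), 0.5)
  expect_equal(belief_update(0.2, 1, 0.25), 0.4)
  expect_error(belief_update(0.5, 1, 1.2), "alpha")
  # asymmetric rates pick the side of the prediction error
  expect_equal(belief_update(0.2, 1, 0.5, alpha_neg = 0.1), 0.6)
  expect_equal(belief_update(0.8, 0, 0.5, alpha_neg = 0.1), 0.72)
})

test_that("prospective rollout equals the outcome-enumeration oracle", {
  for (M in c(0.2, 0.5, 0.8)) {
    for (gamma in c(0.7, 0.9, 1.0)) {
      for (togo in 1:3) {
        for (h in 1:6) {
          expect_equal(
            prospective_value(M, s = 7 - togo, T = 7, gamma = gamma,
                              horizon = h),
            enumeration_rollout(M, gamma, togo, h),
            tolerance = 1e-10
          )
        }
      }
    }
  }
})

test_that("prospective rollout boundary cases and closed form hold", {
  expect_equal(prospective_value(1, s = 6, T = 7, gamma = 1, horizon = 1), 1)
  expect_equal(prospective_value(0.5, s = 3, T = 7, gamma = 0.9,
                                 horizon = 0), 0)
  expect_error(prospective_value(0.5, s = 8, T = 7, gamma = 0.9), "target")

  # infinite-horizon geometric closed form vs horizon-500 DP
  for (M in c(0.3, 0.8)) {
    for (gamma in c(0.9, 0.95)) {
      for (togo in 1:4) {
        closed <- (M * gamma / (1 - (1 - M) * gamma))^togo
        expect_equal(
          prospective_value(M, s = 7 - togo, T = 7, gamma = gamma,
                            horizon = 500),
          closed, tolerance = 1e-9
        )
      }
    }
  }
  expect_equal(prospective_value(0.8, 6, 7, 0.95, horizon = 500),
               0.8 * 0.95 / (1 - 0.2 * 0.95), tolerance = 1e-6)
})

test_that("prospective value is monotone in belief, progress and discount", {
  qs <- sapply(seq(0.1, 0.9, by = 0.1), function(M)
    prospective_value(M, 2, 7, 0.9))
  expect_true(all(diff(qs) > 0))
  qs <- sapply(0:6, function(s) prospective_value(0.5, s, 7, 0.9))
  expect_true(all(diff(qs) > 0))
  qg <- sapply(seq(0.6, 1, by = 0.05), function(g)
    prospective_value(0.5, 2, 7, g))
  expect_true(all(diff(qg) > 0))
})

test_that("retrospective value is proximity discounting", {
  expect_equal(retrospective_value(7, 7, 0.9), 1)
  expect_equal(retrospective_value(3, 7, 1), 1)
  expect_equal(retrospective_value(4, 7, 0.9), 0.729)
})

test_that("momentum value and TD update follow the linear-in-progress form", {
  expect_equal(momentum_value(0.5, 0, 0.1), 0.1)
  expect_equal(momentum_value(0, 0.7, 0), 0)
  expect_equal(momentum_value(1, 0.5, 0.25), 0.75)

  # worked TD-error signs: gamma 0.8, unit progress 0.2 -> 0.25 vs 0.9 -> 0.95
  # (the first case sits exactly on the boundary gamma = m / (m + eta),
  # where the TD error is zero: progress does not depreciate the value)
  up <- momentum_update(v = 1, b = 0, m_before = 0.2, m_after = 0.25,
                        gamma = 0.8, alpha = 0.1)
  expect_gte(up$delta, 0)
  up2 <- momentum_update(v = 1, b = 0, m_before = 0.2, m_after = 0.25,
                         gamma = 0.85, alpha = 0.1)
  expect_gt(up2$delta, 0)
  dn <- momentum_update(v = 1, b = 0, m_before = 0.9, m_after = 0.95,
                        gamma = 0.8, alpha = 0.1)
  expect_lt(dn$delta, 0)
  # no progress with positive value and gamma < 1 always depreciates
  st <- momentum_update(v = 0.5, b = 0.1, m_before = 0.4, m_after = 0.4,
                        gamma = 0.8, alpha = 0.1)
  expect_lt(st$delta, 0)
})

test_that("the sign condition matches the TD error on a (m, gamma) grid", {
  eta <- 0.05
  for (m in seq(0, 0.95, length.out = 50)) {
    for (gamma in seq(0.02, 1, length.out = 50)) {
      cond <- momentum_sign_condition(m, eta, gamma)
      d <- momentum_update(v = 0.7, b = 0, m_before = m, m_after = m + eta,
                           gamma = gamma, alpha = 0.1)$delta
      expect_equal(cond, d >= 0)
    }
  }
  expect_true(momentum_sign_condition(0.2, 0.05, 0.8))
  expect_false(momentum_sign_condition(0.9, 0.05, 0.8))
  expect_true(momentum_sign_condition(0, 0.05, 1e-6))
})

test_that("simple value identities hold for the remaining agents", {
  expect_equal(td_persistence_value(0.8), 0.8)
  expect_equal(hybrid_value(0.4, 0.8, 0.5), 0.6)
  expect_equal(hybrid_value(0.4, 0.8, 1), 0.4)
  expect_equal(hybrid_value(0.4, 0.8, 0), 0.8)
  expect_error(hybrid_value(0.4, 0.8, 1.5), "w")

  expect_equal(hyperbolic_prospective_value(0.3, 2, 7, k = 0), 1)
  expect_equal(hyperbolic_prospective_value(1, 6, 7, k = 1), 0.5)
  expect_lt(hyperbolic_prospective_value(1e-9, 0, 7, k = 1), 0.001)

  up <- rw_ck_update(Q = c(cat = 0, hat = 0, car = 0),
                     kernels = c(cat = 1, hat = 0, car = 0),
                     chosen = "cat", token = 1, eta = 0.5, alpha_ck = 0.3)
  expect_equal(unname(up$Q["cat"]), 0.5)
  expect_equal(unname(up$kernels["cat"]), 1)  # fixed point
  expect_equal(unname(up$kernels["hat"]), 0)

  p <- rw_ck_probs(Q = c(1, 1, 1), kernels = c(0, 0, 0), beta = 3,
                   beta_ck = 2)
  expect_equal(unname(p), rep(1 / 3, 3))
})

test_that("belief converges to the token probability under a delta rule", {
  set.seed(4)
  M <- 1 / 3
  p <- 0.7
  for (i in 1:4000) M <- belief_update(M, rbinom(1, 1, p), 0.02)
  expect_lt(abs(M - p), 0.1)
})

test_that("the learned speed of progress tracks the reinforcement rate", {
  # v when the suit first completes (one full climb of m from 0 to 1):
  # faster reinforcement means fewer depreciating failures per unit progress
  climb_v <- function(p, eta = 1 / 7, gamma = 0.9, alpha = 0.4) {
    v <- 0.5; b <- 0.1; m <- 0
    repeat {
      tok <- rbinom(1, 1, p)
      m2 <- m + tok * eta
      up <- momentum_update(v, b, m, min(m2, 1), gamma, alpha)
      v <- up$v; b <- up$b
      if (m2 >= 1 - 1e-9) return(v)
      m <- m2
    }
  }
  set.seed(21)
  v_slow <- mean(replicate(300, climb_v(0.2)))
  v_mid <- mean(replicate(300, climb_v(0.6)))
  v_fast <- mean(replicate(300, climb_v(0.8)))
  expect_gt(v_mid, v_slow)
  expect_gt(v_fast, v_mid)
})

test_that("momentum value decays gradually after a drop in progress rate", {
  # shared token stream: p = 0.6 for 15 rounds then 0.2
  set.seed(8)
  n <- 60
  tokens <- c(rbinom(15, 1, 0.6), rbinom(n - 15, 1, 0.2))
  eta <- 0.05; gamma <- 0.9; alpha <- 0.4; T <- 20L

  v <- 0.5; b <- 0.1; m <- 0; M <- 1 / 3
  q_mom <- q_pros <- numeric(n)
  s <- 0L
  for (t in seq_len(n)) {
    q_mom[t] <- momentum_value(v, m, b)
    q_pros[t] <- prospective_value(M, s, T, gamma)
    tok <- tokens[t]
    up <- momentum_update(v, b, m, m + tok * eta, gamma, alpha)
    v <- up$v; b <- up$b
    M <- belief_update(M, tok, alpha)
    s <- min(s + tok, T - 1L)
    m <- s / T
  }
  # momentum is the stabler estimate: its per-round changes are far less
  # dispersed than the prospective trace, which jumps with every outcome
  expect_lt(sd(diff(q_mom)), 0.5 * sd(diff(q_pros)))
  expect_lt(sd(diff(q_mom[16:n])), 0.5 * sd(diff(q_pros[16:n])))
  # and after the drop the momentum value does decay
  expect_lt(mean(q_mom[50:n]), max(q_mom[1:20]))
})
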