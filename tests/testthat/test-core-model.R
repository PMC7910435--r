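test_that("mean latency follows the exponent identity across variants", {
  p <- agent_params(0.1, log(48), 1)
  expect_equal(mean_latency(model_state(policy = log(48), rbar = 0), p), 48)
  expect_equal(mean_latency(model_state(policy = 3, rbar = 2), p), exp(2.8))
  # null model ignores the state entirely
  pn <- agent_params(P = log(24), variant = "null_no_learning")
  for (st in list(model_state(5, rbar = -3), model_state(-2, rbar = 10)))
    expect_equal(mean_latency(st, pn), 24)
  # pavlovian variant keeps the policy frozen at P
  pp <- agent_params(0.1, log(24), 1, variant = "pavlovian_only")
  expect_equal(mean_latency(model_state(policy = 99, rbar = 2), pp),
               exp(log(24) - 0.2))
})

test_that("extreme exponents are clamped with a warning, never Inf or 0", {
  p <- agent_params(1, 0, 1)
  expect_warning(m <- mean_latency(model_state(policy = 0, rbar = -200), p),
                 "clamped")
  expect_true(is.finite(m) && m > 0)
  expect_warning(m2 <- mean_latency(model_state(policy = 0, rbar = 200), p),
                 "clamped")
  expect_true(m2 > 0)
})

test_that("prediction error matches its closed form per variant", {
  st <- model_state(0, rbar = 1)
  expect_equal(prediction_error(5, 2, st, agent_params(0.1, 0, 2)), 2)
  expect_equal(prediction_error(3, 0.5, model_state(0, rbar = 2),
                                agent_params(0.1, 0, 4)), -6)
  expect_equal(prediction_error(0, 1, model_state(0, rbar = 0),
                                agent_params(0.1, 0, 1,
                                             variant = "no_effort_cost")), 0)
  # cost variants
  expect_equal(prediction_error(5, 2, st,
                                agent_params(0.1, 0, 2,
                                             variant = "fixed_effort_cost")),
               5 - 2 - 2)
  expect_equal(prediction_error(5, 2, st,
                                agent_params(0.1, 0, 2,
                                             variant = "increasing_effort_cost")),
               5 - 4 - 2)
  expect_error(prediction_error(5, 0, st, agent_params(0.1, 0, 2)),
               "positive")
})

test_that("state updates follow the policy-gradient rules", {
  p <- agent_params(0.1, 0, 1)
  st <- model_state(policy = 3, rbar = 0)
  up <- update_state(st, tau_t = 4, tau_prev = 5, delta = 2, p)
  expect_equal(up$policy, 2.8)
  expect_equal(up$t, 2L)
  # delta = 0 is a fixed point
  up0 <- update_state(st, 4, 5, 0, p)
  expect_equal(up0$policy, st$policy)
  expect_equal(up0$rbar, st$rbar)
  # rbar integrates alpha * delta
  up2 <- update_state(model_state(0, rbar = 1), 1, 1, -2,
                      agent_params(0.5, 0, 1))
  expect_equal(up2$rbar, 0)
  # first interval: no latency difference, policy untouched
  up3 <- update_state(st, 4, NA, 2, p)
  expect_equal(up3$policy, st$policy)
  expect_equal(up3$rbar, st$rbar + 0.1 * 2)
})

test_that("net-reward decomposition holds at every step of a trace", {
  tr <- simulate_agent(agent_params(0.002, log(2), 0.5), 5, 200, seed = 11)
  # delta + C/tau + rbar*tau must reconstruct the reward exactly
  recon <- tr$delta + 0.5 / tr$tau + tr$rbar * tr$tau
  expect_equal(recon, tr$reward, tolerance = 1e-12)
})

test_that("optimal latency equals sqrt(C/rbar) and matches grid search", {
  expect_equal(optimal_latency(4, 1), 2)
  expect_equal(optimal_latency(1, 1), 1)
  expect_equal(optimal_latency(1, 4), 0.5)
  expect_error(optimal_latency(-1, 1), "positive")
  expect_error(optimal_latency(1, 0), "optimum")
  set.seed(42)
  for (i in 1:100) {
    C <- exp(runif(1, log(0.05), log(20)))
    rb <- exp(runif(1, log(0.05), log(20)))
    tau_star <- optimal_latency(C, rb)
    grid <- exp(seq(log(tau_star / 20), log(tau_star * 20), length.out = 4001))
    net <- 5 - C / grid - rb * grid  # fixed reward: argmax independent of R
    expect_lt(abs(grid[which.max(net)] - tau_star) / tau_star, 0.01)
  }
  # monotone decreasing in rbar
  expect_true(all(diff(optimal_latency(2, c(0.5, 1, 2, 4, 8))) < 0))
})

test_that("trace and likelihood agree with direct R arithmetic", {
  tl <- tiny_timeline(c(5, 2, 8, 3), likes = c(1, 4, 0, 6, 2))
  p <- agent_params(0.05, log(4), 0.5)
  tr <- rrl_trace(p, tl)
  # independent R-side replay of the recursion
  pol <- p$P; rb <- 0; nll <- 0
  for (j in seq_along(tr$tau)) {
    expect_equal(tr$policy[j], pol)
    expect_equal(tr$rbar[j], rb)
    mu <- exp(pol - p$alpha * rb)
    expect_equal(tr$mu[j], mu)
    nll <- nll + log(mu) + tr$tau[j] / mu
    d <- tr$reward[j] - p$C / tr$tau[j] - rb * tr$tau[j]
    expect_equal(tr$delta[j], d)
    if (j >= 2) pol <- pol + p$alpha * (tr$tau[j] - tr$tau[j - 1]) * d
    rb <- rb + p$alpha * d
  }
  expect_equal(negative_log_likelihood(p, tl), nll)
})

test_that("simulation is reproducible and respects limiting cases", {
  p <- agent_params(0.002, log(24), 0.5)
  tr1 <- simulate_agent(p, 5, 300, seed = 5)
  tr2 <- simulate_agent(p, 5, 300, seed = 5)
  expect_identical(tr1$tau, tr2$tau)
  expect_identical(tr1$reward, tr2$reward)
  # null agent: sample mean near exp(P)
  trn <- simulate_agent(agent_params(P = log(24),
                                     variant = "null_no_learning"),
                        5, 4000, seed = 6)
  expect_lt(abs(mean(trn$tau) - 24) / 24, 3 / sqrt(4000) * 1.2 + 0.02)
  # alpha -> 0 reproduces the null agent's draws under the same seed
  tr0 <- simulate_agent(agent_params(1e-12, log(24), 0.5), 5, 300, seed = 7)
  trn2 <- simulate_agent(agent_params(P = log(24),
                                      variant = "null_no_learning"),
                         5, 300, seed = 7)
  expect_equal(tr0$tau, trn2$tau, tolerance = 1e-9)
})

test_that("a richer like process shortens latencies for learning agents", {
  p <- agent_params(0.005, log(2), 0.3)
  lo <- sapply(1:20, function(s) mean(simulate_agent(p, 1, 250,
                                                     seed = s)$tau))
  hi <- sapply(1:20, function(s) mean(simulate_agent(p, 10, 250,
                                                     seed = 1000 + s)$tau))
  expect_lt(mean(hi), mean(lo))
})

test_that("custom reward processes run through the R-level simulator", {
  rp <- function(t, tau) if (t %% 2 == 0) 3 else 0
  tr <- simulate_agent(agent_params(0.002, log(4), 0.5), rp, 50, seed = 8)
  expect_identical(tr$reward, rep(c(0, 3), 25))
})
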