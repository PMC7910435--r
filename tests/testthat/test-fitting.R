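test_that("null-model likelihood and MLE have their closed forms", {
  tl <- tiny_timeline(c(10, 20, 30))
  pn <- agent_params(P = log(20), variant = "null_no_learning")
  expect_equal(negative_log_likelihood(pn, tl), 3 * log(20) + 3)
  fit <- rrl_fit(tl, "null_no_learning")
  expect_equal(unname(coef(fit)["P"]), log(20))
  expect_equal(fit$aic, 2 + 2 * (3 * log(20) + 3))
  expect_equal(AIC(fit), fit$aic)
  # MLE identity on arbitrary data
  set.seed(1)
  tl2 <- tiny_timeline(rexp(60, 1 / 15))
  f2 <- rrl_fit(tl2, "null_no_learning")
  expect_equal(exp(unname(coef(f2)["P"])), mean(tl2$latencies))
})

test_that("the full model nests the null at vanishing learning rate", {
  tl <- tiny_timeline(c(10, 20, 30), likes = c(2, 5, 1, 3))
  nll_null <- negative_log_likelihood(
    agent_params(P = log(20), variant = "null_no_learning"), tl)
  nll_full <- negative_log_likelihood(agent_params(1e-300, log(20), 1), tl)
  expect_equal(nll_full, nll_null)  # machine precision
  # fitted full model can never do worse than the fitted null
  set.seed(2)
  tl3 <- tiny_timeline(rexp(80, 1 / 10), likes = c(0, rpois(80, 5)))
  f_null <- rrl_fit(tl3, "null_no_learning")
  f_full <- quiet(rrl_fit(tl3, "rbar_full", seed = 3, n_starts = 10))
  expect_lte(f_full$nll, f_null$nll + 1e-6)
})

test_that("simulated learners are recovered by the optimizer", {
  truth <- agent_params(0.003, log(2), 0.4)
  tl <- trace_to_timeline(simulate_agent(truth, 5, 500, seed = 4))
  fit <- quiet(rrl_fit(tl, "rbar_full", seed = 5))
  expect_equal(fit$convergence, 0L)
  # fitted likelihood at least as good as the generating parameters
  expect_lte(fit$nll, negative_log_likelihood(truth, tl))
  expect_lt(abs(coef(fit)["P"] - truth$P), 0.5)
  expect_lt(abs(log(coef(fit)["alpha"] / truth$alpha)), log(5))
})

test_that("fit methods expose the classic modelling interface", {
  tl <- trace_to_timeline(simulate_agent(agent_params(0.002, log(4), 0.5),
                                         5, 120, seed = 6))
  fit <- quiet(rrl_fit(tl, "rbar_full", seed = 7, n_starts = 5))
  expect_s3_class(fit, "rrl_fit")
  expect_length(coef(fit), 3)
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$nll)
  expect_equal(attr(ll, "df"), 3L)
  mu <- predict(fit)
  expect_length(mu, length(tl$latencies))
  expect_true(all(mu > 0))
  r <- residuals(fit)
  expect_length(r, length(mu))
  expect_lt(abs(mean(r)), 0.5)  # quantile residuals roughly centered
  sims <- simulate(fit, nsim = 3, seed = 8)
  expect_equal(dim(sims), c(length(mu), 3L))
  expect_output(print(summary(fit)), "mean observed latency")
})

test_that("Akaike weights are the normalized relative likelihoods", {
  expect_equal(aic_weights(c(100, 100)), c(0.5, 0.5))
  w <- aic_weights(c(100, 102))
  expect_equal(unname(w), c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(w), 1)
  # invariance to adding a constant
  expect_equal(aic_weights(c(100, 102)), aic_weights(c(1100, 1102)))
  # limit: infinite gap
  expect_equal(unname(aic_weights(c(10, 2000))), c(1, 0))
  expect_error(aic_weights(100), "2 models")
  expect_error(aic_weights(c(1, NA)), "finite")
})

test_that("model comparison prefers the generating model and breaks ties simply", {
  tl <- trace_to_timeline(simulate_agent(
    agent_params(P = log(10), variant = "null_no_learning"), 5, 150,
    seed = 9))
  cmp <- quiet(compare_models(tl, seed = 10, n_starts = 8))
  expect_equal(sum(cmp$table$aic_weight), 1)
  expect_equal(cmp$best, "null_no_learning")  # AIC penalty favors null
  tl2 <- trace_to_timeline(simulate_agent(agent_params(0.008, log(2), 0.2),
                                          5, 400, seed = 11))
  cmp2 <- quiet(compare_models(tl2, seed = 12))
  expect_equal(cmp2$best, "rbar_full")
})

test_that("group Bayesian model selection behaves at its limits", {
  # unanimous evidence drives the exceedance probability to 1
  ev <- cbind(A = rep(-1, 50), B = rep(-8, 50))
  b <- group_bms(ev, seed = 1)
  expect_gt(b$xp[["A"]], 0.99)
  expect_equal(sum(b$xp), 1)
  expect_true(all(b$xp >= 0 & b$xp <= 1))
  # perfectly balanced evidence: symmetric posterior
  b2 <- group_bms(cbind(A = rep(0, 40), B = rep(0, 40)), seed = 2)
  expect_equal(unname(b2$xp), c(0.5, 0.5), tolerance = 0.02)
  # a single user cannot push xp to the boundary
  b3 <- group_bms(cbind(A = -1, B = -6), seed = 3)
  expect_true(b3$xp[["A"]] > 0.5 && b3$xp[["A"]] < 0.95)
  expect_error(group_bms(matrix(1, 5, 1)), "2 models")
})

test_that("cohort fitting returns a tidy comparison table", {
  coh <- generate_cohort(cohort_spec(6, 80, seed = 13))
  fs <- quiet(fit_cohort(coh$timelines, seed = 14, n_starts = 5))
  expect_equal(nrow(fs$table), 12)
  expect_true(all(c("alpha", "P", "C", "aic_weight", "best") %in%
                    names(fs$table)))
  per_user <- tapply(fs$table$aic_weight, fs$table$user_id, sum)
  expect_equal(as.numeric(per_user), rep(1, 6), tolerance = 1e-12)
  gc <- group_comparison(fs, seed = 15)
  expect_equal(sum(gc$best_proportions), 1)
  expect_equal(sum(gc$bms$xp), 1)
})

test_that("recovery suite reports confusion and correlations", {
  cf <- generate_cohort(cohort_spec(12, 250,
                                    param_ranges = strong_learning_ranges(),
                                    seed = 16))
  cn <- generate_cohort(cohort_spec(12, 250, variant = "null_no_learning",
                                    seed = 17))
  rep <- quiet(recovery_suite(list(cf, cn), seed = 18, n_starts = 8))
  expect_equal(sum(rep$confusion), 24)
  expect_gt(rep$accuracy, 0.6)
  expect_true(all(c("alpha", "P", "C") %in% rep$param_recovery$parameter))
})
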