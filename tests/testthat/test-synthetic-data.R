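test_that("a cohort is byte-identical when regenerated from its spec", {
  spec <- cohort_spec(8, 60, seed = 21)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$timelines, `[[`, "timestamps"),
                   lapply(c2$timelines, `[[`, "timestamps"))
  # spec serialization round-trip preserves the cohort
  path <- tempfile(fileext = ".json")
  write_cohort_spec(spec, path)
  c3 <- generate_cohort(read_cohort_spec(path))
  expect_identical(c1$truth, c3$truth)
})

test_that("like counts honor the generating process", {
  coh <- generate_cohort(cohort_spec(30, 120, poisson_lambda = 5, seed = 22))
  likes <- unlist(lapply(coh$timelines, `[[`, "likes"))
  likes <- likes[-seq(1, length(likes), by = 120)]  # drop seeded first posts
  expect_true(all(likes >= 0 & likes == round(likes)))
  n <- length(likes)
  expect_lt(abs(mean(likes) - 5), 3 * sqrt(5 / n))
  # ground truth respects the parameter bounds
  tr <- coh$truth
  rg <- default_param_ranges()
  expect_true(all(tr$alpha >= rg$alpha[1] & tr$alpha <= rg$alpha[2]))
  expect_true(all(tr$P >= rg$P[1] & tr$P <= rg$P[2]))
  expect_true(all(tr$C >= rg$C[1] & tr$C <= rg$C[2]))
})

test_that("null-agent latencies are serially uncorrelated", {
  coh <- generate_cohort(cohort_spec(20, 300, variant = "null_no_learning",
                                     seed = 23))
  ac1 <- vapply(coh$timelines, function(tl) {
    x <- tl$latencies
    cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_lt(abs(mean(ac1)), 2 / sqrt(299 * 20))
  expect_lt(max(abs(ac1)), 4 / sqrt(299))
})

test_that("with no likes and positive effort cost the net reward is negative while rbar is non-negative", {
  coh <- generate_cohort(cohort_spec(5, 80, poisson_lambda = 0, seed = 24))
  for (tl in coh$timelines) {
    i <- match(tl$user_id, coh$truth$user_id)
    tr <- rrl_trace(agent_params(coh$truth$alpha[i], coh$truth$P[i],
                                 coh$truth$C[i]), tl)
    # delta = -C/tau - rbar*tau < 0 whenever rbar >= 0; once rbar has gone
    # negative the opportunity-cost term changes sign, so the first delta
    # is always negative but later ones need not be
    expect_true(all(tr$delta[tr$rbar >= 0] < 0))
    expect_lt(tr$delta[1], 0)
    expect_lt(mean(tr$reward), 1e-12)
  }
})

test_that("experiment sessions implement the two-block design", {
  ex <- generate_experiment(experiment_spec(31, agent = "scripted",
                                            seed = 25))
  # counterbalancing: exactly ceiling(n/2) low-first participants
  ord <- unique(ex[, c("participant", "order")])
  expect_equal(sum(ord$order == "low_first"), 16)
  # like supports exactly as designed
  expect_true(all(ex$likes[ex$block == "low"] %in% 0:9))
  expect_true(all(ex$likes[ex$block == "high"] %in% 10:19))
  # block means approach 4.5 and 14.5
  expect_lt(abs(mean(ex$likes[ex$block == "low"]) - 4.5),
            3 * sqrt(8.25 / sum(ex$block == "low")) + 0.2)
  expect_lt(abs(mean(ex$likes[ex$block == "high"]) - 14.5),
            3 * sqrt(8.25 / sum(ex$block == "high")) + 0.2)
  # all events inside the session, blocks split at the half
  expect_true(all(ex$time > 0 & ex$time <= 25))
  low_first <- ex$order == "low_first"
  expect_true(all(ex$block[low_first & ex$time <= 12.5] == "low"))
  expect_true(all(ex$block[!low_first & ex$time <= 12.5] == "high"))
})

test_that("learning participants post more slowly in the low block", {
  ex <- generate_experiment(experiment_spec(150, agent = "rrl", seed = 26))
  ea <- quiet(run_experiment_analysis(ex))
  expect_gt(ea$block$beta, 0)
})

test_that("reinforcement schedules deliver rewards per their rule", {
  p <- agent_params(0.005, log(1), 0.2)
  # ratio-1: every response rewarded
  tr1 <- generate_schedule_session(schedule_spec("ratio", 1, magnitude = 2),
                                   p, n = 50, seed = 27)
  expect_true(all(tr1$reward == 2))
  # ratio-3: exactly every third response
  tr3 <- generate_schedule_session(schedule_spec("ratio", 3), p, n = 60,
                                   seed = 28)
  expect_equal(which(tr3$reward > 0), seq(3, 60, by = 3))
  # zero magnitude on a schedule equals a rewardless environment bit-for-bit
  trz <- generate_schedule_session(schedule_spec("ratio", 1, magnitude = 0),
                                   p, n = 100, seed = 29)
  tr0 <- simulate_agent(p, function(t, tau) 0, 100, seed = 29)
  expect_identical(trz$tau, tr0$tau)
  # richer interval schedules sustain higher response rates
  rate_at <- function(m, s) {
    tr <- generate_schedule_session(schedule_spec("interval", m,
                                                  magnitude = 5),
                                    agent_params(0.008, log(1), 0.2),
                                    n = 800, seed = s)
    400 / sum(tr$tau[401:800])
  }
  fast <- sapply(1:6, function(s) rate_at(0.2, s))
  slow <- sapply(1:6, function(s) rate_at(4, 100 + s))
  expect_gt(mean(fast), mean(slow))
})

test_that("timeline CSV and JSON Lines round-trips preserve the data", {
  coh <- generate_cohort(cohort_spec(4, 30, seed = 30))
  path <- tempfile(fileext = ".csv")
  write_timelines(coh$timelines, path)
  back <- read_timelines(path)
  expect_equal(names(back), names(coh$timelines))
  expect_equal(back$u0001$latencies, coh$timelines$u0001$latencies)
  expect_equal(back$u0003$likes, coh$timelines$u0003$likes)
  # ISO 8601 timestamps parse to hours
  iso <- data.frame(user_id = "a",
                    timestamp = c("2024-01-01T00:00:00",
                                  "2024-01-01T06:00:00",
                                  "2024-01-02T00:00:00"),
                    likes = c(1, 2, 3))
  p2 <- tempfile(fileext = ".csv")
  write.csv(iso, p2, row.names = FALSE)
  tl <- read_timelines(p2)[["a"]]
  expect_equal(tl$latencies, c(6, 18))
})

test_that("timeline invariants are enforced on construction", {
  expect_error(post_timeline("u", c(0, 1, 1), c(0, 0, 0)), "increasing")
  expect_error(post_timeline("u", c(0, 1), c(0, -1)), "non-negative")
  expect_error(post_timeline("u", c(0, 1), c(0, 1.5)), "integers")
  expect_error(agent_params(0, log(2), 1), "alpha")
  expect_error(agent_params(0.1, -1, 1), "non-negative")
  expect_error(agent_params(0.1, log(2), 0), "positive")
})
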