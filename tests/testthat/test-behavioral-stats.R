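test_that("dichotomization splits standardized ranks at zero", {
  # odd-length monotone series: the median rank standardizes to exactly 0
  # and is assigned Low, leaving floor(n/2) High values
  expect_equal(dichotomize_rbar(1:5), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(sum(dichotomize_rbar(seq(2, 30, by = 2))), 7L)  # floor(15/2)
  # reversing the series flips every label
  x <- c(0.3, -1, 2, 5, -4, 1.2)
  expect_equal(dichotomize_rbar(rev(x)), rev(dichotomize_rbar(x)))
  # four distinct values: balanced split
  expect_equal(sum(dichotomize_rbar(c(10, -2, 3, 7))), 2L)
  expect_warning(out <- dichotomize_rbar(rep(1, 10)), "constant")
  expect_null(out)
})

test_that("law of effect identifies exact generative forms", {
  r <- seq(0.5, 10, length.out = 12)
  hyp_pts <- data.frame(response_rate = 8 * r / (r + 3), reward_rate = r)
  res_h <- law_of_effect(hyp_pts)
  expect_equal(res_h$R2_hyperbolic, 1, tolerance = 1e-6)
  expect_gt(res_h$R2_hyperbolic, res_h$R2_linear)
  expect_equal(res_h$k, 8, tolerance = 1e-4)
  expect_equal(res_h$r0, 3, tolerance = 1e-4)
  lin_pts <- data.frame(response_rate = 0.2 + 0.5 * r, reward_rate = r)
  res_l <- law_of_effect(lin_pts)
  expect_equal(res_l$R2_linear, 1, tolerance = 1e-8)
  # R^2 bounded and scale invariant: changing the time unit rescales both
  # rates and leaves the hyperbola's fit quality unchanged
  scaled <- hyp_pts * 24
  expect_equal(law_of_effect(scaled)$R2_hyperbolic, res_h$R2_hyperbolic,
               tolerance = 1e-6)
  # degenerate windows are skipped with a reason
  expect_warning(law_of_effect(data.frame(response_rate = rep(1, 6),
                                          reward_rate = 1:6)), "degenerate")
  expect_warning(law_of_effect(data.frame(response_rate = 1:3,
                                          reward_rate = 1:3)), "few")
})

test_that("rate windows aggregate posts per unit time", {
  tl <- tiny_timeline(rep(2, 20), likes = c(0, rep(3, 20)))
  w <- rate_windows(tl, window = 10)
  expect_equal(nrow(w), 2)
  expect_equal(w$response_rate, c(0.5, 0.5))
  expect_equal(w$reward_rate, c(1.5, 1.5))
})

test_that("a lagged copy of likes is detected as Granger-causal", {
  set.seed(31)
  tls <- lapply(1:15, function(i) {
    likes <- rpois(120, 5)
    tau <- 5 + c(2, head(likes, -1)) + rnorm(120, 0, 0.05)
    post_timeline(paste0("g", i), cumsum(c(0, tau)), c(0, likes))
  })
  pg <- panel_granger(tls, L = 1)
  expect_lt(pg$p, 1e-10)
  expect_gt(pg$Zbar_tilde, 0)
})

test_that("the panel statistic is calibrated on independent series", {
  cn <- generate_cohort(cohort_spec(300, 120, variant = "null_no_learning",
                                    seed = 32))
  set.seed(33)
  rej <- replicate(150, {
    idx <- sample.int(300, 20, replace = TRUE)
    panel_granger(cn$timelines[idx], 1)$p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("length rule drops short users and errors when none remain", {
  set.seed(72)
  short <- tiny_timeline(rexp(6, 1), likes = c(0, rpois(6, 2)))
  long <- tiny_timeline(rexp(60, 1), likes = c(0, rpois(60, 2)))
  pg <- panel_granger(list(short, long), L = 1)
  expect_equal(pg$n_dropped, 1)
  expect_error(panel_granger(list(short), L = 1), "length rule")
})

test_that("lag calibration reports the full table and flags failure", {
  cl <- generate_cohort(cohort_spec(40, 80, seed = 34))
  cn <- generate_cohort(cohort_spec(40, 80, variant = "null_no_learning",
                                    seed = 35))
  cal <- quiet(calibrate_granger_lags(cn, cn, candidate_lags = 1:2,
                                      n_power_panels = 10,
                                      power_panel_size = 20,
                                      n_null_panels = 30, seed = 36))
  expect_equal(nrow(cal$table), 2)
  # exchangeable inputs: power cannot systematically exceed the FPR band
  expect_true(all(cal$table$power <= 0.3))
  cal2 <- quiet(calibrate_granger_lags(cl, cn, candidate_lags = 1:2,
                                       n_power_panels = 5,
                                       n_null_panels = 20, seed = 37))
  expect_true(is.na(cal2$chosen_L) || cal2$chosen_L %in% 1:2)
})

test_that("the latency mixed model recovers a known generative effect", {
  set.seed(38)
  n_u <- 50; n_t <- 80
  dat <- do.call(rbind, lapply(1:n_u, function(u) {
    high <- rbinom(n_t, 1, 0.5)
    data.frame(user_id = paste0("u", u), t = 1:n_t,
               log_tau = rnorm(1, 0, 0.3) - 0.2 * high +
                 rnorm(n_t, 0, 0.3),
               low_rbar = 1L - high,
               rbar_z = (high - mean(high)) / sd(high),
               likes_prev = rnorm(n_t), post_num = scale(1:n_t)[, 1],
               weekday_prev = factor(sample(0:6, n_t, TRUE), levels = 0:6))
  }))
  mm <- mixed_model_latency(dat)
  # se of the fixed effect ~ 0.01; allow ~3 se
  expect_equal(mm$beta, 0.2, tolerance = 0.2)
  expect_lt(abs(mm$beta - 0.2), 0.035)
  expect_equal(mm$pct_change, exp(mm$beta) - 1)
  expect_gt(mm$aic_weight, 0.99)
  # continuous coding flips the sign
  mm2 <- mixed_model_latency(dat, predictor = "rbar_z")
  expect_lt(mm2$beta, 0)
  # interaction with centered AIC weights runs and reports the term
  w <- setNames(runif(n_u, 0.3, 0.9), paste0("u", 1:n_u))
  mm3 <- mixed_model_latency(dat, interaction_aicw = w)
  expect_true(any(grepl("aicw_c", mm3$coef$term)))
})

test_that("a zero-effect world rejects at the nominal rate", {
  set.seed(39)
  rejections <- replicate(40, {
    dat <- do.call(rbind, lapply(1:10, function(u) {
      high <- rbinom(40, 1, 0.5)
      data.frame(user_id = paste0("u", u),
                 log_tau = rnorm(1, 0, 0.2) + rnorm(40, 0, 0.5),
                 low_rbar = 1L - high)
    }))
    m <- quiet(mixed_model_latency(dat, covariates = character(0)))
    abs(m$coef$z[m$coef$term == "low_rbar"]) > 1.96
  })
  expect_lte(sum(rejections), 6)  # binomial(40, 0.05): P(>6) ~ 0.004
})

test_that("regression data builder lags predictors within user", {
  coh <- generate_cohort(cohort_spec(5, 50, seed = 40))
  dat <- quiet(latency_regression_data(coh))
  expect_true(all(c("log_tau", "low_rbar", "rbar_z", "likes_prev",
                    "post_num", "weekday_prev") %in% names(dat)))
  # within-user standardization: centered covariates
  agg <- aggregate(cbind(likes_prev, post_num) ~ user_id, dat, mean)
  expect_lt(max(abs(agg$likes_prev)), 1e-10)
  expect_lt(max(abs(agg$post_num)), 1e-10)
  # the low indicator at interval j reflects rewards up to post j-1: the
  # first usable row of each user is interval 2
  expect_true(all(tapply(dat$t, dat$user_id, min) == 3))
})

test_that("interval-schedule batteries reproduce the saturating law of effect", {
  res <- quiet(law_of_effect_schedule_study(8, n_responses = 900,
                                            burn_in = 500, seed = 41))
  expect_gt(res$mean_R2_hyperbolic, res$mean_R2_linear)
  expect_true(all(res$table$R2_hyperbolic <= 1))
})
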