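#' Cohort specification for synthetic timelines
#'
#' Describes a population of simulated posters: how many users, how many
#' posts each, how the agent parameters are drawn, and how likes are
#' generated. The default sampling law draws the learning rate and effort
#' cost log-uniformly and the initial policy uniformly on the log-latency
#' scale; likes are i.i.d. Poisson draws with the same rate for every user,
#' the deliberately minimal assumption about the like process.
#'
#' @param n_users Number of users (>= 1).
#' @param posts_per_user Posts per user: a single count, a vector recycled
#'   across users, or a function `f(n_users)` returning counts.
#' @param variant Generating model variant for every user (see
#'   [rrl_variants()]); most commonly `"rbar_full"` or `"null_no_learning"`.
#' @param param_ranges List with elements `alpha` (log-uniform range),
#'   `P` (uniform range, log-hours) and `C` (log-uniform range).
#' @param like_process `"poisson_constant"` (one rate for everybody),
#'   `"poisson_per_user"` (user rates drawn log-normally around
#'   `poisson_lambda`), or `"uniform_block"` (two-block uniform likes, see
#'   [experiment_spec()] for the experiment version).
#' @param poisson_lambda Mean likes per post (>= 0).
#' @param rbar0 Initial average reward rate for every agent.
#' @param seed Integer seed; the whole cohort is reproducible from the spec.
#' @return An object of class `cohort_spec` (serializable with
#'   [write_cohort_spec()]).
#' @export
cohort_spec <- function(n_users, posts_per_user = 250,
                        variant = "rbar_full",
                        param_ranges = default_param_ranges(),
                        like_process = c("poisson_constant",
                                         "poisson_per_user",
                                         "uniform_block"),
                        poisson_lambda = 5, rbar0 = 0, seed = 1) {
  like_process <- match.arg(like_process)
  stopifnot(n_users >= 1, poisson_lambda >= 0)
  variant <- match.arg(variant, rrl_variants())
  structure(list(n_users = as.integer(n_users),
                 posts_per_user = posts_per_user,
                 variant = variant,
                 param_ranges = param_ranges,
                 like_process = like_process,
                 poisson_lambda = as.numeric(poisson_lambda),
                 rbar0 = as.numeric(rbar0),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default agent-parameter sampling ranges
#'
#' The population the cohort generator draws from: learning rates
#' log-uniform on `[7e-4, 3e-3]`, initial policies uniform on
#' `[log(1), log(4)]` log-hours, and effort costs log-uniform on
#' `[0.1, 1]` reward-hours. The box is chosen so that (i) the
#' policy-gradient recursion is numerically stable — its update step is
#' `alpha * Delta-tau * delta`, whose spikes scale with `alpha * C` and the
#' latency scale, so large products diverge — and (ii) agents operate near
#' their steady state (`tau* = 2C/lambda`, here 0.04-0.4 h) with genuine
#' reward-rate fluctuation, which is what gives the dichotomized
#' low-vs-high reward-rate contrast on log latency its ~0.18 magnitude at
#' the default like rate. See the methods vignette for the calibration
#' rationale.
#'
#' @return A named list of ranges.
#' @export
default_param_ranges <- function() {
  list(alpha = c(7e-4, 3e-3),
       P = c(log(1), log(4)),
       C = c(0.1, 1))
}

#' Strong-learning sampling ranges
#'
#' A preset for recovery and power studies: learning rates in the upper,
#' still-stable region (`[3e-3, 1e-2]`, with effort costs capped at
#' `[0.1, 0.3]` to keep the `alpha * C` update product tame). These agents
#' show clearly detectable reward learning within a few hundred posts and
#' are the package's condition for model-recovery classification and
#' Granger power analyses, where the contrast of interest is
#' learning-vs-none rather than the broad default population.
#'
#' @return A named list of ranges.
#' @export
strong_learning_ranges <- function() {
  list(alpha = c(3e-3, 1e-2),
       P = c(log(1), log(4)),
       C = c(0.1, 0.3))
}

#' Identifiability-study sampling ranges
#'
#' The population used for parameter-recovery studies: each parameter spans
#' the full stable, plausible region (learning rates over a decade,
#' `[1e-3, 1e-2]`; effort costs over 1.3 decades, `[0.05, 1]`; initial
#' policies `[0, log 4]` log-hours), so that recovery correlations measure
#' identifiability across the range rather than within a narrow slice.
#'
#' @return A named list of ranges.
#' @export
recovery_study_ranges <- function() {
  list(alpha = c(1e-3, 1e-2),
       P = c(0, log(4)),
       C = c(0.05, 1))
}

#' Vigor-coupling sampling ranges for Granger power studies
#'
#' The regime in which the like history leaves a linearly detectable trace
#' in the latency series: the per-like latency response scales with
#' `alpha^2 * sd(likes)`, while stability requires the `alpha * C` update
#' product small and the Pavlovian saturation `alpha * lambda^2 / (4 C)`
#' moderate. Those constraints meet only at high learning rates with small
#' effort costs, short initial policies, and a sparse like process —
#' pair these ranges with `poisson_lambda = 1`. Agents here post every few
#' minutes; their behavior is strongly, visibly reward-coupled.
#'
#' @return A named list of ranges.
#' @export
granger_power_ranges <- function() {
  list(alpha = c(0.2, 0.3),
       P = c(0, 0.2),
       C = c(0.02, 0.04))
}

sample_params <- function(n, ranges, variant) {
  data.frame(
    alpha = exp(runif(n, log(ranges$alpha[1]), log(ranges$alpha[2]))),
    P = runif(n, ranges$P[1], ranges$P[2]),
    C = exp(runif(n, log(ranges$C[1]), log(ranges$C[2]))),
    variant = variant,
    stringsAsFactors = FALSE)
}

resolve_posts <- function(posts_per_user, n) {
  if (is.function(posts_per_user)) return(as.integer(posts_per_user(n)))
  as.integer(rep_len(posts_per_user, n))
}

#' Generate a synthetic cohort
#'
#' Simulates every user with [simulate_agent()] under the spec's like
#' process and stores the ground-truth parameters alongside the timelines
#' for recovery testing. Each user gets a seed derived deterministically
#' from the spec seed, so the cohort is byte-identical across runs of the
#' same spec.
#'
#' @param spec A [cohort_spec].
#' @return A list of class `cohort`: `timelines` (named list of
#'   [post_timeline]), `truth` (data frame of ground-truth parameters,
#'   one row per user), `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_users = 5, posts_per_user = 40))
#' coh$truth
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_users
  truth <- sample_params(n, spec$param_ranges, spec$variant)
  truth$user_id <- sprintf("u%04d", seq_len(n))
  posts <- resolve_posts(spec$posts_per_user, n)
  truth$n_posts <- posts
  if (spec$like_process == "poisson_per_user") {
    truth$lambda <- spec$poisson_lambda *
      exp(rnorm(n, -0.125, 0.5))  # log-normal with mean poisson_lambda
  } else {
    truth$lambda <- spec$poisson_lambda
  }
  user_seeds <- sample.int(.Machine$integer.max - 1L, n)
  timelines <- vector("list", n)
  truth$n_reseeds <- 0L
  for (i in seq_len(n)) {
    par <- agent_params(truth$alpha[i], truth$P[i], truth$C[i],
                        variant = spec$variant)
    # the policy-gradient recursion has heavy-tailed update steps; a rare
    # unlucky draw sequence can drive the policy into the exponent clamp
    # and produce astronomically long latencies. Such divergent runs are
    # re-simulated under a fresh derived seed (counted in truth$n_reseeds)
    # so every generated timeline is a usable posting record.
    for (attempt in 0:50) {
      seed_i <- (user_seeds[i] + attempt * 1000003L) %% .Machine$integer.max
      tr <- if (spec$like_process == "uniform_block") {
        half <- floor((posts[i] - 1L) / 2)
        rp <- function(t, tau) {
          if (t <= half) sample(0:9, 1) else sample(10:19, 1)
        }
        simulate_agent(par, rp, n_posts = posts[i] - 1L,
                       seed = seed_i, rbar0 = spec$rbar0)
      } else {
        simulate_agent(par, truth$lambda[i], n_posts = posts[i] - 1L,
                       seed = seed_i, rbar0 = spec$rbar0)
      }
      # a mean latency beyond e^20 hours (or below e^-20) marks a diverged
      # policy long before the hard exponent clamp engages
      if (max(abs(log(tr$mu))) < 20) break
      truth$n_reseeds[i] <- truth$n_reseeds[i] + 1L
    }
    if (max(abs(log(tr$mu))) >= 20)
      stop(sprintf(paste0("agent %s (alpha = %.3g, C = %.3g) has divergent",
                          " dynamics under every attempted seed; narrow",
                          " param_ranges (alpha * C is the critical",
                          " product)"),
                   truth$user_id[i], truth$alpha[i], truth$C[i]),
           call. = FALSE)
    timelines[[i]] <- trace_to_timeline(tr, user_id = truth$user_id[i])
  }
  names(timelines) <- truth$user_id
  structure(list(timelines = timelines,
                 truth = truth[, c("user_id", "variant", "alpha", "P", "C",
                                   "lambda", "n_posts", "n_reseeds")],
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d users (%s), %d posts in total\n",
              length(x$timelines), x$spec$variant,
              sum(vapply(x$timelines, length, integer(1)))))
  invisible(x)
}

#' Write / read a cohort spec as JSON
#'
#' A cohort is reproducible from its spec file; generators store the spec
#' next to their outputs for provenance.
#'
#' @param spec A [cohort_spec].
#' @param path Output path.
#' @return `path` invisibly (write) or a [cohort_spec] (read).
#' @export
write_cohort_spec <- function(spec, path) {
  # I(17) significant digits: lossless double round-trip, so a cohort
  # regenerated from the stored spec is byte-identical
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort_spec(n_users = x$n_users, posts_per_user = x$posts_per_user,
              variant = x$variant, param_ranges = x$param_ranges,
              like_process = x$like_process,
              poisson_lambda = x$poisson_lambda, rbar0 = x$rbar0,
              seed = x$seed)
}

## -------------------------------------------------------------------------
## Two-block experiment sessions

#' Experiment session specification
#'
#' A two-block online-experiment session: participants post freely for
#' `session_length` minutes, receiving uniformly distributed likes of 0-9
#' per post in the low-reward block and 10-19 in the high-reward block
#' (expected means 4.5 and 14.5), with block order counterbalanced across
#' participants (`ceiling(n/2)` participants start with the low block).
#' Session time is measured in minutes; [MINUTES_PER_HOUR] is the single
#' conversion constant.
#'
#' @param n_participants Number of participants.
#' @param session_length Session length in minutes (default 25).
#' @param agent `"rrl"` (reward-learning participants with parameters drawn
#'   from `param_ranges`) or `"scripted"` (non-learning participants whose
#'   mean latency is multiplied by `1 + block_effect` in the low block; used
#'   to calibrate the block-effect regression against a known truth).
#' @param param_ranges Minute-scale sampling ranges for the learning agents.
#'   The default learning rates (0.05-0.15) are an order of magnitude above
#'   the platform-cohort defaults: a 25-minute session offers only a dozen
#'   posts, so a visible block contrast requires fast within-session
#'   learning (the latencies here are minutes, which keeps the update
#'   products stable at these rates).
#' @param base_latency Range (minutes) of the scripted agents' mean latency.
#' @param block_effect Scripted multiplicative latency increase in the low
#'   block (0.10 = 10% longer).
#' @param seed Integer seed.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_participants, session_length = 25,
                            agent = c("rrl", "scripted"),
                            param_ranges = list(alpha = c(0.05, 0.15),
                                                P = c(log(1), log(3)),
                                                C = c(0.1, 0.3)),
                            base_latency = c(1, 3),
                            block_effect = 0.10,
                            seed = 1) {
  agent <- match.arg(agent)
  stopifnot(n_participants >= 1, session_length > 0)
  structure(list(n_participants = as.integer(n_participants),
                 session_length = session_length,
                 agent = agent, param_ranges = param_ranges,
                 base_latency = base_latency, block_effect = block_effect,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Minutes per hour: the conversion constant between the experiment's
#' minute-scale clock and the platform timelines' hour-scale clock.
#' @export
MINUTES_PER_HOUR <- 60

#' Generate two-block experiment sessions
#'
#' Simulates each participant posting through a session split into two
#' equal-length blocks. Likes are uniform integers on 0-9 (low block) or
#' 10-19 (high block); block order alternates so that exactly
#' `ceiling(n/2)` participants receive the low block first.
#'
#' @param spec An [experiment_spec].
#' @return A data frame of events with columns `participant`, `order`
#'   (`low_first`/`high_first`), `t` (post index), `time` (minutes into the
#'   session), `block` (`low`/`high`), `likes`, `tau` (minutes, NA for each
#'   participant's first post), plus attribute `spec`.
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  orders <- rep(c("low_first", "high_first"), length.out = n)
  half <- spec$session_length / 2
  if (spec$agent == "rrl") {
    pars <- sample_params(n, spec$param_ranges, "rbar_full")
  } else {
    base <- runif(n, spec$base_latency[1], spec$base_latency[2])
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    low_first <- orders[i] == "low_first"
    times <- likes <- numeric(0)
    if (spec$agent == "rrl") {
      par <- agent_params(pars$alpha[i], pars$P[i], pars$C[i])
      st <- model_state(policy = par$P, rbar = 0)
      now <- 0; prev_tau <- NA_real_
      repeat {
        mu <- mean_latency(st, par)
        tau <- max(rexp(1, rate = 1 / mu), 0.25)  # composing a post takes >= 15 s
        if (now + tau > spec$session_length) break
        now <- now + tau
        lo_block <- xor(now > half, low_first)  # low when in the low block
        r <- if (lo_block) sample(0:9, 1) else sample(10:19, 1)
        times <- c(times, now); likes <- c(likes, r)
        d <- prediction_error(r, tau, st, par)
        st <- update_state(st, tau, prev_tau, d, par)
        prev_tau <- tau
      }
    } else {
      now <- 0
      repeat {
        in_low <- xor(now > half, low_first)
        mu <- base[i] * (1 + if (in_low) spec$block_effect else 0)
        tau <- max(rexp(1, rate = 1 / mu), 0.25)  # composing a post takes >= 15 s
        if (now + tau > spec$session_length) break
        now <- now + tau
        lo_block <- xor(now > half, low_first)
        r <- if (lo_block) sample(0:9, 1) else sample(10:19, 1)
        times <- c(times, now); likes <- c(likes, r)
      }
    }
    m <- length(times)
    if (m == 0) next
    out[[i]] <- data.frame(
      participant = sprintf("p%03d", i),
      order = orders[i],
      t = seq_len(m),
      time = times,
      block = ifelse(xor(times > half, low_first), "low", "high"),
      likes = likes,
      tau = c(NA_real_, diff(times)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "spec") <- spec
  res
}

## -------------------------------------------------------------------------
## Reinforcement schedules

#' Reinforcement schedule specification
#'
#' @param kind `"ratio"` (reward after a fixed number of responses) or
#'   `"interval"` (a reward arms after an exponentially distributed waiting
#'   time and is collected by the next response).
#' @param parameter Responses per reward (ratio) or mean arming interval in
#'   hours (interval); `> 0`.
#' @param magnitude Reward magnitude per delivery.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(kind = c("ratio", "interval"), parameter,
                          magnitude = 1) {
  kind <- match.arg(kind)
  stopifnot(parameter > 0)
  structure(list(kind = kind, parameter = parameter, magnitude = magnitude),
            class = "schedule_spec")
}

#' Simulate an agent on a reinforcement schedule
#'
#' Couples the latency learner to a classic operant schedule: on a ratio
#' schedule every `parameter`-th response is rewarded; on an interval
#' schedule a reward arms after an exponential waiting time (mean
#' `parameter` hours) and the next response collects it, after which the
#' schedule re-arms. This is the free-operant test bed on which reward
#' learning models are expected to reproduce the classic saturating
#' rate-reward relationship.
#'
#' @param spec A [schedule_spec].
#' @param params An [agent_params].
#' @param n Number of responses to simulate.
#' @param seed Integer seed.
#' @param rbar0 Initial average reward rate.
#' @return A `model_trace` (rewards as delivered by the schedule).
#' @export
generate_schedule_session <- function(spec, params, n, seed = NULL,
                                      rbar0 = 0) {
  stopifnot(inherits(spec, "schedule_spec"), inherits(params, "agent_params"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$kind == "ratio") {
    k <- spec$parameter
    count <- 0
    rp <- function(t, tau) {
      count <<- count + 1
      if (count %% k == 0) spec$magnitude else 0
    }
  } else {
    now <- 0
    arm_at <- rexp(1, rate = 1 / spec$parameter)
    rp <- function(t, tau) {
      now <<- now + tau
      if (now >= arm_at) {
        arm_at <<- now + rexp(1, rate = 1 / spec$parameter)
        spec$magnitude
      } else 0
    }
  }
  simulate_agent(params, rp, n_posts = n, rbar0 = rbar0)
}
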