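#' @keywords internal
#' @noRd
EXP_CLAMP <- 50

clamp_exponent <- function(x, warn = TRUE) {
  out <- pmin(pmax(x, -EXP_CLAMP), EXP_CLAMP)
  n <- sum(out != x)
  if (n > 0 && warn)
    warning(sprintf("latency exponent clamped to +/-%d for %d value(s)",
                    EXP_CLAMP, n), call. = FALSE)
  out
}

#' Mean of the latency distribution
#'
#' The model draws each inter-post latency from an exponential distribution
#' whose mean is `exp(policy - alpha * rbar)`: the learned response policy
#' shortened (or lengthened) by the momentary, "Pavlovian" effect of the
#' average net reward rate. The null variant ignores the state and returns
#' the constant `exp(P)`; the Pavlovian-only variant keeps the policy frozen
#' at `P` so that only the `-alpha * rbar` term varies.
#'
#' The exponent is clamped to a documented range (+/-50) with a warning, so
#' the returned mean is always finite and positive.
#'
#' @param state A [model_state].
#' @param params An [agent_params].
#' @return Positive mean latency in hours.
#' @examples
#' mean_latency(model_state(policy = log(48)), agent_params(0.1, log(48), 1))
#' @export
mean_latency <- function(state, params) {
  stopifnot(inherits(state, "model_state"), inherits(params, "agent_params"))
  expo <- switch(params$variant,
                 null_no_learning = params$P,
                 pavlovian_only = params$P - params$alpha * state$rbar,
                 state$policy - params$alpha * state$rbar)
  exp(clamp_exponent(expo))
}

#' Net reward prediction error
#'
#' The experienced reward minus a reference level combining the effort cost
#' of responding and the opportunity cost of the time spent waiting:
#' `delta = R - C / tau - rbar * tau` for the full model. Cost variants
#' replace the effort term: `no_effort_cost` drops it, `fixed_effort_cost`
#' uses a constant `C`, `increasing_effort_cost` uses `C * tau`.
#'
#' @param reward Likes received for the post (non-negative count).
#' @param tau Realized latency (hours), `tau > 0`.
#' @param state A [model_state].
#' @param params An [agent_params].
#' @return The net reward prediction error (reward units).
#' @examples
#' prediction_error(5, 2, model_state(log(24), rbar = 1),
#'                  agent_params(0.1, log(24), 2))
#' @export
prediction_error <- function(reward, tau, state, params) {
  stopifnot(inherits(state, "model_state"), inherits(params, "agent_params"))
  if (!is.finite(tau) || tau <= 0)
    stop("tau must be positive", call. = FALSE)
  cost <- switch(params$variant,
                 no_effort_cost = 0,
                 fixed_effort_cost = params$C,
                 increasing_effort_cost = params$C * tau,
                 params$C / tau)
  reward - cost - state$rbar * tau
}

#' Policy-gradient state update
#'
#' Applies the two update rules of the learner, both with the same step size
#' `alpha`: the policy moves along the gradient estimate
#' `alpha * (tau_t - tau_prev) * delta` (the covariance of the latency
#' "exploration" step with the net outcome), and the average reward rate
#' integrates the prediction error, `rbar' = rbar + alpha * delta`. The two
#' updates both use the pre-update `delta`, so their order is immaterial.
#' Variants without learning (`null_no_learning`) return the state unchanged;
#' `pavlovian_only` updates `rbar` but never the policy.
#'
#' @param state A [model_state].
#' @param tau_t Latency of the current interval (hours).
#' @param tau_prev Latency of the preceding interval (hours), or `NA` when
#'   the current interval is the first (then the policy is left unchanged).
#' @param delta Net reward prediction error for the current interval.
#' @param params An [agent_params].
#' @return The updated [model_state] with `t` advanced by one.
#' @export
update_state <- function(state, tau_t, tau_prev, delta, params) {
  stopifnot(inherits(state, "model_state"), inherits(params, "agent_params"))
  policy <- state$policy
  rbar <- state$rbar
  if (params$variant != "null_no_learning") {
    if (params$variant != "pavlovian_only" && !is.na(tau_prev))
      policy <- policy + params$alpha * (tau_t - tau_prev) * delta
    rbar <- rbar + params$alpha * delta
  }
  model_state(policy = policy, rbar = rbar, t = state$t + 1L)
}

#' Latency maximizing the net reward
#'
#' For a fixed reward, the net reward `R - C / tau - rbar * tau` trades the
#' effort cost (decreasing in `tau`) against the opportunity cost (increasing
#' in `tau`); its maximum is at `tau* = sqrt(C / rbar)`. The optimum shortens
#' as the average reward rate grows, which is the core vigor prediction.
#'
#' @param C Effort cost sensitivity, `C > 0`.
#' @param rbar Average net reward rate, must be positive for a finite
#'   optimum.
#' @return The optimal latency in hours.
#' @examples
#' optimal_latency(C = 4, rbar = 1) # 2 hours
#' @export
optimal_latency <- function(C, rbar) {
  stopifnot(is.numeric(C), is.numeric(rbar))
  if (any(C <= 0))
    stop("C must be positive", call. = FALSE)
  if (any(rbar <= 0))
    stop("no finite optimum: rbar must be positive (the net reward is then monotone in tau)",
         call. = FALSE)
  sqrt(C / rbar)
}

make_trace <- function(tau, reward, policy, rbar, delta, mu, params,
                       user_id = NA_character_) {
  structure(list(user_id = user_id, tau = tau, reward = reward,
                 policy = policy, rbar = rbar, delta = delta, mu = mu,
                 params = params),
            class = "model_trace")
}

#' @export
print.model_trace <- function(x, ...) {
  cat(sprintf("Model trace (%s): %d intervals, mean tau %.3g h, final rbar %.3g\n",
              x$params$variant, length(x$tau), mean(x$tau),
              x$rbar[length(x$rbar)]))
  invisible(x)
}

#' @export
as.data.frame.model_trace <- function(x, ...) {
  data.frame(user_id = x$user_id, t = seq_along(x$tau) + 1L,
             tau = x$tau, likes = x$reward, policy = x$policy,
             rbar = x$rbar, delta = x$delta, mu = x$mu,
             stringsAsFactors = FALSE)
}

#' Run the model forward over an observed timeline
#'
#' Replays the learner's state over a user's observed latencies and likes,
#' returning the per-interval policy, average reward rate, prediction error
#' and predicted mean latency. The trace (and the likelihood built on it) is
#' evaluated for every inter-post interval; the policy update needs a latency
#' difference and therefore starts at the second interval, while the first
#' interval's prediction error already updates the average reward rate.
#'
#' @param params An [agent_params].
#' @param timeline A [post_timeline] with at least 2 posts.
#' @param rbar0 Initial average reward rate (default 0, a neutral prior on
#'   net reward; exposed as a sensitivity knob).
#' @return A `model_trace` with per-interval vectors `tau`, `reward`,
#'   `policy`, `rbar`, `delta`, `mu`, aligned with posts `2..n`.
#' @export
rrl_trace <- function(params, timeline, rbar0 = 0) {
  stopifnot(inherits(params, "agent_params"),
            inherits(timeline, "post_timeline"))
  n <- length(timeline$timestamps)
  if (n < 2)
    stop("timeline must contain at least 2 posts", call. = FALSE)
  tau <- timeline$latencies
  reward <- timeline$likes[-1]
  res <- .rrl_forward_cpp(tau, reward, params$alpha, params$P, params$C,
                          variant_code(params$variant), rbar0, EXP_CLAMP)
  if (res$nclamp > 0)
    warning(sprintf("latency exponent clamped to +/-%d for %d interval(s)",
                    EXP_CLAMP, res$nclamp), call. = FALSE)
  make_trace(tau, reward, res$policy, res$rbar, res$delta, res$mu, params,
             user_id = timeline$user_id)
}

#' Simulate an agent
#'
#' Generates a posting trace from the model: at each step the latency is an
#' exponential draw with mean [mean_latency()], the reward process returns
#' the likes for the post, and the state is advanced with
#' [prediction_error()] and [update_state()]. Fully reproducible under
#' `seed`.
#'
#' @param params An [agent_params].
#' @param reward_process Either a single number (the rate of a constant
#'   Poisson like process, the default study condition) or a function
#'   `f(t, tau)` mapping the post index and realized latency to a like
#'   count.
#' @param n_posts Number of intervals to simulate (`>= 2`).
#' @param seed Integer seed; `NULL` to use the current RNG state.
#' @param rbar0 Initial average reward rate.
#' @param min_latency Minimum producible latency (default 1/60 hour, one
#'   minute): composing and uploading a post takes some minimum time. The
#'   floor also bounds the effort-cost spike `C / tau`, whose expectation
#'   under exponential draws is otherwise infinite.
#' @return A `model_trace`.
#' @examples
#' tr <- simulate_agent(agent_params(0.005, log(24), 1),
#'                      reward_process = 5, n_posts = 100, seed = 1)
#' mean(tr$tau)
#' @export
simulate_agent <- function(params, reward_process = 5, n_posts, seed = NULL,
                           rbar0 = 0, min_latency = 1 / 60) {
  stopifnot(inherits(params, "agent_params"), n_posts >= 2)
  if (!is.null(seed)) set.seed(seed)
  vcode <- variant_code(params$variant)
  if (is.numeric(reward_process) && length(reward_process) == 1L) {
    res <- .rrl_simulate_poisson_cpp(as.integer(n_posts), reward_process,
                                     params$alpha, params$P, params$C,
                                     vcode, rbar0, EXP_CLAMP, min_latency)
    if (res$nclamp > 0)
      warning(sprintf("latency exponent clamped to +/-%d for %d interval(s)",
                      EXP_CLAMP, res$nclamp), call. = FALSE)
    return(make_trace(res$tau, res$reward, res$policy, res$rbar, res$delta,
                      res$mu, params))
  }
  if (!is.function(reward_process))
    stop("reward_process must be a Poisson rate or a function(t, tau)",
         call. = FALSE)
  m <- as.integer(n_posts)
  tau <- reward <- policy <- rbar <- delta <- mu <- numeric(m)
  st <- model_state(policy = params$P, rbar = rbar0)
  for (j in seq_len(m)) {
    policy[j] <- st$policy
    rbar[j] <- st$rbar
    mu[j] <- mean_latency(st, params)
    tau[j] <- max(rexp(1, rate = 1 / mu[j]), min_latency)
    reward[j] <- reward_process(j, tau[j])
    delta[j] <- prediction_error(reward[j], tau[j], st, params)
    st <- update_state(st, tau[j], if (j > 1) tau[j - 1] else NA_real_,
                       delta[j], params)
  }
  make_trace(tau, reward, policy, rbar, delta, mu, params)
}

#' Convert a simulated trace to a posting timeline
#'
#' @param trace A `model_trace`.
#' @param user_id User identifier for the resulting timeline.
#' @param t0 Time of the first post (hours).
#' @param first_likes Likes attached to the first post (default 0; the first
#'   post has no preceding interval so its likes never enter the
#'   likelihood).
#' @return A [post_timeline] with `length(trace$tau) + 1` posts.
#' @export
trace_to_timeline <- function(trace, user_id = "sim", t0 = 0,
                              first_likes = 0) {
  stopifnot(inherits(trace, "model_trace"))
  post_timeline(user_id,
                timestamps = t0 + cumsum(c(0, trace$tau)),
                likes = c(first_likes, trace$reward))
}
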