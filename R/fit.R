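#' Negative log-likelihood of a timeline under the latency model
#'
#' Runs the learner forward on the observed latencies and likes and
#' accumulates the exponential log-density of each inter-post interval given
#' its model-implied mean: `NLL = sum(log mu_t + tau_t / mu_t)`. Every
#' interval contributes a likelihood term; the policy update begins at the
#' second interval (when a latency difference is defined) while the first
#' interval's prediction error already updates the average reward rate.
#'
#' @param params An [agent_params].
#' @param timeline A [post_timeline] with at least 2 posts.
#' @param rbar0 Initial average reward rate (default 0).
#' @return The negative log-likelihood in nats (scalar). Non-finite values
#'   propagate to the caller, where the optimizer treats them as +Inf.
#' @examples
#' tl <- post_timeline("u", cumsum(c(0, 10, 20, 30)), c(0, 0, 0, 0))
#' negative_log_likelihood(agent_params(P = log(20),
#'                                      variant = "null_no_learning"), tl)
#' # 3 * log(20) + 3
#' @export
negative_log_likelihood <- function(params, timeline, rbar0 = 0) {
  stopifnot(inherits(params, "agent_params"),
            inherits(timeline, "post_timeline"))
  if (length(timeline$timestamps) < 2)
    stop("timeline must contain at least 2 posts", call. = FALSE)
  .rrl_nll_cpp(timeline$latencies, timeline$likes[-1],
               params$alpha, params$P, params$C,
               variant_code(params$variant), rbar0, EXP_CLAMP)
}

## Unconstrained optimization scale: alpha through a logistic map, P and C
## through log maps with a small offset on P so the boundary P = 0 stays
## reachable.
P_OFFSET <- 0.01

theta_to_params <- function(theta, variant) {
  if (variant == "null_no_learning")
    return(agent_params(P = max(exp(theta[1]) - P_OFFSET, 0),
                        variant = variant))
  agent_params(alpha = plogis(theta[1]),
               P = max(exp(theta[2]) - P_OFFSET, 0),
               C = exp(theta[3]),
               variant = variant)
}

params_to_theta <- function(params) {
  if (params$variant == "null_no_learning")
    return(log(params$P + P_OFFSET))
  c(qlogis(min(max(params$alpha, 1e-8), 1 - 1e-8)),
    log(params$P + P_OFFSET),
    log(params$C))
}

random_start <- function(variant, tau) {
  p0 <- log(max(mean(tau), 1e-3)) + rnorm(1, 0, 0.5)
  if (variant == "null_no_learning")
    return(log(max(p0, 0) + P_OFFSET))
  c(qlogis(exp(runif(1, log(1e-4), log(0.5)))),
    log(max(p0, 0) + P_OFFSET),
    runif(1, log(0.05), log(10)))
}

#' Fit the latency model to one user by maximum likelihood
#'
#' Multi-start bounded optimization of [negative_log_likelihood()] over the
#' variant's free parameters on an unconstrained scale (logistic-transformed
#' learning rate, log-transformed policy and effort cost). The null model's
#' maximum likelihood estimate is available in closed form (the policy is
#' the log mean latency) and is used directly. Parameter points yielding a
#' non-finite likelihood are treated as +Inf and counted.
#'
#' @param timeline A [post_timeline].
#' @param variant Model variant, see [rrl_variants()].
#' @param n_starts Number of random starts (default 20); one extra
#'   deterministic start at the sample log mean latency is always included.
#' @param rbar0 Initial average reward rate.
#' @param min_posts Minimum posts required (mechanical default 3; the
#'   study-level inclusion rule of 10 posts is applied by [apply_filters()]).
#' @param seed Optional integer seed for the random starts.
#' @param control Passed to [stats::optim()] (Nelder-Mead); defaults set
#'   `reltol = 1e-8`, `maxit = 500`.
#' @return An object of class `rrl_fit` with the estimated [agent_params],
#'   the minimized NLL, AIC (`2k + 2 NLL`), the number of likelihood
#'   intervals, convergence diagnostics, and the data.
#' @examples
#' tl <- post_timeline("u", cumsum(c(0, 10, 20, 30)), rep(0, 4))
#' fit <- rrl_fit(tl, "null_no_learning")
#' coef(fit); AIC(fit)
#' @export
rrl_fit <- function(timeline, variant = "rbar_full", n_starts = 20,
                    rbar0 = 0, min_posts = 3, seed = NULL,
                    control = list()) {
  stopifnot(inherits(timeline, "post_timeline"))
  variant <- match.arg(variant, rrl_variants())
  n <- length(timeline$timestamps)
  if (n < min_posts)
    stop(sprintf("user '%s' has %d posts; %d required", timeline$user_id, n,
                 min_posts), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tau <- timeline$latencies
  likes <- timeline$likes[-1]
  vcode <- variant_code(variant)
  m <- length(tau)
  k <- n_free_params(variant)

  if (variant == "null_no_learning") {
    # closed form: exponential MLE, exp(P) = mean latency
    P_hat <- max(log(mean(tau)), 0)
    par <- agent_params(P = P_hat, variant = variant)
    nll <- negative_log_likelihood(par, timeline)
    out <- structure(list(user_id = timeline$user_id, variant = variant,
                          params = par, nll = nll, k = k, n_intervals = m,
                          aic = 2 * k + 2 * nll, convergence = 0L,
                          n_starts_used = 0L, n_nonfinite = 0L,
                          rbar0 = rbar0, timeline = timeline,
                          boundary = log(mean(tau)) < 0),
                     class = "rrl_fit")
    return(out)
  }

  nonfinite <- 0L
  obj <- function(theta) {
    a <- plogis(theta[1]); P <- max(exp(theta[2]) - P_OFFSET, 0)
    C <- exp(theta[3])
    if (!is.finite(a) || a <= 0 || !is.finite(P) || !is.finite(C) || C <= 0)
      return(1e10)
    v <- .rrl_nll_cpp(tau, likes, a, P, C, vcode, rbar0, EXP_CLAMP)
    if (!is.finite(v)) { nonfinite <<- nonfinite + 1L; return(1e10) }
    v
  }
  ctl <- modifyList(list(reltol = 1e-8, maxit = 500), control)
  P_mle <- log(max(log(max(mean(tau), 1e-3)), 0) + P_OFFSET)
  # two deterministic starts: a weak learner at the exponential MLE and a
  # near-zero learning rate (ensures the nested null likelihood is always
  # attainable)
  smart <- list(c(qlogis(0.001), P_mle, log(1)),
                c(qlogis(1e-8), P_mle, log(1)))
  starts <- c(smart,
              lapply(seq_len(n_starts), function(i) random_start(variant, tau)))
  best <- NULL
  for (s in starts) {
    f0 <- obj(s)
    res <- tryCatch(optim(s, obj, method = "Nelder-Mead", control = ctl),
                    error = function(e) NULL)
    if (is.null(res)) next
    # never worse than the start itself
    if (res$value > f0) res <- list(par = s, value = f0, convergence = 1L)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.null(best) && best$value < 1e10) {
    # Nelder-Mead restart from the incumbent: the simplex re-expands,
    # which polishes premature collapses
    res <- tryCatch(optim(best$par, obj, method = "Nelder-Mead",
                          control = ctl),
                    error = function(e) NULL)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  if (is.null(best) || best$value >= 1e10)
    return(structure(list(user_id = timeline$user_id, variant = variant,
                          params = NULL, nll = Inf, k = k, n_intervals = m,
                          aic = Inf, convergence = 99L,
                          n_starts_used = length(starts),
                          n_nonfinite = nonfinite, rbar0 = rbar0,
                          timeline = timeline, boundary = NA),
                     class = "rrl_fit"))
  par <- theta_to_params(best$par, variant)
  structure(list(user_id = timeline$user_id, variant = variant,
                 params = par, nll = best$value, k = k, n_intervals = m,
                 aic = 2 * k + 2 * best$value,
                 convergence = as.integer(best$convergence),
                 n_starts_used = length(starts), n_nonfinite = nonfinite,
                 rbar0 = rbar0, timeline = timeline,
                 boundary = FALSE),
            class = "rrl_fit")
}

#' @export
print.rrl_fit <- function(x, ...) {
  cat(sprintf("Latency model fit (%s), user '%s'\n", x$variant, x$user_id))
  if (is.null(x$params)) {
    cat("  all optimization starts failed\n")
    return(invisible(x))
  }
  cat(sprintf("  intervals: %d, NLL: %.4f, AIC: %.4f (k = %d)\n",
              x$n_intervals, x$nll, x$aic, x$k))
  cat("  estimates:", paste(sprintf("%s = %.4g", names(coef(x)), coef(x)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.rrl_fit <- function(object, ...) {
  p <- object$params
  if (is.null(p)) return(NULL)
  if (p$variant == "null_no_learning") return(c(P = p$P))
  if (p$variant == "no_effort_cost") return(c(alpha = p$alpha, P = p$P))
  c(alpha = p$alpha, P = p$P, C = p$C)
}

#' @export
logLik.rrl_fit <- function(object, ...) {
  structure(-object$nll, df = object$k, nobs = object$n_intervals,
            class = "logLik")
}

#' @export
summary.rrl_fit <- function(object, ...) {
  tr <- rrl_trace(object$params, object$timeline, object$rbar0)
  out <- list(fit = object,
              mean_tau = mean(tr$tau), mean_mu = mean(tr$mu),
              final_rbar = tr$rbar[length(tr$rbar)],
              range_rbar = range(tr$rbar))
  class(out) <- "summary.rrl_fit"
  out
}

#' @export
print.summary.rrl_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean observed latency %.4g h; mean fitted latency %.4g h\n",
              x$mean_tau, x$mean_mu))
  cat(sprintf("  final rbar %.4g (range %.4g to %.4g)\n",
              x$final_rbar, x$range_rbar[1], x$range_rbar[2]))
  invisible(x)
}

#' Fitted mean latencies
#'
#' @param object An `rrl_fit`.
#' @param ... Unused.
#' @return Numeric vector of model-implied mean latencies (hours), one per
#'   inter-post interval.
#' @export
predict.rrl_fit <- function(object, ...) {
  rrl_trace(object$params, object$timeline, object$rbar0)$mu
}

#' Residuals of a latency model fit
#'
#' @param object An `rrl_fit`.
#' @param type `"quantile"` (randomized-free quantile residuals of the
#'   exponential, mapped through the normal quantile function) or
#'   `"pearson"` (`(tau - mu) / mu`).
#' @param ... Unused.
#' @return Numeric residual vector, one per interval.
#' @export
residuals.rrl_fit <- function(object, type = c("quantile", "pearson"), ...) {
  type <- match.arg(type)
  tr <- rrl_trace(object$params, object$timeline, object$rbar0)
  if (type == "pearson") return((tr$tau - tr$mu) / tr$mu)
  u <- pmin(pmax(1 - exp(-tr$tau / tr$mu), 1e-12), 1 - 1e-12)
  qnorm(u)
}

#' Simulate latencies from a fitted policy
#'
#' Draws latency series from the fitted model's per-interval mean (the
#' estimated policy path conditioned on the observed history), the
#' construction used to visualize expected latency variability around a
#' fitted policy.
#'
#' @param object An `rrl_fit`.
#' @param nsim Number of simulated series.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A matrix with `n_intervals` rows and `nsim` columns.
#' @export
simulate.rrl_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  matrix(rexp(length(mu) * nsim, rate = 1) * rep(mu, nsim),
         ncol = nsim)
}

#' Plot a fitted latency model
#'
#' Observed latencies with the fitted mean latency and the average reward
#' rate path.
#'
#' @param x An `rrl_fit`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.rrl_fit <- function(x, ...) {
  tr <- rrl_trace(x$params, x$timeline, x$rbar0)
  tt <- seq_along(tr$tau)
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(tt, tr$tau, type = "h", col = "grey70", xlab = "interval",
       ylab = "latency (h)",
       main = sprintf("user '%s' (%s)", x$user_id, x$variant), ...)
  lines(tt, tr$mu, col = "purple3", lwd = 2)
  par(new = TRUE)
  plot(tt, tr$rbar, type = "l", col = "goldenrod3", lwd = 2, axes = FALSE,
       xlab = "", ylab = "")
  axis(4, col.axis = "goldenrod4")
  mtext("average reward rate", side = 4, line = 2.5, col = "goldenrod4")
  invisible(x)
}

#' @importFrom graphics axis lines mtext par
NULL
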