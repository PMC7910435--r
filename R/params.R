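#' Model variants
#'
#' Names of the generative model variants understood throughout the package:
#' \describe{
#'   \item{`rbar_full`}{the full average-reward learner: effort cost amortized
#'     over the latency (`C / tau`), opportunity cost `rbar * tau`, policy and
#'     average-reward updates driven by the net prediction error.}
#'   \item{`null_no_learning`}{a stable behavioral tendency: constant mean
#'     latency `exp(P)`, one free parameter, no sensitivity to reward.}
#'   \item{`no_effort_cost`}{drops the effort cost term from the prediction
#'     error (two free parameters).}
#'   \item{`fixed_effort_cost`}{effort cost constant per response (`C`).}
#'   \item{`increasing_effort_cost`}{effort cost growing with the latency
#'     (`C * tau`).}
#'   \item{`pavlovian_only`}{no instrumental policy updating: the policy is
#'     frozen at `P` and only the momentary `-alpha * rbar` term in the
#'     latency mean varies.}
#' }
#' The three cost variants and `pavlovian_only` are reconstructions of the
#' alternative-model family from their verbal descriptions; they are intended
#' for model comparison, not as validated accounts.
#'
#' @return Character vector of variant names.
#' @export
rrl_variants <- function() {
  c("rbar_full", "null_no_learning", "no_effort_cost",
    "fixed_effort_cost", "increasing_effort_cost", "pavlovian_only")
}

variant_code <- function(variant) {
  match(match.arg(variant, rrl_variants()), rrl_variants()) - 1L
}

#' Number of free parameters of a model variant
#'
#' @param variant Variant name, see [rrl_variants()].
#' @return Integer count of free parameters (used in AIC).
#' @export
n_free_params <- function(variant) {
  switch(match.arg(variant, rrl_variants()),
         rbar_full = 3L,
         null_no_learning = 1L,
         no_effort_cost = 2L,
         fixed_effort_cost = 3L,
         increasing_effort_cost = 3L,
         pavlovian_only = 3L)
}

#' Agent parameters
#'
#' Container for the free parameters of the latency model: the learning rate
#' `alpha` (step size of all updates, 0 < alpha <= 1), the initial response
#' policy `P` (log mean latency in log-hours, P >= 0), and the effort cost
#' sensitivity `C` (subjective cost of producing a post, C > 0). The
#' `null_no_learning` variant uses only `P`.
#'
#' @param alpha Learning rate in (0, 1].
#' @param P Initial response policy (log-hours), `P >= 0`.
#' @param C Effort cost sensitivity, `C > 0` (ignored by variants without an
#'   effort cost term; still carried for bookkeeping).
#' @param variant Model variant, see [rrl_variants()].
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(alpha = 0.01, P = log(48), C = 1)
#' @export
agent_params <- function(alpha, P, C, variant = "rbar_full") {
  variant <- match.arg(variant, rrl_variants())
  if (variant == "null_no_learning") {
    if (missing(alpha)) alpha <- 0
    if (missing(C)) C <- 0
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(P), length(P) == 1L, is.finite(P),
            is.numeric(C), length(C) == 1L, is.finite(C))
  if (variant != "null_no_learning") {
    if (alpha <= 0 || alpha > 1)
      stop("alpha must be in (0, 1]", call. = FALSE)
    if (C <= 0)
      stop("C must be positive", call. = FALSE)
  }
  if (P < 0)
    stop("P must be non-negative (log-hours)", call. = FALSE)
  structure(list(alpha = alpha, P = P, C = C, variant = variant),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Agent parameters (", x$variant, ")\n", sep = "")
  if (x$variant == "null_no_learning") {
    cat(sprintf("  P = %.4g (mean latency %.4g h)\n", x$P, exp(x$P)))
  } else {
    cat(sprintf("  alpha = %.4g, P = %.4g (initial mean latency %.4g h), C = %.4g\n",
                x$alpha, x$P, exp(x$P), x$C))
  }
  invisible(x)
}

#' Model state
#'
#' The evolving state of an agent: the current log-latency policy, the
#' subjective average net reward rate `rbar` (reward per hour; may be
#' negative, since it tracks *net* reward), and the post index.
#'
#' @param policy Current log-latency policy (log-hours); finite.
#' @param rbar Subjective average net reward rate (reward/hour); finite.
#' @param t Post index, `t >= 1`.
#' @return An object of class `model_state`.
#' @export
model_state <- function(policy, rbar = 0, t = 1L) {
  stopifnot(is.finite(policy), is.finite(rbar), t >= 1)
  structure(list(policy = policy, rbar = rbar, t = as.integer(t)),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("Model state [t = %d]: policy = %.4g, rbar = %.4g\n",
              x$t, x$policy, x$rbar))
  invisible(x)
}
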