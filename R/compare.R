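#' Akaike weights
#'
#' Normalized relative likelihoods of a compared model set:
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`. Invariant to adding a constant to all AIC
#' values.
#'
#' @param aics Numeric vector of AIC values (length >= 2), optionally named.
#' @return Numeric vector of weights summing to 1.
#' @examples
#' aic_weights(c(null = 100, full = 102))
#' @export
aic_weights <- function(aics) {
  if (length(aics) < 2)
    stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(aics)))
    stop("non-finite AIC values", call. = FALSE)
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit and compare model variants for one user
#'
#' Fits each requested variant with [rrl_fit()] and summarizes the
#' comparison with AIC and Akaike weights. The per-user best model breaks
#' AIC ties toward the variant with fewer free parameters.
#'
#' @param timeline A [post_timeline].
#' @param variants Character vector of variants (default: the full learner
#'   against the no-learning null).
#' @param ... Passed to [rrl_fit()].
#' @return A list of class `rrl_comparison`: `fits` (named list of
#'   `rrl_fit`), `table` (data frame with NLL, k, AIC, AIC weight), and
#'   `best` (variant name).
#' @export
compare_models <- function(timeline,
                           variants = c("rbar_full", "null_no_learning"),
                           ...) {
  variants <- match.arg(variants, rrl_variants(), several.ok = TRUE)
  fits <- lapply(variants, function(v) rrl_fit(timeline, v, ...))
  names(fits) <- variants
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ok <- is.finite(aics)
  w <- rep(NA_real_, length(aics))
  if (sum(ok) >= 2) w[ok] <- aic_weights(aics[ok])
  ks <- vapply(variants, n_free_params, integer(1))
  # ties toward the simpler model
  ord <- order(aics, ks)
  tab <- data.frame(variant = variants,
                    k = ks,
                    nll = vapply(fits, function(f) f$nll, numeric(1)),
                    aic = aics,
                    aic_weight = w,
                    stringsAsFactors = FALSE)
  structure(list(user_id = timeline$user_id, fits = fits, table = tab,
                 best = variants[ord[1]]),
            class = "rrl_comparison")
}

#' @export
print.rrl_comparison <- function(x, ...) {
  cat(sprintf("Model comparison for user '%s' (best: %s)\n", x$user_id,
              x$best))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit model variants across a cohort
#'
#' Per-user maximum likelihood fits of each variant, assembled into a tidy
#' table of estimates, AIC values and Akaike weights. Users for which every
#' optimization start fails are recorded with a reason and excluded from the
#' table.
#'
#' @param timelines List of [post_timeline] objects.
#' @param variants Variants to compare.
#' @param seed Integer seed controlling the random starts (one derived seed
#'   per user, so results do not depend on evaluation order).
#' @param progress Print a dot every 50 users.
#' @param ... Passed to [rrl_fit()].
#' @return An object of class `rrl_fitset`: `table` (one row per user and
#'   variant: `user_id`, `variant`, `alpha`, `P`, `C`, `nll`, `k`, `aic`,
#'   `aic_weight`, `best`), `failures` (data frame of excluded users),
#'   `variants`.
#' @export
fit_cohort <- function(timelines, variants = c("rbar_full", "null_no_learning"),
                       seed = 1, progress = FALSE, ...) {
  stopifnot(length(timelines) >= 1)
  rows <- vector("list", length(timelines))
  failures <- list()
  for (i in seq_along(timelines)) {
    tl <- timelines[[i]]
    cmp <- tryCatch(
      compare_models(tl, variants, seed = seed + 7L * i, ...),
      error = function(e) e)
    if (inherits(cmp, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(user_id = tl$user_id, reason = conditionMessage(cmp),
                   stringsAsFactors = FALSE)
      next
    }
    tab <- cmp$table
    est <- do.call(rbind, lapply(cmp$fits, function(f) {
      p <- f$params
      if (is.null(p)) return(c(alpha = NA_real_, P = NA_real_, C = NA_real_))
      c(alpha = if (p$variant == "null_no_learning") NA_real_ else p$alpha,
        P = p$P,
        C = if (p$variant %in% c("null_no_learning", "no_effort_cost"))
          NA_real_ else p$C)
    }))
    tab <- cbind(data.frame(user_id = tl$user_id, stringsAsFactors = FALSE),
                 tab, est, best = cmp$best)
    rows[[i]] <- tab
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 failures = if (length(failures)) do.call(rbind, failures)
                 else data.frame(user_id = character(), reason = character()),
                 variants = variants),
            class = "rrl_fitset")
}

#' @export
print.rrl_fitset <- function(x, ...) {
  nu <- length(unique(x$table$user_id))
  cat(sprintf("Cohort fits: %d users x %d variants (%d failures)\n",
              nu, length(x$variants), nrow(x$failures)))
  agg <- aggregate(aic_weight ~ variant, data = x$table, FUN = mean)
  names(agg)[2] <- "mean_aic_weight"
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Group-level random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across users and estimates
#' the population frequency of each model with the standard variational
#' Dirichlet scheme, using `-AIC/2` per user and model as the log model
#' evidence proxy. Exceedance probabilities (the probability that a model is
#' the most frequent one in the population) are computed by Monte-Carlo
#' sampling from the Dirichlet posterior.
#'
#' @param evidence A numeric matrix of log model evidence, users in rows,
#'   models in columns (column names are model labels), e.g. `-aic / 2`.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param n_samples Monte-Carlo samples for the exceedance probabilities.
#' @param tol,max_iter Convergence control of the variational iteration.
#' @param seed Optional seed for the Monte-Carlo step.
#' @return An object of class `group_bms`: `alpha` (Dirichlet posterior
#'   counts), `expected_freq`, `xp` (exceedance probabilities, summing to
#'   1), `assignments` (per-user posterior model responsibilities).
#' @examples
#' ev <- cbind(A = c(-1, -1, -1), B = c(-4, -5, -6))
#' group_bms(ev, seed = 1)$xp
#' @export
group_bms <- function(evidence, alpha0 = 1, n_samples = 1e5, tol = 1e-8,
                      max_iter = 500, seed = NULL) {
  evidence <- as.matrix(evidence)
  if (ncol(evidence) < 2)
    stop("group BMS needs at least 2 models", call. = FALSE)
  if (is.null(colnames(evidence)))
    colnames(evidence) <- paste0("m", seq_len(ncol(evidence)))
  K <- ncol(evidence)
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  if (!is.null(seed)) set.seed(seed)
  # Dirichlet sampling via independent gammas
  samp <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                 ncol = K)
  xp <- tabulate(max.col(samp), nbins = K) / n_samples
  names(alpha) <- names(xp) <- colnames(evidence)
  structure(list(alpha = alpha,
                 expected_freq = alpha / sum(alpha),
                 xp = xp,
                 assignments = g),
            class = "group_bms")
}

#' @importFrom stats rgamma
#' @export
print.group_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  print(data.frame(model = names(x$alpha), alpha = x$alpha,
                   expected_freq = x$expected_freq, xp = x$xp,
                   row.names = NULL), digits = 3)
  invisible(x)
}

#' Group summary of a cohort comparison
#'
#' Mean Akaike weight per model with a normal-approximation confidence
#' interval, a one-sample t test of the focal model's weight against 0.5,
#' the per-user best-model proportions, and the random-effects Bayesian
#' model selection of [group_bms()].
#'
#' @param fitset An `rrl_fitset` from [fit_cohort()].
#' @param focal Model whose mean weight is tested against 0.5 (default
#'   `"rbar_full"` if present).
#' @param conf_level Confidence level for the mean-weight interval.
#' @param seed Seed for the exceedance-probability Monte Carlo.
#' @return A list of class `group_comparison` with `mean_weights`,
#'   `t_test`, `best_proportions`, and `bms`.
#' @export
group_comparison <- function(fitset, focal = NULL, conf_level = 0.99,
                             seed = 1) {
  stopifnot(inherits(fitset, "rrl_fitset"))
  tab <- fitset$table[is.finite(fitset$table$aic), ]
  wide_aic <- reshape_wide(tab, "aic")
  wide_w <- reshape_wide(tab, "aic_weight")
  if (is.null(focal))
    focal <- if ("rbar_full" %in% fitset$variants) "rbar_full"
             else fitset$variants[1]
  wbar <- colMeans(wide_w, na.rm = TRUE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- apply(wide_w, 2, sd, na.rm = TRUE) / sqrt(nrow(wide_w))
  mean_weights <- data.frame(variant = colnames(wide_w), mean_w = wbar,
                             lo = wbar - z * se, hi = wbar + z * se,
                             row.names = NULL)
  tt <- t.test(wide_w[, focal], mu = 0.5)
  best <- table(factor(tab$best[!duplicated(tab$user_id)],
                       levels = fitset$variants))
  bms <- group_bms(-wide_aic / 2, seed = seed)
  structure(list(mean_weights = mean_weights, focal = focal,
                 t_test = tt,
                 best_proportions = best / sum(best),
                 bms = bms),
            class = "group_comparison")
}

reshape_wide <- function(tab, value) {
  users <- unique(tab$user_id)
  variants <- unique(tab$variant)
  out <- matrix(NA_real_, length(users), length(variants),
                dimnames = list(users, variants))
  out[cbind(match(tab$user_id, users), match(tab$variant, variants))] <-
    tab[[value]]
  out
}

#' @importFrom stats t.test
#' @export
print.group_comparison <- function(x, ...) {
  cat("Group model comparison\n")
  print(x$mean_weights, digits = 3)
  cat(sprintf("t test of mean AIC weight (%s) vs 0.5: t = %.2f, p = %.3g\n",
              x$focal, unname(x$t_test$statistic), x$t_test$p.value))
  cat("best-model proportions:\n")
  print(round(x$best_proportions, 3))
  cat("exceedance probabilities:\n")
  print(round(x$bms$xp, 3))
  invisible(x)
}
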