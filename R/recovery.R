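#' Parameter- and model-recovery report
#'
#' Fits the compared variants to a synthetic cohort with known ground truth
#' and reports (i) the model-recovery confusion matrix — how often users
#' generated by each variant are classified (by AIC, ties toward the
#' simpler model) as each variant — and (ii) Spearman and Pearson
#' correlations between true and estimated parameters for users generated
#' and classified under learning variants.
#'
#' @param cohort A `cohort` from [generate_cohort()], or a list of such
#'   cohorts (e.g. one of learners and one of null agents).
#' @param variants Variants fitted to every user.
#' @param seed Seed for the optimizer starts.
#' @param n_starts Multi-start count per fit.
#' @param ... Passed to [fit_cohort()].
#' @return A list of class `recovery_report`: `confusion` (true x
#'   classified counts), `accuracy` (overall fraction correctly
#'   classified), `param_recovery` (per-parameter Spearman and Pearson
#'   correlations), `estimates` (merged truth/estimate table), `fitset`.
#' @export
recovery_suite <- function(cohort, variants = c("rbar_full",
                                                "null_no_learning"),
                           seed = 1, n_starts = 20, ...) {
  cohorts <- if (inherits(cohort, "cohort")) list(cohort) else cohort
  timelines <- do.call(c, lapply(cohorts, `[[`, "timelines"))
  truth <- do.call(rbind, lapply(cohorts, `[[`, "truth"))
  if (anyDuplicated(truth$user_id)) {
    # disambiguate ids across merged cohorts
    pre <- rep(seq_along(cohorts),
               vapply(cohorts, function(ch) nrow(ch$truth), integer(1)))
    truth$user_id <- paste0("c", pre, "_", truth$user_id)
    timelines <- lapply(seq_along(timelines), function(i) {
      tl <- timelines[[i]]; tl$user_id <- truth$user_id[i]; tl
    })
    names(timelines) <- truth$user_id
  }
  fs <- fit_cohort(timelines, variants = variants, seed = seed,
                   n_starts = n_starts, ...)
  best <- fs$table[!duplicated(fs$table$user_id),
                   c("user_id", "best")]
  m <- merge(truth, best, by = "user_id")
  confusion <- table(true = m$variant,
                     classified = factor(m$best, levels = variants))
  accuracy <- mean(m$variant == m$best)
  est <- fs$table[fs$table$variant != "null_no_learning" &
                    is.finite(fs$table$aic), ]
  pr <- NULL
  if (nrow(est)) {
    me <- merge(truth, est, by = "user_id",
                suffixes = c("_true", "_hat"))
    me <- me[me$variant_true == me$variant_hat, ]
    if (nrow(me) >= 3) {
      pr <- do.call(rbind, lapply(c("alpha", "P", "C"), function(p) {
        tv <- me[[paste0(p, "_true")]]; ev <- me[[paste0(p, "_hat")]]
        ok <- is.finite(tv) & is.finite(ev)
        if (sum(ok) < 3) return(NULL)
        data.frame(parameter = p,
                   spearman = cor(tv[ok], ev[ok], method = "spearman"),
                   pearson = cor(log(pmax(tv[ok], 1e-12)),
                                 log(pmax(ev[ok], 1e-12))),
                   n = sum(ok))
      }))
    }
  } else me <- NULL
  structure(list(confusion = confusion, accuracy = accuracy,
                 param_recovery = pr, estimates = if (nrow(est)) me else NULL,
                 fitset = fs),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Recovery report: classification accuracy %.1f%%\n",
              100 * x$accuracy))
  print(x$confusion)
  if (!is.null(x$param_recovery)) {
    cat("parameter recovery (generating = classified users):\n")
    print(x$param_recovery, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
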