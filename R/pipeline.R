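#' Pipeline configuration
#'
#' Resolved settings for [run_full_analysis()]: the cohort (or input
#' timelines), the filters, the model set, the analyses, and the seeds.
#' Every run writes the resolved configuration next to its outputs so any
#' output file is regenerable from config + seeds.
#'
#' @param cohort_spec A [cohort_spec] to simulate inputs from, or `NULL`
#'   when `timelines` are supplied directly to the runner.
#' @param min_posts Minimum posts per user (default 10, the study inclusion
#'   rule).
#' @param decile_filter Exclude users whose mean latency falls outside the
#'   20th-80th deciles of the cohort (default `FALSE`; robustness option).
#' @param postcount_filter Exclude users whose post count falls outside the
#'   20th-80th deciles (default `FALSE`).
#' @param partition_quarters Split users into four equal partitions and
#'   summarize model comparison per partition (default `FALSE`).
#' @param variants Models to compare.
#' @param analyses Character subset of
#'   `c("compare", "mixed", "law", "granger", "phenotype")`.
#' @param granger_lags Candidate lags for the Granger calibration.
#' @param n_starts Multi-start count per fit.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec = NULL, min_posts = 10,
                            decile_filter = FALSE, postcount_filter = FALSE,
                            partition_quarters = FALSE,
                            variants = c("rbar_full", "null_no_learning"),
                            analyses = c("compare", "mixed", "law",
                                         "granger", "phenotype"),
                            granger_lags = 1:3, n_starts = 20, seed = 1) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(cohort_spec = cohort_spec, min_posts = min_posts,
                 decile_filter = decile_filter,
                 postcount_filter = postcount_filter,
                 partition_quarters = partition_quarters,
                 variants = variants, analyses = analyses,
                 granger_lags = granger_lags, n_starts = n_starts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Apply inclusion filters to a set of timelines
#'
#' Deterministic filtering with a complete exclusion ledger: the
#' minimum-post rule (users with fewer than `min_posts` posts are excluded)
#' and, optionally, decile-based robustness exclusions of users with
#' especially short or long average latencies or especially few or many
#' posts (outside the 20th-80th deciles). Retained + excluded always equals
#' input.
#'
#' @param timelines List of [post_timeline] objects.
#' @param config A [pipeline_config] (or a list with the filter fields).
#' @return A list: `timelines` (retained), `ledger` (data frame with one
#'   row per excluded user: `user_id`, `rule`, `value`).
#' @export
apply_filters <- function(timelines, config = pipeline_config()) {
  ledger <- list()
  note <- function(ids, rule, values)
    if (length(ids)) data.frame(user_id = ids, rule = rule, value = values,
                                stringsAsFactors = FALSE)
  n_posts <- vapply(timelines, length, integer(1))
  drop <- n_posts < config$min_posts
  ledger[[1]] <- note(names(timelines)[drop], "min_posts", n_posts[drop])
  timelines <- timelines[!drop]
  if (isTRUE(config$decile_filter) && length(timelines)) {
    mt <- vapply(timelines, function(tl) mean(tl$latencies), numeric(1))
    qs <- quantile(mt, c(0.2, 0.8))
    drop <- mt < qs[1] | mt > qs[2]
    ledger[[2]] <- note(names(timelines)[drop], "mean_tau_decile", mt[drop])
    timelines <- timelines[!drop]
  }
  if (isTRUE(config$postcount_filter) && length(timelines)) {
    np <- vapply(timelines, length, integer(1))
    qs <- quantile(np, c(0.2, 0.8))
    drop <- np < qs[1] | np > qs[2]
    ledger[[3]] <- note(names(timelines)[drop], "post_count_decile", np[drop])
    timelines <- timelines[!drop]
  }
  ledger <- do.call(rbind, ledger[!vapply(ledger, is.null, logical(1))])
  if (is.null(ledger))
    ledger <- data.frame(user_id = character(), rule = character(),
                         value = numeric())
  list(timelines = timelines, ledger = ledger)
}

#' Run the full analysis chain
#'
#' Orchestrates the study-style pipeline on a cohort: filter, fit and
#' compare models per user, group-level model comparison, dichotomized
#' reward-rate mixed model, law-of-effect fits, lag-calibrated panel
#' Granger causality, and computational phenotyping. Emits a
#' machine-readable result list and, optionally, JSON + Markdown reports
#' with the resolved config written alongside. Stage failures halt with a
#' stage-tagged error; results computed so far are attached to the error
#' condition.
#'
#' @param config A [pipeline_config].
#' @param timelines Optional list of [post_timeline]s; when `NULL`, the
#'   config's cohort spec is simulated.
#' @param output_dir Optional directory for the report bundle.
#' @param progress Print stage banners.
#' @return A list of class `analysis_report` with elements `config`,
#'   `filter`, `fitset`, `group`, `mixed`, `law`, `granger`, `phenotype`
#'   (those not requested are `NULL`).
#' @export
run_full_analysis <- function(config, timelines = NULL, output_dir = NULL,
                              progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list(config = config)
  stage <- function(name, expr) {
    if (progress) cat(sprintf("[%s] seed=%d\n", name, config$seed))
    tryCatch(expr, error = function(e) {
      e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
      e$partial_results <- results
      stop(e)
    })
  }
  cohort <- NULL
  if (is.null(timelines)) {
    if (is.null(config$cohort_spec))
      stop("[stage input] no timelines and no cohort spec", call. = FALSE)
    cohort <- stage("simulate", generate_cohort(config$cohort_spec))
    timelines <- cohort$timelines
  }
  results$filter <- stage("filter", apply_filters(timelines, config))
  tls <- results$filter$timelines
  if ("compare" %in% config$analyses) {
    results$fitset <- stage("fit", fit_cohort(tls, config$variants,
                                              seed = config$seed,
                                              n_starts = config$n_starts))
    results$group <- stage("compare",
                           group_comparison(results$fitset,
                                            seed = config$seed))
    if (isTRUE(config$partition_quarters)) {
      ids <- unique(results$fitset$table$user_id)
      part <- rep(1:4, length.out = length(ids))[order(order(ids))]
      results$partitions <- stage("partitions", lapply(1:4, function(q) {
        sub <- results$fitset
        sub$table <- sub$table[sub$table$user_id %in% ids[part == q], ]
        group_comparison(sub, seed = config$seed + q)$mean_weights
      }))
    }
  }
  if ("mixed" %in% config$analyses) {
    traces <- stage("traces", {
      if (!is.null(cohort)) {
        lapply(cohort$timelines[names(tls)], function(tl) {
          i <- match(tl$user_id, cohort$truth$user_id)
          rrl_trace(agent_params(cohort$truth$alpha[i], cohort$truth$P[i],
                                 cohort$truth$C[i],
                                 variant = cohort$truth$variant[i]), tl)
        })
      } else {
        stopifnot(!is.null(results$fitset))
        ft <- results$fitset$table
        full <- ft[ft$variant == "rbar_full" & is.finite(ft$aic), ]
        out <- lapply(seq_len(nrow(full)), function(i)
          rrl_trace(agent_params(full$alpha[i], full$P[i], full$C[i]),
                    tls[[full$user_id[i]]]))
        names(out) <- full$user_id
        out
      }
    })
    results$mixed <- stage("mixed", {
      dat <- latency_regression_data(traces)
      mixed_model_latency(dat)
    })
  }
  if ("law" %in% config$analyses)
    results$law <- stage("law", law_of_effect_cohort(tls))
  if ("granger" %in% config$analyses)
    results$granger <- stage("granger", {
      cal_spec_l <- cohort_spec(n_users = 60, posts_per_user = 120,
                                variant = "rbar_full",
                                param_ranges = strong_learning_ranges(),
                                seed = config$seed + 101)
      cal_spec_n <- cohort_spec(n_users = 60, posts_per_user = 120,
                                variant = "null_no_learning",
                                seed = config$seed + 102)
      cal <- calibrate_granger_lags(generate_cohort(cal_spec_l),
                                    generate_cohort(cal_spec_n),
                                    candidate_lags = config$granger_lags,
                                    n_power_panels = 10,
                                    n_null_panels = 40,
                                    null_panel_size = 20,
                                    seed = config$seed)
      L <- if (is.na(cal$chosen_L)) min(config$granger_lags) else cal$chosen_L
      list(calibration = cal, test = panel_granger(tls, L))
    })
  if ("phenotype" %in% config$analyses)
    results$phenotype <- stage("phenotype", {
      stopifnot(!is.null(results$fitset))
      ft <- results$fitset$table
      full <- ft[ft$variant == "rbar_full" & is.finite(ft$aic), ]
      if (nrow(full) < 10) NULL else {
        sol <- cluster_parameters(full[, c("alpha", "P", "C")],
                                  seed = config$seed)
        rownames(sol$pca) <- full$user_id
        sol
      }
    })
  class(results) <- "analysis_report"
  if (!is.null(output_dir))
    write_report(results, output_dir)
  results
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Full analysis report\n")
  cat(sprintf("  users retained: %d (excluded: %d)\n",
              length(x$filter$timelines), nrow(x$filter$ledger)))
  for (nm in c("group", "mixed", "granger", "phenotype"))
    if (!is.null(x[[nm]])) {
      cat("--", nm, "--\n")
      print(if (nm == "granger") x[[nm]]$test else x[[nm]])
    }
  invisible(x)
}

report_summary_list <- function(x) {
  out <- list(seed = x$config$seed,
              n_users = length(x$filter$timelines),
              n_excluded = nrow(x$filter$ledger))
  if (!is.null(x$group)) {
    out$mean_aic_weights <- setNames(x$group$mean_weights$mean_w,
                                     x$group$mean_weights$variant)
    out$xp <- as.list(x$group$bms$xp)
    out$best_proportions <- as.list(x$group$best_proportions)
  }
  if (!is.null(x$mixed))
    out$mixed <- list(predictor = x$mixed$predictor, beta = x$mixed$beta,
                      pct_change = x$mixed$pct_change,
                      aic_weight = x$mixed$aic_weight)
  if (!is.null(x$law))
    out$law <- list(mean_R2_hyperbolic = x$law$mean_R2_hyperbolic,
                    mean_R2_linear = x$law$mean_R2_linear)
  if (!is.null(x$granger))
    out$granger <- list(L = x$granger$test$L,
                        Zbar_tilde = x$granger$test$Zbar_tilde,
                        p = x$granger$test$p)
  if (!is.null(x$phenotype))
    out$phenotype <- list(k = x$phenotype$k,
                          sizes = x$phenotype$sizes)
  out
}

write_report <- function(x, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  s <- report_summary_list(x)
  jsonlite::write_json(s, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- x$config
  cfg$cohort_spec <- if (!is.null(cfg$cohort_spec)) unclass(cfg$cohort_spec)
  jsonlite::write_json(unclass(cfg), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Analysis report", "",
          sprintf("- seed: %d", s$seed),
          sprintf("- users retained: %d (excluded: %d)", s$n_users,
                  s$n_excluded))
  if (!is.null(s$mean_aic_weights))
    md <- c(md, sprintf("- mean AIC weight: %s",
                        paste(names(s$mean_aic_weights),
                              round(s$mean_aic_weights, 3),
                              sep = " = ", collapse = ", ")))
  if (!is.null(s$mixed))
    md <- c(md, sprintf("- mixed model (%s): beta = %.4f (%+.1f%% latency)",
                        s$mixed$predictor, s$mixed$beta,
                        100 * s$mixed$pct_change))
  if (!is.null(s$granger))
    md <- c(md, sprintf("- Granger: Z-tilde = %.2f (L = %d, p = %.3g)",
                        s$granger$Zbar_tilde, s$granger$L, s$granger$p))
  if (!is.null(s$phenotype))
    md <- c(md, sprintf("- phenotypes: k = %d (sizes %s)", s$phenotype$k,
                        paste(s$phenotype$sizes, collapse = ", ")))
  writeLines(md, file.path(output_dir, "report.md"))
  invisible(output_dir)
}

#' Analyze a two-block experiment session log
#'
#' Estimates the block effect on log latency with a random-intercept mixed
#' model (`log tau ~ block + (1 | participant)`; the low-reward block coded
#' as the exposure, so a positive coefficient means longer latencies under
#' the low reward rate), after excluding participants with fewer than
#' `min_responses` posts (logged). Optionally, a model-based variant
#' replaces the block label with a subjective reward-rate series generated
#' by running the learner over each participant's observed likes and
#' latencies.
#'
#' @param events Data frame from [generate_experiment()] (or with columns
#'   `participant`, `t`, `time`, `block`, `likes`, `tau` in minutes).
#' @param min_responses Minimum posts per retained participant (default 5).
#' @param rbar_params An [agent_params] used to generate the subjective
#'   reward-rate series for the model-based analysis (minute units), or
#'   `NULL` to skip it.
#' @return A list of class `experiment_analysis`: `block` (coefficient
#'   table, `beta`, `pct_change`, `n_participants`), `rbar` (same fields
#'   for the model-based predictor, or `NULL`), `excluded` (ledger).
#' @export
run_experiment_analysis <- function(events, min_responses = 5,
                                    rbar_params = NULL) {
  counts <- table(events$participant)
  keep <- names(counts)[counts >= min_responses]
  dropped <- names(counts)[counts < min_responses]
  excluded <- data.frame(participant = dropped,
                         rule = rep("min_responses", length(dropped)),
                         value = as.integer(counts[dropped]),
                         stringsAsFactors = FALSE)
  events <- events[order(events$participant, events$t), ]
  # the latency ending at post t unfolds under the reward condition in
  # force when it started: use the preceding post's block as the exposure
  prev_block <- ave(events$block, events$participant,
                    FUN = function(b) c(NA, head(b, -1)))
  events$low <- as.integer(prev_block == "low")
  ev <- events[events$participant %in% keep & !is.na(events$tau) &
                 !is.na(events$low), ]
  single <- length(keep) < 2
  if (single) {
    warning("single participant: falling back to a fixed-effects model",
            call. = FALSE)
    m <- lm(log(tau) ~ low, data = ev)
    cc <- coef(m); se <- sqrt(diag(vcov(m)))
  } else {
    m <- lme4::lmer(log(tau) ~ low + (1 | participant), data = ev,
                    REML = FALSE)
    cc <- lme4::fixef(m); se <- sqrt(diag(as.matrix(vcov(m))))
  }
  z <- cc / se
  block <- list(coef = data.frame(term = names(cc), estimate = unname(cc),
                                  se = unname(se), z = unname(z),
                                  p = 2 * pnorm(-abs(unname(z))),
                                  row.names = NULL),
                beta = unname(cc["low"]),
                pct_change = exp(unname(cc["low"])) - 1,
                n_participants = length(keep), model = m)
  rbar_res <- NULL
  if (!is.null(rbar_params)) {
    rows <- lapply(split(ev, ev$participant), function(d) {
      d <- d[order(d$t), ]
      if (nrow(d) < 4) return(NULL)
      tl <- post_timeline(d$participant[1],
                          cumsum(c(0, d$tau)) , c(0, d$likes))
      tr <- rrl_trace(rbar_params, tl)
      hi <- dichotomize_rbar(tr$rbar)
      if (is.null(hi)) return(NULL)
      m2 <- length(tr$tau)
      data.frame(participant = d$participant[1],
                 log_tau = log(tr$tau[2:m2]),
                 low = 1L - hi[2:m2])
    })
    dat <- do.call(rbind, rows)
    if (!is.null(dat) && length(unique(dat$participant)) >= 2 &&
        var(dat$low) > 0) {
      m2 <- lme4::lmer(log_tau ~ low + (1 | participant), data = dat,
                       REML = FALSE)
      cc2 <- lme4::fixef(m2); se2 <- sqrt(diag(as.matrix(vcov(m2))))
      rbar_res <- list(beta = unname(cc2["low"]),
                       se = unname(se2["low"]),
                       pct_change = exp(unname(cc2["low"])) - 1,
                       n_participants = length(unique(dat$participant)))
    }
  }
  structure(list(block = block, rbar = rbar_res, excluded = excluded),
            class = "experiment_analysis")
}

#' @export
print.experiment_analysis <- function(x, ...) {
  cat(sprintf("Two-block experiment analysis (%d participants, %d excluded)\n",
              x$block$n_participants, nrow(x$excluded)))
  print(x$block$coef, digits = 3)
  cat(sprintf("low-block effect: beta = %.4f (%+.1f%% latency)\n",
              x$block$beta, 100 * x$block$pct_change))
  if (!is.null(x$rbar))
    cat(sprintf("model-based low-rbar effect: beta = %.4f (se %.3f)\n",
                x$rbar$beta, x$rbar$se))
  invisible(x)
}
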