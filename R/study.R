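# End-to-end study orchestration: cohort -> per-subject protocol (training,
# adaptation, JND, performance) -> outcome measures -> group comparisons and
# learning-effect tests.

#' Default study configuration
#'
#' Encodes the simulated study conditions. Each strategy group's virtual
#' subjects are generated from an internal-model uncertainty `p_param` and a
#' 2IFC observer slope; the adaptation gain follows from the Kalman relation
#' (see [subject_from_uncertainty()]). The defaults encode the feedback
#' structure of the strategies --- RAW and AUG feedback-rich (low perceptual
#' noise, low internal-model uncertainty), FLT feedback-poor --- so the
#' simulated study reproduces the qualitative group ordering: FLT adapts
#' less, has a higher JND and a more uncertain internal model than RAW and
#' AUG.
#'
#' @param n_subjects Cohort size (default 24: three groups of 8).
#' @return A nested list of configuration entries; see the source for the
#'   full schema. All downstream randomness is derived from the single
#'   master seed passed to [run_study()].
#' @export
study_config <- function(n_subjects = 24L) {
  list(
    n_subjects = as.integer(n_subjects),
    strategies = list(
      RAW = list(p_param = 0.095, psychometric_slope = 30),
      FLT = list(p_param = 0.155, psychometric_slope = 48),
      AUG = list(p_param = 0.100, psychometric_slope = 31)
    ),
    subject = list(
      sigma_cntl = 0.025, sigma_sens = 2, motor_noise = 0.03,
      obs_noise = 0.02, leakage = 0.15, visual_delay = 0.2,
      stimulus_scale = 90,
      cv_p = 0.15,      # lognormal inter-subject spread of p_param
      cv_slope = 0.08   # lognormal inter-subject spread of the slope
    ),
    gains = c(20, 20),
    tick = 0.016,
    layout = list(near = 12, far = 20, radius = 1.5),
    staircase = list(start_level = 60, step_down = 1, target_accuracy = 0.84,
                     max_reversals = 23L, max_trials = 400L,
                     average_last = 1L),
    adaptation = list(n_trials = 80L, time_limit = 3),
    steady_hold = list(duration = 2, intent = 0.5),
    run_training = TRUE,
    alpha = 0.05
  )
}

# Build the virtual subject for one participant of a strategy group,
# applying lognormal inter-subject variability to p_param and the slope.
make_group_subject <- function(config, strategy, seed) {
  g <- config$strategies[[strategy]]
  s <- config$subject
  jit <- with_seed(seed, stats::rnorm(2))
  p <- g$p_param * exp(jit[1] * s$cv_p)
  slope <- g$psychometric_slope * exp(jit[2] * s$cv_slope)
  subject_from_uncertainty(
    p_param = p, psychometric_slope = slope,
    sigma_cntl = s$sigma_cntl, sigma_sens = s$sigma_sens,
    stimulus_scale = s$stimulus_scale,
    motor_noise = s$motor_noise, obs_noise = s$obs_noise,
    leakage = s$leakage, visual_delay = s$visual_delay,
    rng_seed = seed
  )
}

#' Run the full protocol for one subject under one strategy
#'
#' Training block (3 x 16 targets, 12 s limit), adaptation block (80 trials
#' of the single +x target) from which the adaptation rate is estimated, a
#' steady-hold segment for the controller-noise estimate, the JND staircase,
#' the two performance sets (16 targets at 1.7 s, 16 at 1.4 s), and finally
#' the internal-model uncertainty inversion.
#'
#' @param subject A [subject_model()].
#' @param strategy_name `"RAW"`, `"FLT"` or `"AUG"`.
#' @param config A [study_config()].
#' @param seed Integer seed for this subject x strategy protocol.
#' @param keep_logs Keep the raw trial logs in the result (memory-heavy for
#'   a full cohort; default `FALSE`).
#' @return A list with `outcomes` (one-row data frame), `metrics` (per-trial
#'   performance), `flags` (character vector of flagged estimator events) and
#'   optionally `logs`.
#' @export
run_subject_protocol <- function(subject, strategy_name, config = study_config(),
                                 seed = 1L, keep_logs = FALSE) {
  strat <- strategy_config(strategy_name, gains = config$gains,
                           tick = config$tick)
  layout <- do.call(target_layout, config$layout)
  flags <- character(0)

  if (isTRUE(config$run_training)) {
    training_logs <- run_block(subject, strat,
                               block_spec("training", layout = layout),
                               seed = derive_seed(seed, 1L))
  } else {
    training_logs <- NULL
  }

  adapt_spec <- block_spec("adaptation", layout = layout,
                           n_trials = config$adaptation$n_trials,
                           time_limit = config$adaptation$time_limit)
  adapt_logs <- run_block(subject, strat, adapt_spec,
                          seed = derive_seed(seed, 2L))
  rate <- estimate_adaptation_rate(adapt_logs)
  if (isTRUE(attr(rate, "flagged"))) flags <- c(flags, "adaptation_rate")

  hold <- simulate_steady_hold(subject,
                               duration = config$steady_hold$duration,
                               intent = config$steady_hold$intent,
                               tick = config$tick,
                               seed = derive_seed(seed, 3L))
  sigma_hat <- estimate_controller_noise(hold)

  sc <- config$staircase
  jnd_res <- run_jnd_experiment(subject,
                                start_level = sc$start_level,
                                step_down = sc$step_down,
                                target_accuracy = sc$target_accuracy,
                                max_reversals = sc$max_reversals,
                                max_trials = sc$max_trials,
                                average_last = sc$average_last,
                                seed = derive_seed(seed, 4L))
  if (jnd_res$flagged) flags <- c(flags, "jnd")

  perf_logs <- run_block(subject, strat,
                         block_spec("performance", layout = layout),
                         seed = derive_seed(seed, 5L))
  metrics <- trial_metrics(perf_logs, strategy = strategy_name)

  p_hat <- if (is.finite(rate) && !jnd_res$flagged) {
    p <- compute_internal_model_uncertainty(
      adaptation_rate = as.numeric(rate), jnd = jnd_res$jnd,
      sigma_cntl_hat = sigma_hat,
      sigma_sens = config$subject$sigma_sens,
      stimulus_scale = config$subject$stimulus_scale,
      target_accuracy = sc$target_accuracy
    )
    if (isTRUE(attr(p, "saturated"))) flags <- c(flags, "p_param_saturated")
    as.numeric(p)
  } else {
    NA_real_
  }

  mean_of <- function(ax, col) {
    v <- metrics[[col]][metrics$axis_class == ax]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }
  outcomes <- data.frame(
    strategy = strategy_name,
    adaptation_rate = as.numeric(rate),
    jnd = jnd_res$jnd,
    p_param = p_hat,
    sigma_cntl_hat = sigma_hat,
    path_efficiency_on = mean_of("on_axis", "path_efficiency"),
    path_efficiency_off = mean_of("off_axis", "path_efficiency"),
    accuracy_on = mean_of("on_axis", "accuracy"),
    accuracy_off = mean_of("off_axis", "accuracy")
  )
  res <- list(outcomes = outcomes, metrics = metrics, flags = flags)
  if (keep_logs) {
    res$logs <- list(training = training_logs, adaptation = adapt_logs,
                     performance = perf_logs)
  }
  res
}

#' Run the complete simulated study
#'
#' Assigns the cohort, runs every subject's protocol under their assigned
#' strategy, reruns the retest subgroups under their retest strategy, and
#' applies the statistical comparison machinery: group comparisons for the
#' psychophysical and performance outcomes, and paired learning-effect t
#' tests for the subgroups. Fully deterministic given the master seed.
#'
#' @param config A [study_config()].
#' @param master_seed Integer master seed; every block, staircase and noise
#'   stream derives from it.
#' @return An object of class `study_report`: a list with `cohort`,
#'   `outcomes` (per subject x exposure), `performance` (tidy summary),
#'   `comparisons` (list of [compare_strategies()] results, one per
#'   outcome), `learning` (paired t table), `flags`, `config`,
#'   `master_seed`.
#' @export
run_study <- function(config = study_config(), master_seed = 1L) {
  cohort <- assign_cohort(seed = derive_seed(master_seed, 0L),
                          n_subjects = config$n_subjects)
  outcome_rows <- list()
  metric_rows <- list()
  flag_rows <- list()

  run_one <- function(subj_id, strategy_name, exposure, seed_offset) {
    subj_seed <- derive_seed(master_seed, seed_offset + subj_id)
    subject <- make_group_subject(config, strategy_name, subj_seed)
    res <- run_subject_protocol(subject, strategy_name, config,
                                seed = derive_seed(subj_seed, 17L))
    out <- cbind(data.frame(subject = subj_id, exposure = exposure),
                 res$outcomes)
    res$metrics$subject <- subj_id
    list(outcomes = out, metrics = res$metrics,
         flags = if (length(res$flags)) {
           data.frame(subject = subj_id, exposure = exposure,
                      flag = res$flags)
         } else {
           NULL
         })
  }

  for (i in seq_len(nrow(cohort))) {
    r <- run_one(cohort$subject[i], cohort$strategy[i], "first", 100L)
    outcome_rows[[length(outcome_rows) + 1L]] <- r$outcomes
    metric_rows[[length(metric_rows) + 1L]] <- r$metrics
    if (!is.null(r$flags)) flag_rows[[length(flag_rows) + 1L]] <- r$flags
  }
  for (i in which(!is.na(cohort$retest))) {
    r <- run_one(cohort$subject[i], cohort$retest[i], "retest", 2000L)
    outcome_rows[[length(outcome_rows) + 1L]] <- r$outcomes
    metric_rows[[length(metric_rows) + 1L]] <- r$metrics
    if (!is.null(r$flags)) flag_rows[[length(flag_rows) + 1L]] <- r$flags
  }

  outcomes <- do.call(rbind, outcome_rows)
  metrics <- do.call(rbind, metric_rows)
  flags <- if (length(flag_rows)) do.call(rbind, flag_rows) else NULL

  first <- outcomes[outcomes$exposure == "first", ]
  comparison_outcomes <- c("adaptation_rate", "jnd", "p_param",
                           "path_efficiency_on", "path_efficiency_off",
                           "accuracy_on", "accuracy_off")
  comparisons <- lapply(comparison_outcomes, function(oc) {
    ok <- is.finite(first[[oc]])
    compare_strategies(first[[oc]][ok], first$strategy[ok], outcome = oc,
                       alpha = config$alpha)
  })
  names(comparisons) <- comparison_outcomes

  first_lab <- merge(first, cohort[c("subject", "subgroup")], by = "subject")
  retest <- outcomes[outcomes$exposure == "retest", ]
  learning <- if (nrow(retest)) {
    paired_learning_tests(first_lab, retest)
  } else {
    NULL
  }

  performance <- summarize_performance(metrics[metrics$subject %in%
                                                 first$subject, ])

  structure(
    list(cohort = cohort, outcomes = outcomes, performance = performance,
         comparisons = comparisons, learning = learning, flags = flags,
         config = config, master_seed = master_seed),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d subjects, master seed %d>\n",
              x$config$n_subjects, x$master_seed))
  first <- x$outcomes[x$outcomes$exposure == "first", ]
  means <- stats::aggregate(
    first[c("adaptation_rate", "jnd", "p_param")],
    by = list(strategy = first$strategy), FUN = mean, na.rm = TRUE
  )
  print(means, digits = 3)
  for (cmp in x$comparisons[c("adaptation_rate", "jnd", "p_param")]) {
    print(cmp)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `outcomes.csv`, `performance_summary.csv`, `cohort.csv`,
#' `learning.csv` (when present) and `comparisons.json` under `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$performance,
                   file.path(dir, "performance_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  if (!is.null(report$learning)) {
    utils::write.csv(report$learning, file.path(dir, "learning.csv"),
                     row.names = FALSE)
  }
  cmp <- lapply(report$comparisons, function(x) {
    list(outcome = x$outcome,
         homogeneity_p = x$homogeneity_p,
         variance_homogeneous = x$variance_homogeneous,
         omnibus = x$omnibus,
         posthoc_method = x$posthoc_method,
         posthoc = x$posthoc,
         group_stats = x$group_stats,
         degenerate = x$degenerate)
  })
  jsonlite::write_json(cmp, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
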