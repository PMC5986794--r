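# The three psychophysical estimators: trial-to-trial adaptation rate, JND
# via an adaptive weighted up-down staircase, and internal-model parameter
# uncertainty via the steady-state Kalman-gain inversion.

#' Mean feedforward activation of a trial
#'
#' Averages the raw activation per DOF over the feedforward window: samples
#' with `t` in `[100 ms, 230 ms]` from trial start (the boundary at 99 ms is
#' excluded, 230 ms included). This window precedes the visuomotor feedback
#' loop, so it reflects the planned command only.
#'
#' @param log A `trial_log` from [run_trial()] covering at least 230 ms.
#' @param window Length-2 window in seconds (default `c(0.100, 0.230)`).
#' @return Named numeric length-2 vector (`dof1`, `dof2`).
#' @export
feedforward_segment <- function(log, window = c(0.100, 0.230)) {
  stopifnot(inherits(log, "trial_log"))
  s <- log$samples
  if (max(s$t) < window[2]) {
    stop(sprintf("trial too short for the feedforward window (%.0f ms < %.0f ms)",
                 max(s$t) * 1000, window[2] * 1000), call. = FALSE)
  }
  sel <- s$t >= window[1] & s$t <= window[2]
  c(dof1 = mean(s$raw1[sel]), dof2 = mean(s$raw2[sel]))
}

#' Estimate the trial-to-trial adaptation rate
#'
#' Least-squares slope of the feedforward command change between consecutive
#' trials against minus the previous trial's observed error:
#' \deqn{u_{n+1} - u_n = \beta \,(-e_n) + \epsilon_n}
#' A slope of 1 means each trial's error is fully cancelled on the next trial
#' (perfect adaptation); 0 means no adaptation.
#'
#' Accepts either the data frame returned by [simulate_adaptation_series()]
#' (columns `command` and `error_obs`) or a list of adaptation-block
#' `trial_log`s, in which case the per-trial command *and* error are both the
#' off-target DOF mean of the feedforward window; trials too short for the
#' window are skipped with a warning.
#'
#' @param x Adaptation series data frame or list of `trial_log`s.
#' @param min_pairs Minimum number of usable consecutive trial pairs.
#' @return The estimated rate (dimensionless). `NA` with attribute
#'   `flagged = TRUE` when the error has zero variance (rate undefined).
#' @export
estimate_adaptation_rate <- function(x, min_pairs = 10L) {
  if (is.data.frame(x)) {
    cmd <- x$command
    err <- if (!is.null(x$error_obs)) x$error_obs else x$error
    if (is.null(err)) stop("series needs an `error_obs` or `error` column",
                           call. = FALSE)
  } else if (is.list(x)) {
    ff <- vapply(x, function(log) {
      tryCatch(feedforward_segment(log)[["dof2"]],
               error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(ff)) {
      warning(sprintf("%d trial(s) shorter than the feedforward window skipped",
                      sum(is.na(ff))))
      # keep the longest run of consecutive usable trials
      r <- rle(!is.na(ff))
      best <- which.max(ifelse(r$values, r$lengths, 0))
      start <- sum(r$lengths[seq_len(best - 1)]) + 1L
      ff <- ff[start:(start + r$lengths[best] - 1L)]
    }
    cmd <- ff
    err <- ff
  } else {
    stop("`x` must be an adaptation series or a list of trial logs",
         call. = FALSE)
  }
  n <- length(cmd)
  if (n < min_pairs + 1L) {
    stop(sprintf("need at least %d consecutive trial pairs", min_pairs),
         call. = FALSE)
  }
  dcmd <- diff(cmd)
  reg <- -err[-n]
  if (stats::var(reg) < 1e-20) {
    return(structure(NA_real_, flagged = TRUE,
                     reason = "zero error variance; rate undefined"))
  }
  unname(stats::coef(stats::lm(dcmd ~ reg))[2])
}

#' Initialize an adaptive weighted up-down staircase
#'
#' Kaernbach's weighted up-down rule: after a correct response the stimulus
#' level drops by `step_down`, after an incorrect one it rises by
#' `step_up = step_down * p / (1 - p)`; the procedure then converges on the
#' level answered correctly with probability `p` (`target_accuracy`, 0.84
#' here, giving the step ratio 5.25). A reversal is logged whenever the
#' movement direction flips, and the staircase terminates at `max_reversals`
#' reversals.
#'
#' @param start_level Initial stimulus level (degrees).
#' @param step_down Downward step size (degrees).
#' @param target_accuracy Converged proportion correct (default 0.84).
#' @param max_reversals Reversals to termination (default 23).
#' @return An object of class `staircase_state`.
#' @export
staircase_init <- function(start_level = 60, step_down = 1,
                           target_accuracy = 0.84, max_reversals = 23L) {
  stopifnot_scalar(start_level, "start_level", lower = 0)
  stopifnot_scalar(step_down, "step_down", lower = 0, allow_zero = FALSE)
  stopifnot_scalar(target_accuracy, "target_accuracy", lower = 0,
                   allow_zero = FALSE)
  if (target_accuracy <= 0.5 || target_accuracy >= 1) {
    stop("`target_accuracy` must be in (0.5, 1)", call. = FALSE)
  }
  structure(
    list(current_level = start_level,
         step_down = step_down,
         step_up = step_down * target_accuracy / (1 - target_accuracy),
         target_accuracy = target_accuracy,
         max_reversals = as.integer(max_reversals),
         reversal_levels = numeric(0),
         last_direction = "none",
         trial_count = 0L,
         levels = numeric(0),
         responses = logical(0),
         reversal_flags = logical(0),
         terminated = FALSE),
    class = "staircase_state"
  )
}

#' Advance the staircase by one response
#'
#' @param state A `staircase_state` (not yet terminated).
#' @param correct Logical: was the 2IFC response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$terminated) {
    stop("staircase already terminated", call. = FALSE)
  }
  correct <- isTRUE(correct)
  direction <- if (correct) "down" else "up"
  reversal <- state$last_direction != "none" &&
    direction != state$last_direction
  state$levels <- c(state$levels, state$current_level)
  state$responses <- c(state$responses, correct)
  state$reversal_flags <- c(state$reversal_flags, reversal)
  if (reversal) {
    # log the turning point: the level presented when direction flipped
    state$reversal_levels <- c(state$reversal_levels, state$current_level)
  }
  state$current_level <- if (correct) {
    max(0, state$current_level - state$step_down)
  } else {
    state$current_level + state$step_up
  }
  state$last_direction <- direction
  state$trial_count <- state$trial_count + 1L
  if (length(state$reversal_levels) >= state$max_reversals) {
    state$terminated <- TRUE
  }
  state
}

#' Threshold of a terminated staircase
#'
#' The just-noticeable difference is the stimulus level at the final (23rd by
#' default) reversal. Averaging the last `average_last` reversal levels is
#' available as a more stable variant.
#'
#' @param state A terminated `staircase_state`.
#' @param average_last Number of trailing reversal levels to average
#'   (default 1: the literal level at the last reversal).
#' @return Threshold in degrees.
#' @export
staircase_threshold <- function(state, average_last = 1L) {
  stopifnot(inherits(state, "staircase_state"))
  if (!state$terminated ||
      length(state$reversal_levels) < state$max_reversals) {
    stop("staircase has not reached its reversal criterion", call. = FALSE)
  }
  mean(utils::tail(state$reversal_levels[seq_len(state$max_reversals)],
                   average_last))
}

#' Run a full JND staircase experiment
#'
#' Drives the 2IFC observer of a virtual subject against the weighted
#' up-down staircase until 23 reversals (or a trial-count guard). The
#' stimulus is an angular rotation (degrees) of the cursor-velocity mapping
#' in one of the two intervals, which is why the JND is reported in degrees.
#'
#' @param subject A [subject_model()].
#' @param start_level,step_down,target_accuracy,max_reversals Passed to
#'   [staircase_init()].
#' @param seed Integer seed; defaults to `subject$rng_seed`.
#' @param max_trials Guard: runs exceeding this many trials (e.g. a
#'   degenerate always-correct observer never reverses) are flagged.
#' @param average_last Passed to [staircase_threshold()].
#' @return A list with `jnd` (degrees; `NA` if flagged), `state` (the full
#'   `staircase_state` history), and `flagged`.
#' @export
run_jnd_experiment <- function(subject, start_level = 60, step_down = 1,
                               target_accuracy = 0.84, max_reversals = 23L,
                               seed = NULL, max_trials = 400L,
                               average_last = 1L) {
  stopifnot(inherits(subject, "subject_model"))
  if (is.null(seed)) seed <- subject$rng_seed
  state <- staircase_init(start_level, step_down, target_accuracy,
                          max_reversals)
  state <- with_seed(seed, {
    while (!state$terminated && state$trial_count < max_trials) {
      correct <- observe_2ifc(subject, state$current_level)
      state <- staircase_update(state, correct)
    }
    state
  })
  if (!state$terminated) {
    return(list(jnd = NA_real_, state = state, flagged = TRUE))
  }
  list(jnd = staircase_threshold(state, average_last = average_last),
       state = state, flagged = FALSE)
}

#' Staircase history as a data frame
#'
#' @param state A `staircase_state`.
#' @return Data frame with `trial`, `level`, `correct`, `reversal`.
#' @export
staircase_history <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  data.frame(trial = seq_along(state$levels), level = state$levels,
             correct = state$responses, reversal = state$reversal_flags)
}

#' Estimate the controller noise SD
#'
#' Sample SD of the raw activation around its mean over steady-intent
#' segments (the subject holds a constant activation, so residual
#' variability is controller noise). Invariant to the held level under the
#' additive noise model.
#'
#' @param x Numeric vector of raw activation samples from steady-hold
#'   segments (at least about 1 s, i.e. >= 30 ticks).
#' @return Estimated controller noise SD (activation units).
#' @export
estimate_controller_noise <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 30L) {
    stop("need at least 30 steady-hold samples (about 0.5 s)", call. = FALSE)
  }
  stats::sd(x)
}

#' Internal-model parameter uncertainty from the psychophysical estimates
#'
#' Inverts the steady-state Kalman relation between the adaptation gain and
#' the uncertainties: the observed feedback variance is reconstructed from
#' the JND,
#' \deqn{\sigma_{fb} = \frac{JND}{\sqrt{2}\, z_{0.84}}, \qquad
#'       R = (\sigma_{fb}/s)^2 + (\sigma_{sens}/s)^2 + \hat\sigma_{cntl}^2}
#' (with \eqn{s} the stimulus scale in degrees and \eqn{z_{0.84}} the normal
#' quantile of the staircase's converged accuracy), and the parameter
#' uncertainty is the unique \eqn{P \ge 0} with Kalman gain equal to the
#' adaptation rate, \eqn{K = P/(P + R)}:
#' \deqn{P = \frac{K}{1 - K} R.}
#' This is the exact inverse of [subject_from_uncertainty()], so generated
#' subjects are recoverable. Strictly increasing in both the adaptation rate
#' and the JND.
#'
#' @param adaptation_rate Estimated adaptation gain (must be < 1 for a finite
#'   result; rates >= 1 indicate over-compensation, for which the
#'   one-parameter model is unbounded and `Inf` is returned with attribute
#'   `saturated = TRUE`).
#' @param jnd Just-noticeable difference (degrees, > 0).
#' @param sigma_cntl_hat Estimated controller noise SD (activation units).
#' @param sigma_sens Sensory noise SD of the perturbation channel (degrees;
#'   a configuration constant).
#' @param stimulus_scale Stimulus normalization (degrees).
#' @param target_accuracy Converged accuracy of the staircase (0.84).
#' @return Internal-model uncertainty `p_param` (normalized variance).
#' @export
compute_internal_model_uncertainty <- function(adaptation_rate, jnd,
                                               sigma_cntl_hat,
                                               sigma_sens = 2,
                                               stimulus_scale = 90,
                                               target_accuracy = 0.84) {
  stopifnot_scalar(jnd, "jnd", lower = 0, allow_zero = FALSE)
  stopifnot_scalar(sigma_cntl_hat, "sigma_cntl_hat", lower = 0)
  stopifnot_scalar(adaptation_rate, "adaptation_rate")
  z <- stats::qnorm(target_accuracy)
  sigma_fb <- jnd / (sqrt(2) * z)
  r <- (sigma_fb / stimulus_scale)^2 + (sigma_sens / stimulus_scale)^2 +
    sigma_cntl_hat^2
  k <- adaptation_rate
  if (k <= 0) {
    return(0)
  }
  if (k >= 1) {
    return(structure(Inf, saturated = TRUE,
                     reason = "adaptation rate >= 1: P unbounded under the model"))
  }
  k / (1 - k) * r
}
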