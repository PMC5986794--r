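# Virtual subjects: generative model for EMG-like signals, trial-by-trial
# adaptive behaviour, and two-interval forced-choice perceptual responses.
# Every downstream estimator is tested against the ground truth held here.

#' Create a virtual subject
#'
#' A virtual subject bundles the generative parameters behind all simulated
#' behaviour: internal-model parameter uncertainty, sensory and controller
#' noise, trial-to-trial feedforward execution noise, the slope of the
#' cumulative-Gaussian two-interval forced-choice (2IFC) observer, and the
#' ground-truth trial-to-trial adaptation gain.
#'
#' @param p_param Internal-model parameter uncertainty (variance, normalized
#'   task units squared). Non-negative.
#' @param sigma_sens Sensory noise SD of the perturbation channel (degrees).
#' @param sigma_cntl Controller noise SD (activation units per control tick).
#' @param motor_noise SD of the trial-to-trial feedforward command execution
#'   noise (activation units).
#' @param psychometric_slope SD of the cumulative-Gaussian 2IFC observer
#'   (degrees). Smaller values mean finer perceptual resolution.
#' @param adaptation_gain Ground-truth trial-to-trial error-correction gain in
#'   `[0, 1.5]`. 1 means each trial's observed error is fully cancelled on the
#'   next trial.
#' @param rng_seed Integer seed attached to the subject; generators fall back
#'   to it when no explicit seed is given.
#' @param obs_noise SD of the noise on the subject's observation of its own
#'   self-generated error (activation units).
#' @param leakage Systematic off-target activation leaked into the unused
#'   degree of freedom when driving the other one (activation units per unit
#'   of on-target intent). This is the source of the "self-generated error"
#'   that the adaptation block measures.
#' @param visual_delay Visuomotor feedback delay (seconds). Intent inside a
#'   trial tracks the cursor position this far in the past, which keeps the
#'   100--230 ms feedforward window free of feedback corrections.
#' @param lapse_rate Probability of a stimulus-independent random 2IFC
#'   response. Default 0 (ideal observer).
#' @param stimulus_scale Normalization constant for rotation stimuli
#'   (degrees); used to express perceptual variances in task units.
#' @return An object of class `subject_model`.
#' @seealso [subject_from_uncertainty()] for constructing a subject whose
#'   adaptation gain is derived from `(p_param, psychometric_slope)` via the
#'   steady-state Kalman relation.
#' @export
subject_model <- function(p_param = 0.12,
                          sigma_sens = 2,
                          sigma_cntl = 0.025,
                          motor_noise = 0.03,
                          psychometric_slope = 30,
                          adaptation_gain = 0.5,
                          rng_seed = 1L,
                          obs_noise = 0.02,
                          leakage = 0.15,
                          visual_delay = 0.2,
                          lapse_rate = 0,
                          stimulus_scale = 90) {
  stopifnot_scalar(p_param, "p_param", lower = 0)
  stopifnot_scalar(sigma_sens, "sigma_sens", lower = 0)
  stopifnot_scalar(sigma_cntl, "sigma_cntl", lower = 0)
  stopifnot_scalar(motor_noise, "motor_noise", lower = 0)
  stopifnot_scalar(psychometric_slope, "psychometric_slope", lower = 0,
                   allow_zero = FALSE)
  stopifnot_scalar(adaptation_gain, "adaptation_gain")
  if (adaptation_gain < 0 || adaptation_gain > 1.5) {
    stop("`adaptation_gain` must lie in [0, 1.5]", call. = FALSE)
  }
  stopifnot_scalar(obs_noise, "obs_noise", lower = 0)
  stopifnot_scalar(leakage, "leakage")
  stopifnot_scalar(visual_delay, "visual_delay", lower = 0)
  stopifnot_scalar(lapse_rate, "lapse_rate", lower = 0)
  stopifnot_scalar(stimulus_scale, "stimulus_scale", lower = 0,
                   allow_zero = FALSE)
  structure(
    list(
      p_param = p_param,
      sigma_sens = sigma_sens,
      sigma_cntl = sigma_cntl,
      motor_noise = motor_noise,
      psychometric_slope = psychometric_slope,
      adaptation_gain = adaptation_gain,
      rng_seed = as.integer(rng_seed),
      obs_noise = obs_noise,
      leakage = leakage,
      visual_delay = visual_delay,
      lapse_rate = lapse_rate,
      stimulus_scale = stimulus_scale
    ),
    class = "subject_model"
  )
}

#' Construct a subject from internal-model and feedback uncertainties
#'
#' Builds a [subject_model()] whose adaptation gain is the steady-state Kalman
#' gain implied by the internal-model parameter uncertainty `p_param` and the
#' total observation variance:
#' \deqn{K = P / (P + R_{fb} + (\sigma_{sens}/s)^2 + \sigma_{cntl}^2)}
#' where \eqn{R_{fb}} is the perceptual feedback variance in normalized task
#' units and \eqn{s} the stimulus scale. The psychometric slope is set to
#' \eqn{\sqrt{R_{fb}} \cdot s} degrees, so the estimator chain in the
#' psychophysics module inverts this construction exactly.
#'
#' @param p_param Internal-model parameter uncertainty (normalized variance).
#' @param r_fb Perceptual feedback noise variance (normalized units). Exactly
#'   one of `r_fb` and `psychometric_slope` must be given.
#' @param psychometric_slope Alternative parameterization: observer slope in
#'   degrees, converted to `r_fb = (slope/stimulus_scale)^2`.
#' @param sigma_cntl,sigma_sens,stimulus_scale,... Passed to [subject_model()].
#' @return A `subject_model` with derived `adaptation_gain`.
#' @export
subject_from_uncertainty <- function(p_param,
                                     r_fb = NULL,
                                     psychometric_slope = NULL,
                                     sigma_cntl = 0.025,
                                     sigma_sens = 2,
                                     stimulus_scale = 90,
                                     ...) {
  if (is.null(r_fb) == is.null(psychometric_slope)) {
    stop("give exactly one of `r_fb` or `psychometric_slope`", call. = FALSE)
  }
  if (is.null(r_fb)) {
    r_fb <- (psychometric_slope / stimulus_scale)^2
  } else {
    psychometric_slope <- sqrt(r_fb) * stimulus_scale
  }
  v <- r_fb + (sigma_sens / stimulus_scale)^2 + sigma_cntl^2
  gain <- p_param / (p_param + v)
  subject_model(
    p_param = p_param,
    sigma_sens = sigma_sens,
    sigma_cntl = sigma_cntl,
    psychometric_slope = psychometric_slope,
    adaptation_gain = gain,
    stimulus_scale = stimulus_scale,
    ...
  )
}

#' Configuration of the synthetic EMG generator
#'
#' Describes an array of surface-EMG channels whose amplitude is modulated by
#' signed two-degree-of-freedom wrist activations (extension/flexion and
#' abduction/adduction). Each of the four movement directions drives channels
#' through a non-negative synergy weight matrix.
#'
#' @param n_channels Number of electrodes (default 8).
#' @param fs Sampling rate in Hz (default 1000).
#' @param synergy_matrix 4 x `n_channels` non-negative matrix of weights;
#'   rows are the directions `ext` (+DOF1), `flex` (-DOF1), `abd` (+DOF2),
#'   `add` (-DOF2). Rows must be pairwise distinct so the directions are
#'   separable. Defaults to [default_synergy_matrix()].
#' @param baseline_noise SD of the resting signal (arbitrary amplitude units).
#' @return An object of class `emg_config`.
#' @export
emg_config <- function(n_channels = 8L,
                       fs = 1000,
                       synergy_matrix = default_synergy_matrix(n_channels),
                       baseline_noise = 0.05) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 2L) stop("`n_channels` must be >= 2", call. = FALSE)
  stopifnot_scalar(fs, "fs", lower = 0, allow_zero = FALSE)
  stopifnot_scalar(baseline_noise, "baseline_noise", lower = 0)
  synergy_matrix <- as.matrix(synergy_matrix)
  if (!identical(dim(synergy_matrix), c(4L, n_channels))) {
    stop("`synergy_matrix` must be 4 x n_channels", call. = FALSE)
  }
  if (any(synergy_matrix < 0)) {
    stop("`synergy_matrix` must be non-negative", call. = FALSE)
  }
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (isTRUE(all.equal(synergy_matrix[i, ], synergy_matrix[j, ]))) {
        stop("synergy_matrix rows must distinguish the 4 directions",
             call. = FALSE)
      }
    }
  }
  rownames(synergy_matrix) <- c("ext", "flex", "abd", "add")
  structure(
    list(
      n_channels = n_channels,
      fs = fs,
      synergy_matrix = synergy_matrix,
      baseline_noise = baseline_noise
    ),
    class = "emg_config"
  )
}

#' Default direction-to-channel synergy weights
#'
#' Each direction strongly drives a dedicated pair of adjacent channels with
#' weak crosstalk elsewhere, mimicking electrodes placed over the four
#' principal forearm muscle groups.
#'
#' @param n_channels Number of channels (>= 2).
#' @return A 4 x `n_channels` matrix.
#' @export
default_synergy_matrix <- function(n_channels = 8L) {
  m <- matrix(0.05, nrow = 4, ncol = n_channels)
  for (d in 1:4) {
    primary <- (d - 1L) * n_channels %/% 4L + 1L
    secondary <- primary %% n_channels + 1L
    m[d, primary] <- 1.0
    m[d, secondary] <- 0.7
  }
  rownames(m) <- c("ext", "flex", "abd", "add")
  m
}

#' Generate a multichannel synthetic EMG signal
#'
#' Each channel is zero-mean Gaussian noise whose instantaneous SD is
#' `baseline_noise` plus the synergy-weighted rectified activation of the four
#' signed directions. This amplitude-modulation model preserves the
#' activation-to-feature monotonicity that the downstream feature/regression
#' chain relies on without simulating motor units.
#'
#' @param config An [emg_config()].
#' @param activation_trace Numeric matrix (n_samples x 2) of signed DOF
#'   activations in `[-1, 1]`, sampled at `config$fs`. Column 1 is wrist
#'   extension(+)/flexion(-), column 2 abduction(+)/adduction(-).
#' @param seed Integer seed; identical seeds give bit-identical signals.
#' @return Numeric matrix, `n_channels` x `n_samples`.
#' @export
generate_emg <- function(config, activation_trace, seed = 1L) {
  stopifnot(inherits(config, "emg_config"))
  activation_trace <- as.matrix(activation_trace)
  if (ncol(activation_trace) != 2L) {
    stop("`activation_trace` must have 2 columns (one per DOF)", call. = FALSE)
  }
  if (nrow(activation_trace) < 1L) {
    stop("`activation_trace` is empty", call. = FALSE)
  }
  if (any(!is.finite(activation_trace)) ||
      any(abs(activation_trace) > 1 + 1e-12)) {
    stop("activations must be finite and within [-1, 1]", call. = FALSE)
  }
  n <- nrow(activation_trace)
  # 4 x n drive matrix of rectified signed directions
  drive <- rbind(
    ext = pmax(activation_trace[, 1], 0),
    flex = pmax(-activation_trace[, 1], 0),
    abd = pmax(activation_trace[, 2], 0),
    add = pmax(-activation_trace[, 2], 0)
  )
  envelope <- config$baseline_noise + t(config$synergy_matrix) %*% drive
  with_seed(seed, {
    noise <- matrix(stats::rnorm(config$n_channels * n),
                    nrow = config$n_channels)
    noise * envelope
  })
}

#' Simulate a trial-by-trial adaptation series
#'
#' Generates the per-trial feedforward off-target command of a subject
#' repeatedly acquiring a single on-axis target. On every trial the executed
#' self-generated error is the current feedforward command plus controller
#' noise; the subject observes it through sensory noise and corrects the next
#' trial's command by `adaptation_gain` times the observed error, plus
#' feedforward execution noise:
#' \deqn{u_{n+1} = u_n - K \cdot e^{obs}_n + m_n}
#'
#' @param subject A [subject_model()].
#' @param n_trials Number of trials (>= 2). The adaptation block uses 80.
#' @param target_dof Which DOF is the task axis; the returned series is the
#'   command on the *other* (off-target) DOF. `"dof1"` or `"dof2"`.
#' @param initial_command Initial off-target feedforward command; defaults to
#'   the subject's `leakage` (an uncompensated synergy leak).
#' @param seed Integer seed; defaults to `subject$rng_seed`.
#' @return A data frame with columns `trial`, `command` (planned feedforward
#'   off-target command), `error_true` (executed self-generated error) and
#'   `error_obs` (what the subject perceived and corrected against), with the
#'   ground-truth gain in `attr(, "adaptation_gain")`.
#' @export
simulate_adaptation_series <- function(subject, n_trials = 80L,
                                       target_dof = c("dof1", "dof2"),
                                       initial_command = NULL,
                                       seed = NULL) {
  stopifnot(inherits(subject, "subject_model"))
  target_dof <- match.arg(target_dof)
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L) stop("`n_trials` must be >= 2", call. = FALSE)
  if (is.null(initial_command)) initial_command <- subject$leakage
  if (is.null(seed)) seed <- subject$rng_seed
  with_seed(seed, {
    u <- numeric(n_trials)
    e_true <- numeric(n_trials)
    e_obs <- numeric(n_trials)
    u[1] <- initial_command
    for (n in seq_len(n_trials)) {
      e_true[n] <- u[n] + stats::rnorm(1, sd = subject$sigma_cntl)
      e_obs[n] <- e_true[n] + stats::rnorm(1, sd = subject$obs_noise)
      if (n < n_trials) {
        u[n + 1] <- u[n] - subject$adaptation_gain * e_obs[n] +
          stats::rnorm(1, sd = subject$motor_noise)
      }
    }
    structure(
      data.frame(trial = seq_len(n_trials), command = u,
                 error_true = e_true, error_obs = e_obs),
      adaptation_gain = subject$adaptation_gain,
      target_dof = target_dof
    )
  })
}

#' 2IFC detection probability of the ideal observer
#'
#' Probability that the observer correctly identifies which of two intervals
#' carried a perturbation of the given magnitude:
#' \deqn{P(correct) = \Phi\left(\frac{stimulus}{\sigma\sqrt{2}}\right)}
#' with \eqn{\sigma} the psychometric slope. At zero stimulus this is the 2IFC
#' chance floor of 0.5; a non-zero lapse rate mixes in random guessing.
#'
#' @param subject A [subject_model()].
#' @param stimulus_magnitude Non-negative stimulus magnitude (degrees).
#' @return Probability of a correct response.
#' @export
prob_correct_2ifc <- function(subject, stimulus_magnitude) {
  stopifnot(inherits(subject, "subject_model"))
  if (any(stimulus_magnitude < 0)) {
    stop("`stimulus_magnitude` must be >= 0", call. = FALSE)
  }
  p <- stats::pnorm(stimulus_magnitude / (subject$psychometric_slope * sqrt(2)))
  subject$lapse_rate * 0.5 + (1 - subject$lapse_rate) * p
}

#' Draw one 2IFC response
#'
#' Simulates the subject's forced choice between two intervals, one of which
#' carried the stimulus.
#'
#' @inheritParams prob_correct_2ifc
#' @param seed Optional integer seed. When `NULL` the current RNG stream is
#'   consumed (so staircase drivers can seed once).
#' @return `TRUE` when the subject picked the interval with the stimulus.
#' @export
observe_2ifc <- function(subject, stimulus_magnitude, seed = NULL) {
  p <- prob_correct_2ifc(subject, stimulus_magnitude)
  if (is.null(seed)) {
    stats::runif(1) < p
  } else {
    with_seed(seed, stats::runif(1) < p)
  }
}

#' Simulate a steady-hold activation segment
#'
#' The subject holds a constant intent on one DOF; each 16 ms control tick
#' adds controller noise. Used to estimate the controller noise SD.
#'
#' @param subject A [subject_model()].
#' @param duration Hold duration in seconds (default 2).
#' @param intent Constant intended activation level (default 0.5).
#' @param tick Control tick in seconds (default 0.016).
#' @param seed Integer seed; defaults to `subject$rng_seed`.
#' @return Numeric vector of raw activation samples, one per tick.
#' @export
simulate_steady_hold <- function(subject, duration = 2, intent = 0.5,
                                 tick = 0.016, seed = NULL) {
  stopifnot(inherits(subject, "subject_model"))
  if (is.null(seed)) seed <- subject$rng_seed
  n <- max(2L, floor(duration / tick))
  with_seed(seed, intent + stats::rnorm(n, sd = subject$sigma_cntl))
}

#' @export
print.subject_model <- function(x, ...) {
  cat("<subject_model>\n")
  cat(sprintf("  p_param: %.4g  adaptation_gain: %.3f\n",
              x$p_param, x$adaptation_gain))
  cat(sprintf("  psychometric_slope: %.3g deg  sigma_sens: %.3g deg\n",
              x$psychometric_slope, x$sigma_sens))
  cat(sprintf("  sigma_cntl: %.3g  motor_noise: %.3g  leakage: %.3g\n",
              x$sigma_cntl, x$motor_noise, x$leakage))
  invisible(x)
}

#' Read or write subject/EMG configuration as YAML
#'
#' @param x A `subject_model` or `emg_config`.
#' @param path File path.
#' @return `read_subject_yaml()` returns a `subject_model`;
#'   `read_emg_config_yaml()` an `emg_config`. Writers return `path`
#'   invisibly.
#' @name config_io
#' @export
write_subject_yaml <- function(x, path) {
  stopifnot(inherits(x, "subject_model"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_subject_yaml <- function(path) {
  do.call(subject_model, yaml::read_yaml(path))
}

#' @rdname config_io
#' @export
write_emg_config_yaml <- function(x, path) {
  stopifnot(inherits(x, "emg_config"))
  out <- unclass(x)
  out$synergy_matrix <- lapply(seq_len(nrow(x$synergy_matrix)),
                               function(i) as.numeric(x$synergy_matrix[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_emg_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$synergy_matrix <- do.call(rbind, raw$synergy_matrix)
  do.call(emg_config, raw)
}

#' Write a multichannel signal as CSV
#'
#' One column per channel plus a leading sample-index column.
#'
#' @param signal Matrix, channels x samples.
#' @param path File path.
#' @export
write_signal_csv <- function(signal, path) {
  df <- data.frame(sample = seq_len(ncol(signal)), t(signal))
  names(df) <- c("sample", paste0("ch", seq_len(nrow(signal))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  t(as.matrix(df[, -1, drop = FALSE]))
}
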