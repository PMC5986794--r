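# Virtual target-acquisition experiment: target layouts, closed-loop trial
# execution at 16 ms ticks, and block orchestration (training, adaptation,
# performance).

#' Target layout parameters
#'
#' The canonical two-ring, 16-target layout: 8 on-axis targets at two
#' distances along +/-x and +/-y, and 8 off-axis targets on the four quadrant
#' diagonals at the same two radial distances. All outcome metrics are ratios
#' (efficiency, normalized accuracy), so they are insensitive to the absolute
#' pixel scale chosen here.
#'
#' @param near,far Radial distances of the two rings (pixels).
#' @param radius Acquisition radius (pixels): the cursor acquires the target
#'   the first tick it is within this Euclidean distance of the center.
#' @return A list with `near`, `far`, `radius`.
#' @export
target_layout <- function(near = 12, far = 20, radius = 1.5) {
  stopifnot_scalar(near, "near", lower = 0, allow_zero = FALSE)
  stopifnot_scalar(far, "far", lower = 0, allow_zero = FALSE)
  stopifnot_scalar(radius, "radius", lower = 0, allow_zero = FALSE)
  list(near = near, far = far, radius = radius)
}

#' Create a single target
#'
#' @param center Numeric length-2 center position in pixels (origin at the
#'   screen center).
#' @param time_limit Acquisition time limit in seconds.
#' @param radius Acquisition radius in pixels.
#' @return An object of class `task_target` with an `axis_class` field:
#'   `"on_axis"` when exactly one coordinate is zero (single-DOF target),
#'   `"off_axis"` otherwise.
#' @export
task_target <- function(center, time_limit, radius = 1.5) {
  stopifnot(length(center) == 2L, all(is.finite(center)))
  stopifnot_scalar(time_limit, "time_limit", lower = 0)
  stopifnot_scalar(radius, "radius", lower = 0, allow_zero = FALSE)
  axis_class <- if (sum(center == 0) == 1L) "on_axis" else "off_axis"
  structure(list(center = as.numeric(center), time_limit = time_limit,
                 radius = radius, axis_class = axis_class),
            class = "task_target")
}

#' Specify an experimental block
#'
#' Encodes the protocol's block structure: training is 3 sets of 16 targets
#' at a 12 s limit; the adaptation block repeats a single on-axis target (on
#' the +x axis, i.e. wrist extension) for 80 trials; the performance test is
#' 2 sets of 16 targets with limits of 1.7 s then 1.4 s.
#'
#' @param kind One of `"training"`, `"adaptation"`, `"performance"`, `"jnd"`.
#' @param layout A [target_layout()].
#' @param n_sets,targets_per_set,time_limit,n_trials Overrides for the
#'   protocol defaults; normally left alone.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(kind = c("training", "adaptation", "performance", "jnd"),
                       layout = target_layout(),
                       n_sets = NULL, targets_per_set = 16L,
                       time_limit = NULL, n_trials = 80L) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    training = list(n_sets = n_sets %||% 3L,
                    targets_per_set = targets_per_set,
                    time_limit = time_limit %||% 12),
    adaptation = list(n_trials = as.integer(n_trials),
                      time_limit = time_limit %||% 3),
    performance = list(n_sets = n_sets %||% 2L,
                       targets_per_set = targets_per_set,
                       time_limit = time_limit %||% c(1.7, 1.4)),
    jnd = list()
  )
  if (kind == "performance" &&
      length(spec$time_limit) != spec$n_sets) {
    stop("performance blocks need one time limit per set", call. = FALSE)
  }
  structure(c(list(kind = kind, layout = layout), spec),
            class = "block_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

canonical_positions <- function(layout) {
  d <- c(layout$near, layout$far)
  on_axis <- rbind(
    cbind(d, 0), cbind(-d, 0), cbind(0, d), cbind(0, -d)
  )
  diag_d <- d / sqrt(2)
  off_axis <- rbind(
    cbind(diag_d, diag_d), cbind(-diag_d, diag_d),
    cbind(-diag_d, -diag_d), cbind(diag_d, -diag_d)
  )
  rbind(on_axis, off_axis)
}

#' Generate the ordered target list for a block
#'
#' Targets appear at the fixed canonical positions of the layout but in a
#' seed-shuffled order, independently per set. The adaptation block instead
#' returns `n_trials` copies of the single +x-axis target at the far
#' distance.
#'
#' @param spec A [block_spec()].
#' @param seed Integer seed for the shuffle.
#' @return A data frame with one row per trial: `set`, `trial`, `x`, `y`,
#'   `radius`, `time_limit`, `axis_class`.
#' @export
generate_target_set <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "block_spec"))
  layout <- spec$layout
  if (spec$kind == "adaptation") {
    n <- spec$n_trials
    df <- data.frame(set = 1L, trial = seq_len(n),
                     x = layout$far, y = 0,
                     radius = layout$radius,
                     time_limit = spec$time_limit)
  } else if (spec$kind %in% c("training", "performance")) {
    pos <- canonical_positions(layout)
    sets <- lapply(seq_len(spec$n_sets), function(s) {
      ord <- with_seed(derive_seed(seed, s), sample.int(nrow(pos)))
      tl <- if (length(spec$time_limit) > 1) spec$time_limit[s] else spec$time_limit
      data.frame(set = s, trial = seq_len(nrow(pos)),
                 x = pos[ord, 1], y = pos[ord, 2],
                 radius = layout$radius, time_limit = tl)
    })
    df <- do.call(rbind, sets)
  } else {
    stop("the jnd block has no target set; use run_jnd_experiment()",
         call. = FALSE)
  }
  df$axis_class <- ifelse((df$x == 0) + (df$y == 0) == 1L,
                          "on_axis", "off_axis")
  rownames(df) <- NULL
  df
}

#' Run one closed-loop target-acquisition trial
#'
#' Simulates the cursor loop at 16 ms ticks. Each tick the subject forms a
#' proportional pursuit intent toward the target based on the cursor position
#' `visual_delay` seconds in the past, adds a systematic synergy leakage into
#' the off-target DOF, any feedforward offset carried across trials by the
#' adaptation state, and per-tick controller noise. The resulting raw
#' activation drives the cursor through the strategy mapping (RAW:
#' simultaneous; FLT/AUG: winner-take-all gated). The trial ends the first
#' tick the cursor is within the acquisition radius, or at the time limit.
#'
#' When a trained regression model and an EMG configuration are supplied, the
#' executed activation is instead obtained by synthesizing a 160 ms EMG
#' window from the intended activation and decoding it with the model --- the
#' full signal chain in the loop. This path is used for validation; the
#' default direct path executes the intent with noise.
#'
#' @param subject A [subject_model()].
#' @param strategy A [strategy_config()].
#' @param target A [task_target()].
#' @param seed Integer seed for the trial's noise.
#' @param model Optional [train_regressor()] model.
#' @param emg_cfg Optional [emg_config()] (required with `model`).
#' @param ff_offset Length-2 feedforward offset added to the raw activation
#'   every tick (the adaptation state; default none).
#' @param aim_horizon Proportional-pursuit time constant in seconds: intent
#'   is `clip(error / (gains * aim_horizon))`.
#' @return An object of class `trial_log`: a list with `target`, `strategy`,
#'   `samples` (data frame `t`, `x`, `y`, `raw1`, `raw2`, `gated1`, `gated2`,
#'   plus tone amplitude columns `a500`, `a400`, `a800`, `a900` for AUG),
#'   `outcome` (`"acquired"` or `"timeout"`), `movement_onset_time` and
#'   `duration`.
#' @export
run_trial <- function(subject, strategy, target, seed = 1L, model = NULL,
                      emg_cfg = NULL, ff_offset = c(0, 0),
                      aim_horizon = 0.2) {
  stopifnot(inherits(subject, "subject_model"),
            inherits(strategy, "strategy_config"),
            inherits(target, "task_target"))
  if (!is.null(model) && is.null(emg_cfg)) {
    stop("`emg_cfg` is required when decoding through a regression model",
         call. = FALSE)
  }
  dt <- strategy$tick
  gains <- strategy$gains
  n_max <- floor(target$time_limit / dt + 1e-9)
  delay_ticks <- round(subject$visual_delay / dt)
  raw_mode <- strategy$name == "RAW"
  wlen <- if (!is.null(model)) round(0.160 * emg_cfg$fs) else 0L

  n_rows <- n_max + 1L
  S <- matrix(0, nrow = n_rows, ncol = 7,
              dimnames = list(NULL, c("t", "x", "y", "raw1", "raw2",
                                      "gated1", "gated2")))
  with_seed(seed, {
    pos <- c(0, 0)
    used_rows <- 1L
    outcome <- "timeout"
    intent_buffer <- NULL
    if (!is.null(model)) intent_buffer <- matrix(0, nrow = wlen, ncol = 2)
    k <- 0L
    while (k < n_max) {
      row <- k + 1L
      idx <- max(1L, row - delay_ticks)
      pos_delayed <- c(S[idx, "x"], S[idx, "y"])
      err <- target$center - pos_delayed
      a_star <- clip_activation(err / (gains * aim_horizon))
      leak <- subject$leakage * c(abs(a_star[2]), abs(a_star[1]))
      intended <- clip_activation(a_star + leak + ff_offset +
                                    stats::rnorm(2, sd = subject$sigma_cntl))
      if (is.null(model)) {
        a_raw <- intended
      } else {
        step_n <- round(dt * emg_cfg$fs)
        new_block <- matrix(rep(intended, each = step_n), ncol = 2)
        intent_buffer <- rbind(intent_buffer[-seq_len(step_n), , drop = FALSE],
                               new_block)
        emg <- generate_emg(emg_cfg, intent_buffer,
                            seed = derive_seed(seed, 7000L + k))
        feats <- extract_features(emg, fs = emg_cfg$fs)
        fv <- as.vector(t(as.matrix(feats[, c("mav", "wl", "zc", "ssc")])))
        a_raw <- as.numeric(predict_activation(model, fv))
      }
      used <- if (raw_mode) a_raw else gate_highest_dof(a_raw)
      S[row, ] <- c(k * dt, pos, a_raw, used)
      pos <- pos + gains * used * dt
      k <- k + 1L
      S[k + 1L, c("t", "x", "y")] <- c(k * dt, pos)
      S[k + 1L, 4:7] <- S[row, 4:7]
      used_rows <- k + 1L
      if (sqrt(sum((target$center - pos)^2)) <= target$radius) {
        outcome <- "acquired"
        break
      }
    }
    samples <- as.data.frame(S[seq_len(used_rows), , drop = FALSE])
    if (strategy$name == "AUG") {
      samples$a500 <- pmax(samples$raw1, 0)
      samples$a400 <- pmax(-samples$raw1, 0)
      samples$a800 <- pmax(samples$raw2, 0)
      samples$a900 <- pmax(-samples$raw2, 0)
    }
    moving <- which(abs(samples$raw1) + abs(samples$raw2) > 0.05)
    structure(
      list(target = target, strategy = strategy$name, samples = samples,
           outcome = outcome,
           movement_onset_time = if (length(moving)) samples$t[moving[1]] else NA_real_,
           duration = samples$t[used_rows], seed = seed),
      class = "trial_log"
    )
  })
}

#' Run an experimental block
#'
#' Concatenates [run_trial()] over the block's target list, deriving one seed
#' per trial from the block seed. Adaptation blocks additionally carry the
#' subject's feedforward off-target command across trials: after each trial
#' the subject observes the mean off-target activation of the 100--230 ms
#' feedforward window (plus observation noise) and corrects the next trial's
#' command by `adaptation_gain` times that error, with feedforward execution
#' noise.
#'
#' @param subject A [subject_model()].
#' @param strategy A [strategy_config()].
#' @param spec A [block_spec()] of kind `"training"`, `"adaptation"` or
#'   `"performance"`.
#' @param seed Integer block seed.
#' @param model,emg_cfg Optional decoding path, passed to [run_trial()].
#' @return A list of `trial_log` objects with the target data frame in
#'   `attr(, "targets")`.
#' @export
run_block <- function(subject, strategy, spec, seed = 1L, model = NULL,
                      emg_cfg = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  if (spec$kind == "jnd") {
    stop("use run_jnd_experiment() for the jnd block", call. = FALSE)
  }
  targets <- generate_target_set(spec, seed = seed)
  logs <- vector("list", nrow(targets))
  adaptation <- spec$kind == "adaptation"
  u <- 0
  for (i in seq_len(nrow(targets))) {
    tg <- task_target(c(targets$x[i], targets$y[i]),
                      time_limit = targets$time_limit[i],
                      radius = targets$radius[i])
    off <- if (adaptation) c(0, u) else c(0, 0)
    logs[[i]] <- run_trial(subject, strategy, tg,
                           seed = derive_seed(seed, i),
                           model = model, emg_cfg = emg_cfg,
                           ff_offset = off)
    if (adaptation) {
      # The subject perceives its executed off-target error through its own
      # observation of the whole pre-correction movement: the planned command
      # plus leakage, an averaged controller-noise sample, and sensory
      # observation noise. This channel is distinct from the analyst's
      # 100-230 ms window measurement, which only estimates the same error.
      noise <- with_seed(derive_seed(seed, 5000L + i), stats::rnorm(3))
      e_obs <- subject$leakage + u +
        noise[1] * subject$sigma_cntl / sqrt(8) +
        noise[2] * subject$obs_noise
      u <- u - subject$adaptation_gain * e_obs +
        noise[3] * subject$motor_noise
    }
  }
  attr(logs, "targets") <- targets
  logs
}

#' Write or read a trial log
#'
#' The sample stream goes to one CSV per trial; block-level metadata (target,
#' outcome, timing) goes to a JSON index via [write_block_index()].
#'
#' @param log A `trial_log`.
#' @param path CSV file path.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  utils::write.csv(log$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @param logs List of `trial_log` objects.
#' @param dir Output directory; trial CSVs and `index.json` are written here.
#' @export
write_block_index <- function(logs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  index <- lapply(seq_along(logs), function(i) {
    log <- logs[[i]]
    file <- sprintf("trial_%03d.csv", i)
    write_trial_log(log, file.path(dir, file))
    list(file = file, strategy = log$strategy,
         target = as.list(stats::setNames(log$target$center, c("x", "y"))),
         axis_class = log$target$axis_class,
         time_limit = log$target$time_limit,
         outcome = log$outcome, duration = log$duration)
  })
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
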