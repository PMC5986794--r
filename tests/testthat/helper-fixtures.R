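# Shared fixtures: handcrafted trial logs and quiet subjects.

# A trial log built directly from a sample table, bypassing the simulator,
# for closed-form metric tests.
make_log <- function(t, x, y, raw1 = NULL, raw2 = NULL,
                     target_center = c(20, 0), time_limit = 3,
                     radius = 1.5, outcome = "acquired") {
  n <- length(t)
  samples <- data.frame(
    t = t, x = x, y = y,
    raw1 = if (is.null(raw1)) rep(0, n) else raw1,
    raw2 = if (is.null(raw2)) rep(0, n) else raw2,
    gated1 = 0, gated2 = 0
  )
  structure(
    list(target = task_target(target_center, time_limit = time_limit,
                              radius = radius),
         strategy = "RAW", samples = samples, outcome = outcome,
         movement_onset_time = 0, duration = t[n], seed = 0L),
    class = "trial_log"
  )
}

# Subject with no stochastic behaviour at all.
noiseless_subject <- function(gain = 1) {
  subject_model(adaptation_gain = gain, sigma_cntl = 0, motor_noise = 0,
                obs_noise = 0, leakage = 0)
}

quick_config <- function() {
  cfg <- study_config(n_subjects = 6L)
  cfg$run_training <- FALSE
  cfg
}
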