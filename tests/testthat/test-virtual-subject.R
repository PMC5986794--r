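# Generative model of the virtual subject: EMG synthesis, trial-by-trial
# adaptation behaviour, and the 2IFC ideal observer.

test_that("subject_model validates its parameters", {
  expect_s3_class(subject_model(), "subject_model")
  expect_error(subject_model(sigma_cntl = -0.1), "sigma_cntl")
  expect_error(subject_model(adaptation_gain = 1.6), "adaptation_gain")
  expect_error(subject_model(psychometric_slope = 0), "psychometric_slope")
})

test_that("subject_from_uncertainty applies the Kalman gain relation", {
  s <- subject_from_uncertainty(p_param = 0.1, psychometric_slope = 30,
                                sigma_cntl = 0.025, sigma_sens = 2,
                                stimulus_scale = 90)
  v <- (30 / 90)^2 + (2 / 90)^2 + 0.025^2
  expect_equal(s$adaptation_gain, 0.1 / (0.1 + v))
  # parameterizations are interchangeable
  s2 <- subject_from_uncertainty(p_param = 0.1, r_fb = (30 / 90)^2,
                                 sigma_cntl = 0.025, sigma_sens = 2,
                                 stimulus_scale = 90)
  expect_equal(s2$adaptation_gain, s$adaptation_gain)
  expect_equal(s2$psychometric_slope, 30)
  expect_error(subject_from_uncertainty(0.1), "exactly one")
})

test_that("resting EMG has SD close to the baseline noise", {
  cfg <- emg_config()
  trace <- matrix(0, nrow = 2e4, ncol = 2)
  sig <- generate_emg(cfg, trace, seed = 1)
  expect_equal(dim(sig), c(8L, 2e4L))
  sds <- apply(sig, 1, sd)
  expect_true(all(abs(sds - cfg$baseline_noise) / cfg$baseline_noise < 0.1))
  expect_true(all(abs(rowMeans(sig)) < 0.01))
})

test_that("constant full extension raises SD to baseline + synergy weight", {
  cfg <- emg_config()
  trace <- cbind(rep(1, 2e4), 0)
  sig <- generate_emg(cfg, trace, seed = 2)
  expected <- cfg$baseline_noise + cfg$synergy_matrix["ext", ]
  sds <- apply(sig, 1, sd)
  expect_true(all(abs(sds - expected) / expected < 0.1))
})

test_that("EMG generation is deterministic per seed and validates input", {
  cfg <- emg_config(n_channels = 4)
  trace <- cbind(sin(seq(0, 2 * pi, length.out = 500)), 0)
  expect_identical(generate_emg(cfg, trace, seed = 7),
                   generate_emg(cfg, trace, seed = 7))
  expect_false(identical(generate_emg(cfg, trace, seed = 7),
                         generate_emg(cfg, trace, seed = 8)))
  expect_error(generate_emg(cfg, cbind(trace, 0)), "2 columns")
  expect_error(generate_emg(cfg, trace * 3), "\\[-1, 1\\]")
})

test_that("synergy matrix rows must distinguish the four directions", {
  m <- default_synergy_matrix(8)
  m[2, ] <- m[1, ]
  expect_error(emg_config(synergy_matrix = m), "distinguish")
})

test_that("full compensation cancels the previous error exactly", {
  s <- noiseless_subject(gain = 1)
  ser <- simulate_adaptation_series(s, 10, initial_command = 0.3)
  # command change from trial n to n+1 equals minus the observed error
  expect_equal(diff(ser$command), -ser$error_obs[-10], tolerance = 1e-12)
  # and the error is fully cancelled from trial 2 on
  expect_equal(ser$command[-1], rep(0, 9))
})

test_that("zero adaptation gain leaves the command a motor-noise walk", {
  s <- subject_model(adaptation_gain = 0, sigma_cntl = 0.02,
                     motor_noise = 0.01)
  ser <- simulate_adaptation_series(s, 50, initial_command = 0.2, seed = 3)
  expect_true(all(abs(diff(ser$command)) < 5 * 0.01))
  s0 <- subject_model(adaptation_gain = 0, sigma_cntl = 0.02,
                      motor_noise = 0)
  ser0 <- simulate_adaptation_series(s0, 50, initial_command = 0.2, seed = 3)
  expect_equal(ser0$command, rep(0.2, 50))
})

test_that("the regression estimator recovers a known moderate gain", {
  est <- vapply(1:20, function(i) {
    s <- subject_model(adaptation_gain = 0.5, rng_seed = i)
    estimate_adaptation_rate(simulate_adaptation_series(s, 80, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("2IFC observer sits at chance for zero stimulus and saturates", {
  s <- subject_model(psychometric_slope = 20)
  expect_equal(prob_correct_2ifc(s, 0), 0.5)
  expect_equal(prob_correct_2ifc(s, 1e6), 1)
  draws <- with(list(), {
    set.seed(11)
    replicate(1e4, observe_2ifc(s, 0))
  })
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  expect_true(all(replicate(50, observe_2ifc(s, 1e6))))
})

test_that("empirical accuracy matches the psychometric function at 0.84", {
  s <- subject_model(psychometric_slope = 20)
  level84 <- 20 * sqrt(2) * qnorm(0.84)
  expect_equal(prob_correct_2ifc(s, level84), 0.84, tolerance = 1e-12)
  set.seed(12)
  draws <- replicate(1e4, observe_2ifc(s, level84))
  expect_lt(abs(mean(draws) - 0.84), 0.01)
})

test_that("steady-hold samples carry the controller noise", {
  s <- subject_model(sigma_cntl = 0.1)
  x <- simulate_steady_hold(s, duration = 10, intent = 0.5, seed = 4)
  expect_lt(abs(mean(x) - 0.5), 0.01)
  expect_lt(abs(sd(x) - 0.1), 0.02)
})

test_that("subject and EMG configs round-trip through YAML", {
  s <- subject_model(p_param = 0.07, psychometric_slope = 25,
                     adaptation_gain = 0.4)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_subject_yaml(s, f)
  s2 <- read_subject_yaml(f)
  expect_equal(unclass(s2), unclass(s))

  cfg <- emg_config(n_channels = 4)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_emg_config_yaml(cfg, f2)
  cfg2 <- read_emg_config_yaml(f2)
  expect_equal(cfg2$synergy_matrix, cfg$synergy_matrix,
               ignore_attr = TRUE)
  expect_equal(cfg2$fs, cfg$fs)
})

test_that("signals round-trip through CSV", {
  sig <- matrix(rnorm(40), nrow = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(sig, f)
  expect_equal(read_signal_csv(f), sig, ignore_attr = TRUE,
               tolerance = 1e-12)
})
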