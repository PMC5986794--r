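# The EMG signal chain: Butterworth filtering, windowed Hudgins time-domain
# features, and support vector regression from features to 2-DOF activations.

#' Design the EMG preprocessing filter chain
#'
#' Three cascaded Butterworth stages applied in the fixed order high-pass ->
#' band-stop -> low-pass (offset and motion artifact are removed before band
#' shaping): a 3rd-order 20 Hz high-pass, a 2nd-order 57--63 Hz band-stop for
#' mains interference, and a 5th-order 450 Hz low-pass.
#'
#' @param fs Sampling rate in Hz; must exceed 900 Hz so the 450 Hz cutoff is
#'   below Nyquist (default 1000).
#' @param lp Low-pass cutoff (Hz).
#' @param hp High-pass cutoff (Hz).
#' @param notch Length-2 band-stop edges (Hz).
#' @return An object of class `filter_chain` holding the three stages in
#'   application order.
#' @export
design_filter_chain <- function(fs = 1000, lp = 450, hp = 20,
                                notch = c(57, 63)) {
  stopifnot_scalar(fs, "fs", lower = 0, allow_zero = FALSE)
  if (fs <= 900) stop("`fs` must exceed 900 Hz", call. = FALSE)
  if (fs <= 2 * lp) {
    stop("`fs` too low for the low-pass cutoff (need fs > 2 * lp)",
         call. = FALSE)
  }
  nyq <- fs / 2
  stages <- list(
    hp = signal::butter(3, hp / nyq, type = "high"),
    notch = signal::butter(2, notch / nyq, type = "stop"),
    lp = signal::butter(5, lp / nyq, type = "low")
  )
  for (nm in names(stages)) {
    a <- stages[[nm]]$a
    poles <- polyroot(rev(a))
    if (any(Mod(poles) >= 1)) {
      stop(sprintf("designed %s stage is unstable", nm), call. = FALSE)
    }
  }
  structure(
    list(stages = stages, fs = fs,
         cutoffs = list(lp = lp, hp = hp, notch = notch)),
    class = "filter_chain"
  )
}

#' Evaluate the chain's magnitude response
#'
#' Computes `|H(f)|` of the full cascade (or one stage) directly from the
#' transfer-function polynomials at the unit circle.
#'
#' @param chain A [design_filter_chain()] result.
#' @param f Frequencies in Hz.
#' @param stage `"all"` for the cascade, or one of `"hp"`, `"notch"`, `"lp"`.
#' @return Numeric vector of magnitude gains.
#' @export
filter_chain_response <- function(chain, f, stage = c("all", "hp", "notch", "lp")) {
  stopifnot(inherits(chain, "filter_chain"))
  stage <- match.arg(stage)
  w <- 2 * pi * f / chain$fs
  z <- exp(-1i * w)
  eval_stage <- function(flt) {
    num <- vapply(z, function(zz) sum(flt$b * zz^(seq_along(flt$b) - 1)),
                  complex(1))
    den <- vapply(z, function(zz) sum(flt$a * zz^(seq_along(flt$a) - 1)),
                  complex(1))
    num / den
  }
  h <- if (stage == "all") {
    Reduce(`*`, lapply(chain$stages, eval_stage))
  } else {
    eval_stage(chain$stages[[stage]])
  }
  Mod(h)
}

#' Apply the filter chain to a multichannel signal
#'
#' Stages run in the order high-pass, band-stop, low-pass. The default is
#' causal filtering, honouring the real-time streaming contract; zero-phase
#' forward-backward filtering is available for offline analysis.
#'
#' @param chain A [design_filter_chain()] result.
#' @param x Numeric vector or matrix (channels x samples) sampled at
#'   `chain$fs`.
#' @param zero_phase Use forward-backward filtering (offline only).
#' @return Filtered signal with the same shape as `x`.
#' @export
apply_filters <- function(chain, x, zero_phase = FALSE) {
  stopifnot(inherits(chain, "filter_chain"))
  if (any(!is.finite(x))) {
    stop("input signal contains NaN/Inf", call. = FALSE)
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  out <- xm
  for (ch in seq_len(nrow(xm))) {
    y <- xm[ch, ]
    for (flt in chain$stages) {
      y <- if (zero_phase) {
        as.numeric(signal::filtfilt(flt, y))
      } else {
        as.numeric(signal::filter(flt, y))
      }
    }
    out[ch, ] <- y
  }
  if (vec) drop(out) else out
}

#' Extract Hudgins time-domain features from one window
#'
#' Per channel: mean absolute value (MAV), waveform length (WL), zero
#' crossings (ZC) and slope sign changes (SSC). ZC counts sign changes whose
#' amplitude step exceeds the deadband threshold; SSC counts slope reversals
#' exceeding it.
#'
#' @param window Numeric vector or matrix (channels x samples); must contain
#'   exactly `round(window_ms/1000 * fs)` samples.
#' @param fs Sampling rate in Hz.
#' @param window_ms Window length in ms (default 160).
#' @param zc_ssc_threshold Amplitude deadband for ZC/SSC counting. The
#'   conventional choice is about 3x the baseline noise level; default 0.
#' @return A data frame with one row per channel and columns `mav`, `wl`,
#'   `zc`, `ssc`.
#' @export
extract_features <- function(window, fs = 1000, window_ms = 160,
                             zc_ssc_threshold = 0) {
  vec <- is.null(dim(window))
  wm <- if (vec) matrix(window, nrow = 1) else as.matrix(window)
  expected <- round(window_ms / 1000 * fs)
  if (ncol(wm) != expected) {
    stop(sprintf("window must contain exactly %d samples (got %d)",
                 expected, ncol(wm)), call. = FALSE)
  }
  thr <- zc_ssc_threshold
  one <- function(x) {
    d <- diff(x)
    zc <- sum(x[-length(x)] * x[-1] < 0 & abs(d) >= thr)
    if (length(x) >= 3) {
      mid <- x[2:(length(x) - 1)]
      prev <- x[1:(length(x) - 2)]
      nxt <- x[3:length(x)]
      ssc <- sum((mid - prev) * (mid - nxt) > 0 &
                   (abs(mid - prev) >= thr | abs(mid - nxt) >= thr))
    } else {
      ssc <- 0L
    }
    c(mav = mean(abs(x)), wl = sum(abs(d)), zc = zc, ssc = ssc)
  }
  res <- t(apply(wm, 1, one))
  data.frame(channel = seq_len(nrow(wm)), mav = res[, "mav"],
             wl = res[, "wl"], zc = as.integer(res[, "zc"]),
             ssc = as.integer(res[, "ssc"]))
}

#' Slide a feature window over a signal
#'
#' Windows of `window_ms` advance by `increment_ms` (64 ms for training
#' material, 16 ms for the real-time path). A signal shorter than one window
#' yields zero frames.
#'
#' @param x Numeric vector or matrix (channels x samples).
#' @param fs Sampling rate in Hz.
#' @param window_ms Window length in ms.
#' @param increment_ms Frame increment in ms.
#' @param zc_ssc_threshold Passed to [extract_features()].
#' @return A data frame with one row per frame: `frame_time` (seconds, end of
#'   window) plus `ch<i>_mav`, `ch<i>_wl`, `ch<i>_zc`, `ch<i>_ssc` columns.
#' @export
window_stream <- function(x, fs = 1000, window_ms = 160, increment_ms = 64,
                          zc_ssc_threshold = 0) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  wlen <- round(window_ms / 1000 * fs)
  step <- round(increment_ms / 1000 * fs)
  n <- ncol(xm)
  n_frames <- if (n < wlen) 0L else (n - wlen) %/% step + 1L
  nch <- nrow(xm)
  cols <- as.vector(t(outer(paste0("ch", seq_len(nch)),
                            c("mav", "wl", "zc", "ssc"), paste, sep = "_")))
  if (n_frames == 0L) {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = 1 + length(cols)))
    names(empty) <- c("frame_time", cols)
    return(empty)
  }
  out <- matrix(NA_real_, nrow = n_frames, ncol = length(cols))
  times <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * step + 1L
    feats <- extract_features(xm[, i0:(i0 + wlen - 1L), drop = FALSE],
                              fs = fs, window_ms = window_ms,
                              zc_ssc_threshold = zc_ssc_threshold)
    out[k, ] <- as.vector(t(as.matrix(feats[, c("mav", "wl", "zc", "ssc")])))
    times[k] <- (i0 + wlen - 1L) / fs
  }
  df <- data.frame(frame_time = times, out)
  names(df) <- c("frame_time", cols)
  df
}

#' Train the feature-to-activation regression model
#'
#' Fits one epsilon support vector regression (RBF kernel) per degree of
#' freedom, mapping a frame's time-domain features to the signed activation.
#' Training material is prompted tracking of a sinusoidal velocity profile
#' (plus rest), generated synthetically.
#'
#' @param frames Feature data frame from [window_stream()] (the `frame_time`
#'   column is ignored if present).
#' @param targets Numeric matrix (n_frames x 2) of signed DOF activations.
#' @param cost,epsilon,gamma SVR hyperparameters; fixed defaults are part of
#'   the experiment configuration (`gamma = NULL` uses `1/n_features`).
#' @return An object of class `activation_regressor`.
#' @export
train_regressor <- function(frames, targets, cost = 4, epsilon = 0.01,
                            gamma = NULL) {
  feats <- frames[, setdiff(names(frames), "frame_time"), drop = FALSE]
  targets <- as.matrix(targets)
  if (ncol(targets) != 2L) stop("`targets` must have 2 columns", call. = FALSE)
  if (nrow(feats) != nrow(targets)) {
    stop("`frames` and `targets` must have the same number of rows",
         call. = FALSE)
  }
  if (nrow(feats) < 50L) {
    stop("need at least 50 training pairs", call. = FALSE)
  }
  if (any(apply(targets, 2, stats::sd) < 1e-12)) {
    stop("degenerate (constant) targets", call. = FALSE)
  }
  xm <- as.matrix(feats)
  if (is.null(gamma)) gamma <- 1 / ncol(xm)
  models <- lapply(1:2, function(d) {
    e1071::svm(x = xm, y = targets[, d], type = "eps-regression",
               kernel = "radial", cost = cost, epsilon = epsilon,
               gamma = gamma, scale = TRUE)
  })
  structure(
    list(models = models, feature_names = colnames(feats),
         n_features = ncol(xm),
         hyper = list(cost = cost, epsilon = epsilon, gamma = gamma),
         version = "audiomyo-regressor/1"),
    class = "activation_regressor"
  )
}

#' Predict 2-DOF activation from feature frames
#'
#' @param model An [train_regressor()] result.
#' @param frames Feature data frame (or matrix) with the same feature columns
#'   as at training time.
#' @return Numeric matrix (n_frames x 2) of activations clipped to `[-1, 1]`.
#' @export
predict_activation <- function(model, frames) {
  stopifnot(inherits(model, "activation_regressor"))
  if (is.data.frame(frames)) {
    frames <- frames[, setdiff(names(frames), "frame_time"), drop = FALSE]
    if (!all(model$feature_names %in% names(frames))) {
      stop("frame feature columns do not match the trained model",
           call. = FALSE)
    }
    frames <- as.matrix(frames[, model$feature_names, drop = FALSE])
  } else {
    frames <- matrix(frames, ncol = model$n_features)
  }
  if (ncol(frames) != model$n_features) {
    stop("frame feature count does not match the trained model",
         call. = FALSE)
  }
  preds <- vapply(model$models,
                  function(m) as.numeric(stats::predict(m, frames)),
                  numeric(nrow(frames)))
  clip_activation(matrix(preds, ncol = 2,
                         dimnames = list(NULL, c("dof1", "dof2"))))
}

#' Serialize a trained regressor with a versioned header
#'
#' The model is written as a base R serialization wrapped in a small header
#' identifying the format version, so stale models are rejected on read.
#'
#' @param model An `activation_regressor`.
#' @param path File path.
#' @export
write_regressor <- function(model, path) {
  stopifnot(inherits(model, "activation_regressor"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_regressor
#' @export
read_regressor <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "activation_regressor") ||
      !identical(model$version, "audiomyo-regressor/1")) {
    stop("not a recognized activation_regressor file", call. = FALSE)
  }
  model
}

#' Sinusoidal prompted training profile
#'
#' The prompted activation used to collect regression training data: after a
#' 1 s rest, each DOF in turn follows full-range sinusoidal cycles while the
#' other rests, ending with a rest segment so the model learns the zero.
#'
#' @param fs Sampling rate in Hz.
#' @param cycle_s Seconds per sinusoidal cycle.
#' @param n_cycles Cycles per DOF.
#' @param rest_s Rest duration (seconds) at start, between DOFs, and at end.
#' @return Numeric matrix (n_samples x 2) of activations in `[-1, 1]`.
#' @export
training_profile <- function(fs = 1000, cycle_s = 2, n_cycles = 4,
                             rest_s = 1) {
  rest <- matrix(0, nrow = round(rest_s * fs), ncol = 2)
  t_act <- seq_len(round(n_cycles * cycle_s * fs)) / fs
  s <- sin(2 * pi * t_act / cycle_s)
  dof1 <- cbind(s, 0)
  dof2 <- cbind(0, s)
  rbind(rest, dof1, rest, dof2, rest)
}

#' Align activation targets with feature frames
#'
#' Returns the mean activation over each sliding window produced by
#' [window_stream()] with the same windowing settings, for use as regression
#' targets.
#'
#' @param activation_trace Numeric matrix (n_samples x 2).
#' @param fs Sampling rate in Hz.
#' @param window_ms,increment_ms Windowing settings.
#' @return Numeric matrix (n_frames x 2).
#' @export
window_targets <- function(activation_trace, fs = 1000, window_ms = 160,
                           increment_ms = 64) {
  am <- as.matrix(activation_trace)
  wlen <- round(window_ms / 1000 * fs)
  step <- round(increment_ms / 1000 * fs)
  n <- nrow(am)
  n_frames <- if (n < wlen) 0L else (n - wlen) %/% step + 1L
  out <- matrix(NA_real_, nrow = n_frames, ncol = 2)
  for (k in seq_len(n_frames)) {
    i0 <- (k - 1L) * step + 1L
    out[k, ] <- colMeans(am[i0:(i0 + wlen - 1L), , drop = FALSE])
  }
  colnames(out) <- c("dof1", "dof2")
  out
}
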