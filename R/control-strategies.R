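# The three control strategies. RAW maps both DOF activations to cursor
# velocity simultaneously; FLT gates motion to the highest-activated DOF
# (winner-take-all, classifier-like sequential control); AUG moves like FLT
# but sonifies the full raw activation vector through a 4-tone audio map.

#' Strategy configuration
#'
#' @param name One of `"RAW"`, `"FLT"`, `"AUG"`.
#' @param gains Cursor velocity gains in pixels/s per unit activation, one per
#'   DOF (default 20 pixels/s each).
#' @param tick Control tick in seconds (default 0.016, i.e. the 16 ms
#'   real-time output period).
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(name = c("RAW", "FLT", "AUG"),
                            gains = c(20, 20), tick = 0.016) {
  name <- match.arg(name)
  if (length(gains) != 2L || any(!is.finite(gains)) || any(gains <= 0)) {
    stop("`gains` must be two positive numbers", call. = FALSE)
  }
  stopifnot_scalar(tick, "tick", lower = 0, allow_zero = FALSE)
  structure(list(name = name, gains = as.numeric(gains), tick = tick),
            class = "strategy_config")
}

#' Winner-take-all DOF gating
#'
#' Keeps the DOF with the larger absolute activation and zeroes the other;
#' exact ties go to DOF 1 (the extension/flexion axis), a deterministic rule
#' for a probability-zero event under continuous activations. Used by the FLT
#' and AUG strategies for cursor motion. Idempotent.
#'
#' @param a Numeric length-2 signed activation vector.
#' @return The gated activation vector.
#' @export
gate_highest_dof <- function(a) {
  stopifnot(length(a) == 2L, all(is.finite(a)))
  if (abs(a[1]) >= abs(a[2])) c(a[1], 0) else c(0, a[2])
}

#' Map a raw activation vector to audio feedback tones
#'
#' Each active movement direction emits one tone: wrist extension (+DOF1)
#' at 500 Hz, flexion (-DOF1) at 400 Hz, abduction (+DOF2, screen up) at
#' 800 Hz and adduction (-DOF2) at 900 Hz. Tone amplitude equals the
#' magnitude of that direction's activation (linear in the regression
#' output); inactive directions emit nothing.
#'
#' @param a Numeric length-2 signed raw (ungated) activation vector.
#' @param freq_map Named numeric vector giving the tone frequency per
#'   direction; exposed so the extension/flexion vs abduction/adduction
#'   assignment can be reconfigured.
#' @return A data frame with columns `direction`, `frequency` (Hz) and
#'   `amplitude` in `[0, 1]`, one row per active direction (zero rows at
#'   rest).
#' @export
audio_map <- function(a, freq_map = c(ext = 500, flex = 400,
                                      abd = 800, add = 900)) {
  stopifnot(length(a) == 2L, all(is.finite(a)))
  amps <- c(ext = max(a[1], 0), flex = max(-a[1], 0),
            abd = max(a[2], 0), add = max(-a[2], 0))
  active <- amps > 0
  data.frame(direction = names(amps)[active],
             frequency = unname(freq_map[names(amps)[active]]),
             amplitude = unname(amps[active]),
             row.names = NULL)
}

#' Advance the cursor by one control tick
#'
#' RAW integrates both DOFs simultaneously (`pos + gains * a * dt`); FLT and
#' AUG integrate the winner-take-all gated activation. AUG additionally emits
#' the audio frame for the *raw* activation, so the feedback channel carries
#' the simultaneous information that the motion channel discards.
#'
#' @param pos Numeric length-2 screen position (pixels; origin at screen
#'   center, x rightward = extension, y upward = abduction).
#' @param a Numeric length-2 raw activation vector.
#' @param cfg A [strategy_config()].
#' @param dt Time step in seconds (normally `cfg$tick`).
#' @return A list with `pos` (new position), `gated` (activation used for
#'   motion) and `audio` (an [audio_map()] frame for AUG, otherwise `NULL`).
#' @export
cursor_step <- function(pos, a, cfg, dt = cfg$tick) {
  stopifnot(inherits(cfg, "strategy_config"), length(pos) == 2L)
  used <- if (cfg$name == "RAW") a else gate_highest_dof(a)
  list(
    pos = pos + cfg$gains * used * dt,
    gated = used,
    audio = if (cfg$name == "AUG") audio_map(a) else NULL
  )
}
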