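# Internal helpers: seeding, clipping.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do not
#' disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream derivation. Multipliers are kept small so the
# arithmetic stays exact in double precision; result is always < 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Clip activations to the valid range [-1, 1].
clip_activation <- function(x, lo = -1, hi = 1) {
  pmin(pmax(x, lo), hi)
}

stopifnot_scalar <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || (!allow_zero && x == lower)) {
    stop(sprintf("`%s` must be %s %s", name, if (allow_zero) ">=" else ">", lower),
         call. = FALSE)
  }
  invisible(x)
}
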