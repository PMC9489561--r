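# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Round half away from zero (so 10.5 -> 11, -10.5 -> -11), unlike round()'s
# banker's rounding.  Used for reporting temporal resolution in integer ms.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_param("`", name, "` must be > 0")
  if (nonnegative && x < 0) stop_param("`", name, "` must be >= 0")
  invisible(as.numeric(x))
}
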