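# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = env) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = env)
      } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    }, add = TRUE)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  force(code)
}

# n child seeds derived reproducibly from one parent seed; always < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_band <- function(band, nyquist = NULL, what = "band") {
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band))) {
    stop(what, " must be two finite numbers (low, high)", call. = FALSE)
  }
  if (band[1] <= 0 || band[1] >= band[2]) {
    stop(what, " must satisfy 0 < low < high (got ",
         band[1], ", ", band[2], ")", call. = FALSE)
  }
  if (!is.null(nyquist) && band[2] >= nyquist) {
    stop(what, " upper edge ", band[2], " Hz must lie below the Nyquist ",
         "frequency ", nyquist, " Hz", call. = FALSE)
  }
  invisible(band)
}
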