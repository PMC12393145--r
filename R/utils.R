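# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards (seed = NULL leaves the RNG untouched).  Relies on lazy
# evaluation of `code`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Deterministic per-stage substream seed derived from a top-level seed.
# All arithmetic stays below 2^53 so the modular reduction is exact, and
# the result fits a 32-bit integer.
substream <- function(seed, label, k = 0L) {
  u <- utf8ToInt(as.character(label))
  h <- sum(u * seq_along(u)) %% 104729
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69069 + h * 40503 + as.numeric(k) * 7919) %% 2147483629)
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < lower)
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
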