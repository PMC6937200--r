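# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible 32-bit sub-seed from a master seed and a string key.
# Keyed sub-streams keep per-station draws stable under station re-ordering.
sub_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * (31^(seq_along(utf8ToInt(as.character(key))) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
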