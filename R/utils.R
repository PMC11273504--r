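# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

assert_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (x < lower) stop_field(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

# Deterministic per-animal substream seed. Animals are numbered in config
# order, so appending a group never perturbs draws for earlier animals.
heifer_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647) * 48271 + index * 1009) %% 2147483647L
}

# Run `expr` without clobbering the caller's RNG state.
with_local_rng <- function(expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
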