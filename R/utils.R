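# internal validation helpers

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

# conditions of the self-projection-in-time task, in canonical order
task_conditions <- function() c("Past", "Now", "Future")

as_condition <- function(x) {
  factor(as.character(x), levels = task_conditions())
}

# run body under a fixed RNG state when seed is given, leaving the global
# RNG untouched; with seed = NULL the global stream is used
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
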