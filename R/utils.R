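#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG state. All seeded operations in the package funnel through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive a stage seed from a global seed. Kept below 2^31 - 1 so the result
# is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count_arg <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < min) {
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_invalid("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max))
  }
  as.numeric(x)
}
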