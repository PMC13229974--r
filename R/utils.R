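# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed means "use the current RNG stream".
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

check_probability <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", name))
  }
  if (open) {
    if (any(x <= 0 | x >= 1)) {
      abort(sprintf("`%s` must lie strictly inside (0, 1).", name))
    }
  } else if (any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

# ceiling/floor with a small fuzz so grid thresholds such as 0.55 * n do not
# tip over an exact integer through floating-point representation error.
fuzzy_ceiling <- function(x, eps = 1e-9) as.integer(ceiling(x - eps))
fuzzy_floor <- function(x, eps = 1e-9) as.integer(floor(x + eps))
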