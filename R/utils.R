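# Internal helpers: seed derivation and argument checks.

# Derive a child seed from a master seed and an integer tag. Plain LCG-style
# mixing; results stay strictly below 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647
  s <- (abs(seed) %% m)
  as.integer((s * 48271 + 7919 * (abs(tag) %% m)) %% m)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. A NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(
      sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper),
      class = "afuq_parameter_error"
    )
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, 0, 1)

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
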