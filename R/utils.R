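# Internal helpers: condition constructors and small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("imugrf_invalid_argument", "imugrf_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("imugrf_format_error", "imugrf_error")))
}

abort_sync <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("imugrf_sync_failure", "imugrf_error")))
}

abort_training <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("imugrf_training_failure", "imugrf_error")))
}

# standard gravitational acceleration used for BW normalization (m/s^2)
GRAVITY <- 9.81

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid("`%s` must be a single finite number", name)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort_invalid("`%s` = %g is outside its valid range [%g, %g]",
                  name, x, lower, upper)
  invisible(x)
}

# Derive a child RNG seed from a base seed; stays inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483629)
}
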