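# Shared internal helpers: classed conditions and seeded RNG scoping.

abort_ll <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "listlearn_error"), ...)
}

abort_validation <- function(message, ...) abort_ll(message, "ll_error_validation", ...)
abort_format     <- function(message, ...) abort_ll(message, "ll_error_format", ...)
abort_argument   <- function(message, ...) abort_ll(message, "ll_error_argument", ...)
abort_capacity   <- function(message, ...) abort_ll(message, "ll_error_capacity", ...)
abort_infeasible <- function(message, ...) abort_ll(message, "ll_error_infeasible", ...)
abort_protocol   <- function(message, ...) abort_ll(message, "ll_error_protocol", ...)
abort_data       <- function(message, ...) abort_ll(message, "ll_error_data", ...)
abort_state      <- function(message, ...) abort_ll(message, "ll_error_state", ...)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported stochastic operations route through this.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

check_seed <- function(seed) {
  if (length(seed) != 1 || is.na(seed) || !is.numeric(seed)) {
    abort_argument("`seed` must be a single integer.")
  }
  as.integer(seed)
}

# Deterministic per-unit substream seeds derived from a master seed.
# Kept below 2^31 so they remain valid R integers.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647L)
}

`%||%` <- rlang::`%||%`

clip01 <- function(x) pmin(1, pmax(0, x))
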