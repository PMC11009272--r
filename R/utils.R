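# Shared argument checks. All user-facing errors go through rlang::abort()
# with a class so tests can assert on them.

stop_param <- function(msg, field = NULL) {
  abort(msg, class = "nitribalance_parameter_error", field = field)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "nitribalance_format_error", ...)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_param(sprintf("`%s` must be a single non-missing number.", field),
               field = field)
  }
  if (x < lower || x > upper || (!allow_zero_lower && x == lower)) {
    stop_param(sprintf("`%s` = %g is outside its allowed range.", field, x),
               field = field)
  }
  invisible(x)
}

check_strictly_increasing <- function(x, field) {
  if (length(x) < 1L || anyNA(x) || any(diff(x) <= 0)) {
    stop_param(sprintf("`%s` must be strictly increasing with no missing values.",
                       field), field = field)
  }
  invisible(x)
}

# Derive a per-stage/per-core seed from a root seed, staying within 32-bit
# integer range so set.seed() accepts it.
derive_seed <- function(root_seed, index) {
  as.integer((as.double(root_seed) * 1009 + index * 9973) %% 2147483647)
}
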