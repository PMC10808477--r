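# Shared small helpers.

# Round half up to `digits` decimal places (display rounding for percentages;
# base round() is round-half-even, which would turn e.g. 0.25 into 0.2).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  out <- floor(abs(x) * p + 0.5) / p * sign(x)
  out[is.na(x)] <- NA_real_
  out
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_masscnv <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "masscnv_error"), ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
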