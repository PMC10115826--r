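# Classed conditions so callers can distinguish failure modes programmatically.

abort_oc <- function(class, message) {
  stop(errorCondition(message, class = c(class, "orthocircuit_error")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_oc("invalid_parameter_error",
             sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_oc("invalid_parameter_error",
             sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}
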