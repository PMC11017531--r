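# Classed conditions so callers can distinguish bad input from degenerate
# statistics. All errors inherit from "prevcal_error".

stop_prevcal <- function(message, class) {
  stop(structure(
    class = c(class, "prevcal_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_validation <- function(message) {
  stop_prevcal(message, "prevcal_validation_error")
}

# an operation consumed an undefined (NA-marked) statistic
abort_undefined <- function(message) {
  stop_prevcal(message, "prevcal_undefined_error")
}

# prevalence endpoint where the limit itself is not defined
abort_undefined_limit <- function(message) {
  stop_prevcal(message, "prevcal_undefined_limit_error")
}

abort_io <- function(message) {
  stop_prevcal(message, "prevcal_io_error")
}

check_number <- function(x, name, lo = -Inf, hi = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    abort_validation(sprintf("`%s` must be a single number", name))
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    abort_validation(sprintf("`%s` must not be NA", name))
  }
  if (!is.finite(x)) abort_validation(sprintf("`%s` must be finite", name))
  if (x < lo || x > hi) {
    abort_validation(sprintf("`%s` must be in [%s, %s], got %s", name, lo, hi, x))
  }
  invisible(x)
}
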