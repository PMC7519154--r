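# Classed conditions so callers (and the CLI) can react per failure mode.
scyf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "scyf_error"), call = call))
}

check_numeric_vector <- function(x, what = "x", min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len)
    scyf_stop(sprintf("`%s` must be a numeric vector of length >= %d", what, min_len),
              "scyf_invalid_input")
  if (anyNA(x) || any(!is.finite(x)))
    scyf_stop(sprintf("`%s` contains non-finite samples", what), "scyf_invalid_input")
  invisible(x)
}

is_power_of_two <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}
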