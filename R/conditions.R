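# Classed conditions so callers (and tests) can distinguish failure modes.

tdeg_error <- function(kind, msg, ...) {
  stop(errorCondition(
    sprintf(msg, ...),
    class = c(paste0("tdeg_", kind), "tdeg_error")
  ))
}

# Parse errors name the offending record of a 3ddose file.
parse_error <- function(kind, msg, ...) {
  stop(errorCondition(
    sprintf(msg, ...),
    class = c(paste0("tdeg_parse_", kind), "tdeg_parse_error", "tdeg_error")
  ))
}
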