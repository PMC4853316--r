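# Classed conditions so callers (and the command-line wrapper) can map
# failures onto stable exit codes: validation errors -> 1, data-format
# errors -> 2.

.txpValidationError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("txpValidationError", "txpError"),
                      call = call))
}

.txpFormatError <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("txpFormatError", "txpError"),
                      call = call))
}
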