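# Classed conditions so the CLI can map failures to exit codes:
# configuration error -> 2, data error -> 3, numerical failure -> 4.

stopConfig <- function(fmt, ...) {
  stop(structure(class = c("prsConfigError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stopData <- function(fmt, ...) {
  stop(structure(class = c("prsDataError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stopNumeric <- function(fmt, ...) {
  stop(structure(class = c("prsNumericError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
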