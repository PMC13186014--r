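# Structured error conditions so callers (and the CLI) can distinguish
# bad clinical input from bad files.

costas_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "costas_error", "error")))
}

abort_validation <- function(message, field = NULL) {
  costas_abort(message, "costas_validation_error", field = field)
}

abort_io <- function(message) {
  costas_abort(message, "costas_io_error")
}
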