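# Classed conditions so callers (and the command-line wrapper) can map
# failure kinds to exit codes without string matching.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dasnet_config_error", "dasnet_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dasnet_data_error", "dasnet_error")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dasnet_numeric_error", "dasnet_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
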