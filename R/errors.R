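# Condition helpers: input errors (bad data) vs configuration errors
# (bad parameters). The CLI maps these to exit codes 1 and 2.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stseg_input_error", "stseg_error")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stseg_config_error", "stseg_error")))
}

stop_fit <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("stseg_fit_error", "stseg_error")))
}
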