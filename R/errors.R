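# Classed conditions: validation errors are data problems (bad rows, bad
# values); configuration errors are caller problems (bad arguments, wrong
# shapes agreed upfront). Tests match on the class.

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hazardnet_validation_error")
}

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hazardnet_config_error")
}
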