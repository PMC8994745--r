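rst_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "rst_error"), ...)
}

rst_warn <- function(message, class = "rst_warning") {
  rlang::warn(message, class = class)
}
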