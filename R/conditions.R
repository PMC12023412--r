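# Typed conditions. Every user-facing failure carries a subclass of
# "mbc_error" so callers (and the CLI) can distinguish usage problems from
# data problems without parsing messages.

mbc_stop <- function(class, msg, ..., call. = FALSE) {
  stop(structure(
    class = c(class, "mbc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

#' @noRd
is_mbc_error <- function(x) inherits(x, "mbc_error")
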