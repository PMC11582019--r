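## Typed conditions. Every validation failure in the package signals a
## condition whose class carries the error kind, so callers (and tests) can
## dispatch on e.g. "DuplicateIdError" rather than matching message text.

rtStop <- function(class, fmt, ..., call. = FALSE) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "rtError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

rtWarn <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  warning(structure(
    class = c(class, "rtWarning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}
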