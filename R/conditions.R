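# Classed conditions so callers (and the CLI) can dispatch on failure mode.

stop_dbso <- function(subclass, message, ..., call = sys.call(-1)) {
  cnd <- structure(
    class = c(paste0("dbsorient_error_", subclass), "dbsorient_error",
              "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

warn_dbso <- function(subclass, message, ...) {
  cnd <- structure(
    class = c(paste0("dbsorient_warning_", subclass), "dbsorient_warning",
              "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  warning(cnd)
}
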