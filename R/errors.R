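# Classed conditions so callers (and tests) can trap specific domain failures.
# Every error is also a "dichokey_error" for blanket handling in the CLI.

dk_stop <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "dichokey_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

dk_unknown_token <- function(token, where = NULL) {
  loc <- if (is.null(where)) "" else paste0(" (at ", where, ")")
  dk_stop("dk_unknown_token_error",
          sprintf("unrecognized state token %s%s", encodeString(token, quote = '"'), loc),
          token = token, where = where)
}
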