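## Structured error conditions: every error carries a machine-readable code
## (class mkm_error_<code>) so the CLI and tests can dispatch on it.
stop_mkm <- function(code, message, ...) {
  cond <- structure(
    class = c(paste0("mkm_error_", code), "mkm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), code = code, ...))
  stop(cond)
}

mkm_error_code <- function(cond) {
  if (inherits(cond, "mkm_error")) cond$code else "internal"
}
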