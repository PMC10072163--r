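# Classed conditions so callers (and the CLI) can map failure modes to
# exit codes without string-matching messages.

stop_metpoly <- function(msg, subclass = character()) {
  cond <- structure(
    class = c(subclass, "metpoly_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

stop_validation <- function(msg) stop_metpoly(msg, "metpoly_validation_error")

stop_format <- function(msg) {
  stop_metpoly(msg, c("metpoly_format_error", "metpoly_validation_error"))
}

stop_qc <- function(msg) stop_metpoly(msg, "metpoly_qc_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
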