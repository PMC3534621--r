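# Classed conditions so callers (and the CLI) can map failures to exit codes.

sgt_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "sgt_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

usage_error      <- function(msg) sgt_error(msg, "sgt_usage_error")
validation_error <- function(msg) sgt_error(msg, "sgt_validation_error")
parse_error      <- function(msg) sgt_error(msg, "sgt_parse_error")
io_error         <- function(msg) sgt_error(msg, "sgt_io_error")
fit_error        <- function(msg) sgt_error(msg, "sgt_fit_error")
range_error      <- function(msg) sgt_error(msg, "sgt_range_error")
estimation_error <- function(msg) sgt_error(msg, "sgt_estimation_error")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
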