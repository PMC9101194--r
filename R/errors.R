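# Typed condition helpers. Every user-facing failure carries a condition
# class so callers (and the CLI) can map it to an exit code:
#   pf_parse_error / pf_invalid_sample / pf_parameter_error  -> input problems
#   pf_degenerate_sample / pf_degenerate_fuzzy / pf_numerical_error -> numerics

pf_stop <- function(class, message, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "pfindex_error"),
                      call = call))
}

#' @keywords internal
pf_check <- function(ok, class, message) {
  if (!isTRUE(ok)) pf_stop(class, message, call = sys.call(-1))
  invisible(TRUE)
}
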