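# Classed conditions so callers (and the CLI) can react to specific failures.

osv_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "outsvd_error"),
                      call = sys.call(-1)))
}
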