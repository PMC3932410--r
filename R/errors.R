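# Classed error helpers so callers can distinguish failure modes.

df_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dynform_error"), call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
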