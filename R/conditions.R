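# Classed error conditions so callers and tests can discriminate failure modes.

zd_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("zoodrift_", class), "zoodrift_error"),
                      call = call))
}

AXIS_NAMES <- c("x", "y", "z")
COMP_NAMES <- c("u", "v", "w")

`%||%` <- function(a, b) if (is.null(a)) b else a
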