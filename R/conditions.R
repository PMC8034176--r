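# Condition helpers: three distinct error classes so callers (and the config
# reader's tests) can tell a parse failure from a missing section from a
# violated domain invariant.

stop_with <- function(class, ...) {
  stop(structure(
    class = c(class, "sccapacity_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1L))))
}

stop_invariant <- function(...) stop_with("sccapacity_invariant_error", ...)
stop_config    <- function(...) stop_with("sccapacity_config_error", ...)
stop_parse     <- function(...) stop_with("sccapacity_parse_error", ...)
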