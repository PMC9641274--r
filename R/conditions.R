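# Structured error conditions.  Every user-facing failure mode carries a
# condition class so callers (and the CLI) can distinguish configuration
# mistakes from malformed data and from numerical degeneracies.

thz_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "thzburn_error"), call = call))
}

config_error    <- function(msg) thz_error(msg, "thzburn_config_error")
format_error    <- function(msg) thz_error(msg, "thzburn_format_error")
integrity_error <- function(msg) thz_error(msg, "thzburn_integrity_error")
label_error     <- function(msg) thz_error(msg, "thzburn_label_error")
degenerate_error <- function(msg) thz_error(msg, "thzburn_degenerate_error")
reference_error <- function(msg) thz_error(msg, "thzburn_reference_error")
gating_error    <- function(msg) thz_error(msg, "thzburn_gating_error")
partition_error <- function(msg) thz_error(msg, "thzburn_partition_error")
metric_error    <- function(msg) thz_error(msg, "thzburn_metric_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
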