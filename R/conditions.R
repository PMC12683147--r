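# Structured conditions so callers (and tests) can dispatch on error class
# rather than matching message text.

sensmap_abort <- function(msg, class, call = sys.call(-1L)) {
  stop(errorCondition(msg, class = c(class, "sensmap_error"), call = call))
}

abort_format <- function(msg) sensmap_abort(msg, "sensmap_format_error")
abort_parse <- function(msg) sensmap_abort(msg, "sensmap_parse_error")
abort_validation <- function(msg) sensmap_abort(msg, "sensmap_validation_error")
abort_usage <- function(msg) sensmap_abort(msg, "sensmap_usage_error")
abort_insufficient <- function(msg) sensmap_abort(msg, "sensmap_insufficient_data_error")
abort_incomplete_panel <- function(msg) sensmap_abort(msg, "sensmap_incomplete_panel_error")
abort_budget <- function(msg) sensmap_abort(msg, "sensmap_budget_error")
abort_degenerate <- function(msg) sensmap_abort(msg, "sensmap_degenerate_error")
abort_io <- function(msg) sensmap_abort(msg, "sensmap_io_error")
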