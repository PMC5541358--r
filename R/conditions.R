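# Classed error conditions so callers (and tests) can distinguish failure
# modes without matching message text.

saxs_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "saxs_error"),
                      call = call))
}

saxs_validation_error <- function(message) saxs_abort(message, "saxs_validation_error")
saxs_io_error         <- function(message) saxs_abort(message, "saxs_io_error")
saxs_format_error     <- function(message) saxs_abort(message, "saxs_format_error")
saxs_geometry_error   <- function(message) saxs_abort(message, "saxs_geometry_error")
saxs_empty_data_error <- function(message) saxs_abort(message, "saxs_empty_data_error")
saxs_peak_error       <- function(message) saxs_abort(message, "saxs_peak_error")
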