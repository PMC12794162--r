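# Classed conditions so callers (and tests) can distinguish configuration,
# validation, geometry, numeric and I/O failures.

pmms_abort <- function(message, type, ...) {
  rlang::abort(message, class = c(paste0("pmms_", type, "_error"), "pmms_error"), ...)
}

stop_validation  <- function(message, ...) pmms_abort(message, "validation", ...)
stop_parse       <- function(message, ...) pmms_abort(message, "parse", ...)
stop_config      <- function(message, ...) pmms_abort(message, "config", ...)
stop_geometry    <- function(message, ...) pmms_abort(message, "geometry", ...)
stop_numeric     <- function(message, ...) pmms_abort(message, "numeric", ...)
stop_selection   <- function(message, ...) pmms_abort(message, "selection", ...)
stop_range       <- function(message, ...) pmms_abort(message, "range", ...)
stop_feasibility <- function(message, ...) pmms_abort(message, "feasibility", ...)
stop_degenerate  <- function(message, ...) pmms_abort(message, "degenerate", ...)
stop_io          <- function(message, ...) pmms_abort(message, "io", ...)
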