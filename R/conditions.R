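## Structured conditions.  Every error photonsim raises carries a specific
## class plus the family "photonsim_error" so callers (and the CLI exit-code
## mapper) can dispatch without string matching.

ps_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "photonsim_error"), ...)
}

ps_layout_error <- function(message, ...) {
  ps_abort(message, c("photonsim_layout_error", "photonsim_format_error"), ...)
}

ps_format_error <- function(message, ...) {
  ps_abort(message, "photonsim_format_error", ...)
}

ps_stack_error <- function(message, ...) {
  ps_abort(message, c("photonsim_stack_error", "photonsim_format_error"), ...)
}

ps_io_error <- function(message, ...) {
  ps_abort(message, c("photonsim_io_error", "photonsim_format_error"), ...)
}

ps_schema_error <- function(message, ...) {
  ps_abort(message, c("photonsim_schema_error", "photonsim_format_error"), ...)
}

ps_insufficient_levels_error <- function(message, ...) {
  ps_abort(message,
           c("photonsim_insufficient_levels_error", "photonsim_calibration_error"),
           ...)
}

ps_calibration_error <- function(message, ...) {
  ps_abort(message, "photonsim_calibration_error", ...)
}

ps_empty_selection_error <- function(message, ...) {
  ps_abort(message,
           c("photonsim_empty_selection_error", "photonsim_calibration_error"), ...)
}

ps_implausible_contrast_error <- function(message, ...) {
  ps_abort(message,
           c("photonsim_implausible_contrast_error", "photonsim_calibration_error"),
           ...)
}

ps_degenerate_input_error <- function(message, ...) {
  ps_abort(message,
           c("photonsim_degenerate_input_error", "photonsim_calibration_error"), ...)
}

ps_parameter_error <- function(message, ...) {
  ps_abort(message, c("photonsim_parameter_error", "photonsim_usage_error"), ...)
}

ps_protocol_error <- function(message, ...) {
  ps_abort(message, c("photonsim_protocol_error", "photonsim_usage_error"), ...)
}

ps_usage_error <- function(message, ...) {
  ps_abort(message, "photonsim_usage_error", ...)
}

ps_saturation_warning <- function(message, ...) {
  rlang::warn(message, class = c("photonsim_saturation_warning", "photonsim_warning"),
              ...)
}
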