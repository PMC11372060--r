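#' Signal a classed error
#'
#' All package errors carry a subclass of `cyanorhythm_error` so callers can
#' condition on the failure mode (`grid_error`, `shape_error`, `parse_error`,
#' `param_error`, `spec_error`, `fit_error`, `feature_error`, `sample_error`,
#' `domain_error`, `key_error`, `config_error`).
#'
#' @param message error message.
#' @param class character subclass, e.g. `"grid_error"`.
#' @param ... fields stored on the condition object.
#' @keywords internal
#' @noRd
cr_abort <- function(message, class, ...) {
  stop(errorCondition(
    message,
    ...,
    class = c(class, "cyanorhythm_error", "error", "condition")
  ))
}

cr_warn <- function(message, class) {
  warning(warningCondition(
    message,
    class = c(class, "cyanorhythm_warning", "warning", "condition")
  ))
}

# shared validation helper: scalar finite number
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
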