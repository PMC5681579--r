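# Internal error helpers. Validation problems (bad user input, malformed
# files) are classed separately from numerical failures so the CLI can map
# them to distinct exit codes.

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "olfactomap_validation_error")
}

stop_numerical <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "olfactomap_numerical_error")
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_validation("`%s` must be a single positive finite number.", name)
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
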