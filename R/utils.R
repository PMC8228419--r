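#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish bad inputs from bad state
# from bad configuration.
mr_abort <- function(msg, class = "mrwald_input_error", ...) {
  stop(structure(
    class = c(class, "mrwald_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

mr_input_error  <- function(msg, ...) mr_abort(msg, "mrwald_input_error", ...)
mr_config_error <- function(msg, ...) mr_abort(msg, "mrwald_config_error", ...)
mr_state_error  <- function(msg, ...) mr_abort(msg, "mrwald_state_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report-layer rounding. Unlike [base::round()], which rounds half to even,
#' ties are rounded away from zero, so 0.005 becomes 0.01 and -0.005 becomes
#' -0.01 at two decimals. Used only for presentation; computations are never
#' rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(c(0.005, -0.005, 0.0649), 2)
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by machine epsilon so values that are exactly .5 after floating
  # point representation (e.g. 0.065 stored as 0.06499999...) still go up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

fmt_round <- function(x, digits = 2) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

# Detect the field separator from the header line: tab wins if present,
# otherwise comma; anything else is rejected.
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) mr_input_error(sprintf("file '%s' is empty", path))
  if (grepl("\t", header, fixed = TRUE)) return("\t")
  if (grepl(",", header, fixed = TRUE)) return(",")
  mr_input_error(sprintf(
    "cannot detect delimiter in '%s': header contains neither tab nor comma", path))
}
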