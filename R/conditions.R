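#' @title Typed error conditions
#' @description Internal constructors for the package's typed error
#'   conditions. Every anticipated failure mode signals a classed condition
#'   so callers can distinguish, e.g., an unmeasurable location from a
#'   malformed file, instead of matching on message strings.
#' @details Condition classes used throughout:
#' \itemize{
#'   \item \code{cdiValidationError}: invalid argument or object state.
#'   \item \code{cdiDegenerateContour}: polyline too short / zero length.
#'   \item \code{cdiUnmeasurableLocation}: an informative location resolves
#'     to a slice with no usable contour (fields \code{kneeId},
#'     \code{location}).
#'   \item \code{cdiEmptyMeasurement}: every location of a bone was
#'     unmeasurable.
#'   \item \code{cdiUndefinedStatistic}: a statistic has no defined value
#'     (zero variance, constant vector).
#'   \item \code{cdiNoDenudedRegion}: frequency map is identically zero.
#'   \item \code{cdiParseError}: file does not match the expected schema
#'     (field named in the message).
#' }
#' @name cdi-conditions
#' @keywords internal
NULL

.cdiStop <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "cdiError", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

.assert <- function(ok, message, class = "cdiValidationError") {
  if (!isTRUE(ok)) .cdiStop(class, message)
  invisible(TRUE)
}
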