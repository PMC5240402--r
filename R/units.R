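#' Unit handling
#'
#' All internal computation uses canonical units: seconds, millilitres and
#' pascals (flows in ml/s, resistances in Pa/(ml/s), compliances in ml/Pa).
#' Configuration files and the clinical literature use hour-based units
#' (ml/h for flow rates, Pa/(ml/h) for resistances); these are converted at
#' the boundary by [to_internal()] and back by [from_internal()].
#'
#' @name units
NULL

# multiplicative factor clinical -> canonical, per accepted unit tag
.unit_factors <- c(
  "ml/h"      = 1 / 3600,
  "ml/s"      = 1,
  "Pa/(ml/h)" = 3600,
  "Pa/(ml/s)" = 1,
  "ml/Pa"     = 1,
  "s"         = 1,
  "min"       = 60,
  "h"         = 3600,
  "ml"        = 1,
  "Pa"        = 1
)

#' Convert a clinical-unit value to canonical internal units
#'
#' @param value numeric vector.
#' @param unit unit tag, one of `"ml/h"`, `"ml/s"`, `"Pa/(ml/h)"`,
#'   `"Pa/(ml/s)"`, `"ml/Pa"`, `"s"`, `"min"`, `"h"`, `"ml"`, `"Pa"`.
#' @return `value` expressed in canonical units (s, ml, Pa and compounds).
#' @examples
#' to_internal(12, "ml/h")        # 0.003333... ml/s
#' to_internal(1145, "Pa/(ml/h)") # 4.122e6 Pa/(ml/s)
#' @export
to_internal <- function(value, unit) {
  f <- .unit_factors[unit]
  if (length(unit) != 1L || is.na(f)) {
    stop("unknown unit tag: '", unit, "' (accepted: ",
         paste(names(.unit_factors), collapse = ", "), ")", call. = FALSE)
  }
  unname(value * f)
}

#' Convert a canonical internal value back to a clinical unit
#'
#' Inverse of [to_internal()]; round-trip is exact to floating point.
#'
#' @inheritParams to_internal
#' @return `value` expressed in the requested clinical unit.
#' @export
from_internal <- function(value, unit) {
  f <- .unit_factors[unit]
  if (length(unit) != 1L || is.na(f)) {
    stop("unknown unit tag: '", unit, "' (accepted: ",
         paste(names(.unit_factors), collapse = ", "), ")", call. = FALSE)
  }
  unname(value / f)
}
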