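#' Exact reduced fractions
#'
#' Construct a [Rational-class] value.  The fraction is reduced by the
#' greatest common divisor at construction; arithmetic stays exact as long
#' as intermediate whole numbers remain below 2^53 (an error is raised
#' otherwise, never a silent rounding).
#'
#' @param numerator,denominator whole numbers; `denominator > 0`.
#' @return A [Rational-class] object.
#' @examples
#' rational(2, 8)              # 1/4
#' as.numeric(rational(1, 3))
#' @export
rational <- function(numerator, denominator = 1) {
  if (denominator == 0) stop("zero denominator", call. = FALSE)
  if (denominator < 0) { numerator <- -numerator; denominator <- -denominator }
  g <- gcdInt(numerator, denominator)
  if (g > 0) { numerator <- numerator / g; denominator <- denominator / g }
  new("Rational", numerator = as.numeric(numerator),
      denominator = as.numeric(denominator))
}

#' @rdname gdinet-accessors
#' @export
setMethod("numerator", "Rational", function(x) x@numerator)

#' @rdname gdinet-accessors
#' @export
setMethod("denominator", "Rational", function(x) x@denominator)

#' @describeIn rational coerce to double.
#' @param x a `Rational`.
#' @param ... ignored.
#' @export
setMethod("as.numeric", "Rational", function(x, ...) x@numerator / x@denominator)

setMethod("show", "Rational", function(object) {
  cat(object@numerator, "/", object@denominator,
      " (", format(object@numerator / object@denominator, digits = 6), ")\n",
      sep = "")
})

.ratGuard <- function(x) {
  if (abs(x) >= 2^53)
    stop("exact rational arithmetic overflow (value >= 2^53)", call. = FALSE)
  x
}

# a + n/d, all reduced; inputs are Rational and whole numbers.
ratAdd <- function(a, n, d) {
  g <- gcdInt(a@denominator, d)
  den <- .ratGuard((a@denominator / g) * d)
  num <- .ratGuard(a@numerator * (d / g) + n * (a@denominator / g))
  rational(num, den)
}

# a / m for whole m > 0.
ratDivInt <- function(a, m) rational(a@numerator, .ratGuard(a@denominator * m))
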