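## S4 containers for melting-curve data and fits.

#' MeltingCurve: a thermal denaturation series
#'
#' Holds a (temperature, normalized ellipticity) series from a thermal
#' melting assay. Temperatures must be strictly increasing and finite;
#' fitting additionally requires at least 12 points spanning at least
#' 30 degrees C (checked by \code{\link{fitMelting}}).
#'
#' @slot temperatures Numeric, degrees C, strictly increasing.
#' @slot values Numeric, dimensionless (normalized ellipticity).
#' @slot curveId Character scalar identifier.
#' @aliases MeltingCurve
#' @exportClass MeltingCurve
setClass("MeltingCurve",
         representation(temperatures = "numeric", values = "numeric",
                        curveId = "character"))

setValidity("MeltingCurve", function(object) {
  t <- object@temperatures
  v <- object@values
  if (length(t) != length(v))
    return("temperatures and values must have equal length")
  if (length(t) < 2L)
    return("a melting curve needs at least 2 points")
  if (!all(is.finite(t)) || !all(is.finite(v)))
    return("temperatures and values must be finite")
  if (any(diff(t) <= 0))
    return("temperatures must be strictly increasing")
  if (length(object@curveId) != 1L)
    return("curveId must be a single string")
  TRUE
})

#' Construct a MeltingCurve
#'
#' @param temperatures Numeric vector of temperatures (degrees C),
#'   strictly increasing.
#' @param values Numeric vector of (normalized) ellipticity values.
#' @param curveId Identifier (default \code{"curve"}).
#' @return A \code{\linkS4class{MeltingCurve}}.
#' @examples
#' MeltingCurve(seq(5, 95, 5), seq(0, 1, length.out = 19))
#' @export
MeltingCurve <- function(temperatures, values, curveId = "curve") {
  new("MeltingCurve", temperatures = as.numeric(temperatures),
      values = as.numeric(values), curveId = as.character(curveId))
}

#' @describeIn MeltingCurve-class Temperatures (degrees C).
#' @param x,object A \code{MeltingCurve}.
#' @export
temperatures <- function(x) x@temperatures

#' @describeIn MeltingCurve-class Ellipticity values.
#' @export
ellipticities <- function(x) x@values

#' @describeIn MeltingCurve-class Curve identifier.
#' @export
curveId <- function(x) x@curveId

setMethod("show", "MeltingCurve", function(object) {
  t <- object@temperatures
  cat("MeltingCurve '", object@curveId, "': ", length(t), " points, ",
      min(t), "-", max(t), " degC\n", sep = "")
})

#' @describeIn MeltingCurve-class Number of points.
#' @export
setMethod("length", "MeltingCurve", function(x) length(x@temperatures))

#' BiphasicFit: a fitted double-sigmoid melting model
#'
#' The biphasic melting model is the sum of two logistic transitions,
#' \deqn{f(x) = \frac{a}{1 + e^{-(x - x_0)/b}} +
#'   \frac{c}{1 + e^{-(x - x_2)/d}},}
#' whose midpoints \eqn{x_0 < x_2} are reported as the melting temperatures
#' tm1 and tm2. A monophasic fit constrains \eqn{c = 0} (tm2 is then
#' \code{NA}).
#'
#' @slot params Named numeric: \code{a, x0, b, c, x2, d}.
#' @slot stderr Named numeric: asymptotic standard errors from the fit
#'   curvature (NA where unavailable).
#' @slot residualSSE Residual sum of squares.
#' @slot model \code{"monophasic"} or \code{"biphasic"}.
#' @slot selectionStat Corrected information-criterion difference from
#'   model selection (\code{NA} unless set by
#'   \code{\link{classifyTransition}}).
#' @slot nPoints Number of fitted points.
#' @slot curveId Identifier of the fitted curve.
#' @aliases BiphasicFit
#' @exportClass BiphasicFit
setClass("BiphasicFit",
         representation(params = "numeric", stderr = "numeric",
                        residualSSE = "numeric", model = "character",
                        selectionStat = "numeric", nPoints = "integer",
                        curveId = "character"))

setValidity("BiphasicFit", function(object) {
  p <- object@params
  if (!all(c("a", "x0", "b", "c", "x2", "d") %in% names(p)))
    return("params must contain a, x0, b, c, x2, d")
  if (!object@model %in% c("monophasic", "biphasic"))
    return("model must be 'monophasic' or 'biphasic'")
  if (object@model == "biphasic") {
    if (!is.na(p[["b"]]) && p[["b"]] <= 0) return("slope b must be > 0")
    if (!is.na(p[["d"]]) && p[["d"]] <= 0) return("slope d must be > 0")
    if (!is.na(p[["x0"]]) && !is.na(p[["x2"]]) && p[["x0"]] >= p[["x2"]])
      return("canonical ordering violated: need x0 < x2")
  }
  TRUE
})

#' @describeIn BiphasicFit-class Melting temperatures: \code{c(tm1, tm2)}
#'   (tm2 is \code{NA} for a monophasic fit).
#' @param x,object A \code{BiphasicFit}.
#' @export
meltingTemperatures <- function(x)
  c(tm1 = unname(x@params[["x0"]]), tm2 = unname(x@params[["x2"]]))

#' @describeIn BiphasicFit-class Fitted parameters.
#' @export
setMethod("coef", "BiphasicFit", function(object) object@params)

#' @describeIn BiphasicFit-class Residual sum of squares.
#' @export
residualSSE <- function(x) x@residualSSE

#' @describeIn BiphasicFit-class Fitted model kind.
#' @export
fitModel <- function(x) x@model

setMethod("show", "BiphasicFit", function(object) {
  p <- object@params
  cat(object@model, " melting fit ('", object@curveId, "', ",
      object@nPoints, " points)\n", sep = "")
  cat(sprintf("  tm1 = %.2f degC (a = %.3f, b = %.2f)\n",
              p[["x0"]], p[["a"]], p[["b"]]))
  if (object@model == "biphasic")
    cat(sprintf("  tm2 = %.2f degC (c = %.3f, d = %.2f)\n",
                p[["x2"]], p[["c"]], p[["d"]]))
  cat(sprintf("  residual SSE = %.3g\n", object@residualSSE))
})
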