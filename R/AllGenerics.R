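#' Accessors for gridded objects
#'
#' `gridValues()`, `gridLat()`, `gridLon()` and `gridMask()` extract the
#' value matrix, cell-centre coordinates and land mask from a
#' [ClimateGrid-class] (or [ScalingPattern-class]); `gridVariable()` and
#' `gridPeriod()` return the labels. `globalDT()` returns the global-mean
#' warming divisor of a [ScalingPattern-class].
#'
#' @param x a `ClimateGrid` or `ScalingPattern`.
#' @return matrix, numeric vector or string as appropriate.
#' @name grid-accessors
#' @aliases gridValues gridLat gridLon gridMask gridVariable gridPeriod
#'   globalDT
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname grid-accessors
#' @export
setGeneric("gridLat", function(x) standardGeneric("gridLat"))
#' @rdname grid-accessors
#' @export
setGeneric("gridLon", function(x) standardGeneric("gridLon"))
#' @rdname grid-accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @rdname grid-accessors
#' @export
setGeneric("gridVariable", function(x) standardGeneric("gridVariable"))
#' @rdname grid-accessors
#' @export
setGeneric("gridPeriod", function(x) standardGeneric("gridPeriod"))
#' @rdname grid-accessors
#' @export
setGeneric("globalDT", function(x) standardGeneric("globalDT"))

#' @rdname grid-accessors
setMethod("gridValues", "ClimateGrid", function(x) x@values)
#' @rdname grid-accessors
setMethod("gridLat", "ClimateGrid", function(x) x@lat)
#' @rdname grid-accessors
setMethod("gridLon", "ClimateGrid", function(x) x@lon)
#' @rdname grid-accessors
setMethod("gridMask", "ClimateGrid", function(x) x@mask)
#' @rdname grid-accessors
setMethod("gridVariable", "ClimateGrid", function(x) x@variable)
#' @rdname grid-accessors
setMethod("gridPeriod", "ClimateGrid", function(x) x@period)
#' @rdname grid-accessors
setMethod("globalDT", "ScalingPattern", function(x) x@globalDT)

#' Accessors for fitted niche models
#'
#' Standard `coef()`, `vcov()` and `logLik()` methods plus `modelAICc()`,
#' `predictorNames()` and `isSeparated()`.
#'
#' @param object,x a [FittedNicheModel-class].
#' @param ... ignored.
#' @return numeric vector/matrix/scalar as appropriate.
#' @name model-accessors
#' @aliases modelAICc predictorNames isSeparated
NULL

#' @rdname model-accessors
#' @export
setGeneric("modelAICc", function(x) standardGeneric("modelAICc"))
#' @rdname model-accessors
#' @export
setGeneric("predictorNames", function(x) standardGeneric("predictorNames"))
#' @rdname model-accessors
#' @export
setGeneric("isSeparated", function(x) standardGeneric("isSeparated"))

#' @rdname model-accessors
#' @export
setMethod("coef", "FittedNicheModel", function(object, ...) object@coefficients)
#' @rdname model-accessors
#' @export
setMethod("vcov", "FittedNicheModel", function(object, ...) object@vcov)
#' @rdname model-accessors
#' @export
setMethod("logLik", "FittedNicheModel", function(object, ...) object@logLik)
#' @rdname model-accessors
setMethod("modelAICc", "FittedNicheModel", function(x) x@aicc)
#' @rdname model-accessors
setMethod("predictorNames", "FittedNicheModel", function(x) x@predictorNames)
#' @rdname model-accessors
setMethod("isSeparated", "FittedNicheModel", function(x) x@separation)

setMethod("show", "ClimateGrid", function(object) {
  cat(sprintf(
    "%s of '%s' [%s]: %d x %d cells, lat %.2f..%.2f, lon %.2f..%.2f, %d masked-in\n",
    class(object), object@variable, object@period,
    nrow(object@values), ncol(object@values),
    min(object@lat), max(object@lat), min(object@lon), max(object@lon),
    sum(object@mask)
  ))
  invisible(object)
})

setMethod("show", "ScalingPattern", function(object) {
  callNextMethod()
  cat(sprintf("  per 1 degC of global warming (globalDT = %.2f degC)\n",
              object@globalDT))
  invisible(object)
})

setMethod("show", "GlobalAnomalySeries", function(object) {
  cat(sprintf(
    "GlobalAnomalySeries: %d years (%s..%s), %g-yr running mean, ref %g, preindustrial offset %.2f degC\n",
    length(object@years), min(object@years), max(object@years),
    object@window, object@refYear, object@preindustrialOffset
  ))
  invisible(object)
})

setMethod("show", "FittedNicheModel", function(object) {
  cat(sprintf(
    "FittedNicheModel (binomial logit): %s\n  n = %d, k = %d, logLik = %.3f, AICc = %.3f%s\n",
    if (length(object@predictorNames)) {
      paste(object@predictorNames, collapse = " + ")
    } else "intercept only",
    object@nObs, object@kParams, object@logLik, object@aicc,
    if (object@separation) " [complete separation]" else ""
  ))
  print(round(object@coefficients, 4))
  invisible(object)
})

setMethod("show", "HabitatProjection", function(object) {
  cat(sprintf(
    "HabitatProjection: tau = %.3f, habitat fraction = %.3f, northern limit = %s degN\n",
    object@threshold, object@habitatFraction,
    if (is.na(object@northernLimitLat)) "none" else
      sprintf("%.2f", object@northernLimitLat)
  ))
  invisible(object)
})

setMethod("show", "MESSSurface", function(object) {
  s <- object@similarity[object@mask]
  cat(sprintf(
    "MESSSurface over %d variables (%s): %.1f%% of %d cells novel (similarity < 0)\n",
    length(object@variables), object@reference,
    100 * mean(s < 0, na.rm = TRUE), sum(object@mask)
  ))
  invisible(object)
})
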