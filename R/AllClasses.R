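#' @import methods
NULL

#' ClimateGrid: a single-variable gridded climate field
#'
#' A regular latitude/longitude grid of one climate variable (mean annual
#' temperature in degC or sun radiation in MJ m^-2 day^-1), with cell-centre
#' coordinates (decimal degrees, WGS84), a land/region mask, and a period
#' label. Rows of `values` index latitude, columns index longitude.
#'
#' @slot values numeric matrix, `length(lat)` x `length(lon)`; `NA` outside
#'   the mask.
#' @slot lat,lon numeric cell-centre coordinates; `lat` strictly monotone.
#' @slot mask logical matrix, same shape; `TRUE` marks valid (land) cells.
#' @slot variable single string naming the variable.
#' @slot period single string labelling the climatological period.
#'
#' @exportClass ClimateGrid
setClass("ClimateGrid",
  slots = c(
    values = "matrix",
    lat = "numeric",
    lon = "numeric",
    mask = "matrix",
    variable = "character",
    period = "character"
  )
)

setValidity("ClimateGrid", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (!is.numeric(object@values)) {
    msg <- c(msg, "'values' must be a numeric matrix")
  }
  if (d[1] != length(object@lat) || d[2] != length(object@lon)) {
    msg <- c(msg, sprintf(
      "values is %d x %d but lat/lon have lengths %d/%d",
      d[1], d[2], length(object@lat), length(object@lon)
    ))
  }
  if (!identical(dim(object@mask), d)) {
    msg <- c(msg, "'mask' must have the same shape as 'values'")
  }
  if (!is.logical(object@mask)) {
    msg <- c(msg, "'mask' must be logical")
  }
  dl <- diff(object@lat)
  if (length(object@lat) > 1 && !(all(dl > 0) || all(dl < 0))) {
    msg <- c(msg, "'lat' must be strictly monotone")
  }
  dn <- diff(object@lon)
  if (length(object@lon) > 1 && !(all(dn > 0) || all(dn < 0))) {
    msg <- c(msg, "'lon' must be strictly monotone")
  }
  if (length(object@variable) != 1L) {
    msg <- c(msg, "'variable' must be a single string")
  }
  if (length(object@period) != 1L) {
    msg <- c(msg, "'period' must be a single string")
  }
  if (length(msg)) msg else TRUE
})

#' ScalingPattern: per-cell climate change per 1 degC of global warming
#'
#' A [ClimateGrid-class] whose values are the change in the variable per
#' degree of global-mean warming, together with the global-mean temperature
#' difference `globalDT` (degC) that was used as the divisor.
#'
#' @slot globalDT positive number, the global-mean warming of the source
#'   future-minus-present pair (e.g. 3.49, 3.57, 3.50, 3.41 degC for a
#'   four-member SST ensemble).
#'
#' @exportClass ScalingPattern
setClass("ScalingPattern",
  contains = "ClimateGrid",
  slots = c(globalDT = "numeric")
)

setValidity("ScalingPattern", function(object) {
  if (length(object@globalDT) != 1L || !is.finite(object@globalDT) ||
      object@globalDT <= 0) {
    "'globalDT' must be a single positive number"
  } else {
    TRUE
  }
})

#' GlobalAnomalySeries: smoothed global-mean temperature anomaly
#'
#' A 20-year (by default) running-mean global temperature anomaly relative
#' to a reference year (1990, the centre of a 1980-2000 average), plus the
#' offset of that reference above the preindustrial state (default 0.5 degC).
#'
#' @slot years numeric, one per anomaly value.
#' @slot anomaly numeric, degC relative to the reference year.
#' @slot window running-mean window length in years (recorded, not applied).
#' @slot refYear the reference year at which the anomaly is zero.
#' @slot preindustrialOffset degC by which the reference period already
#'   exceeds the preindustrial state.
#'
#' @exportClass GlobalAnomalySeries
setClass("GlobalAnomalySeries",
  slots = c(
    years = "numeric",
    anomaly = "numeric",
    window = "numeric",
    refYear = "numeric",
    preindustrialOffset = "numeric"
  )
)

setValidity("GlobalAnomalySeries", function(object) {
  msg <- character()
  if (length(object@years) != length(object@anomaly)) {
    msg <- c(msg, "'years' and 'anomaly' must have equal length")
  }
  if (length(object@refYear) != 1L) {
    msg <- c(msg, "'refYear' must be a single year")
  }
  i <- match(object@refYear, object@years)
  if (!is.na(i) && abs(object@anomaly[i]) > 1e-8) {
    msg <- c(msg, "anomaly must be zero at the reference year")
  }
  if (length(object@preindustrialOffset) != 1L ||
      object@preindustrialOffset < 0) {
    msg <- c(msg, "'preindustrialOffset' must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' FittedNicheModel: a binomial-logit niche model
#'
#' Coefficients on the logit scale with their covariance (inverse observed
#' information), the maximized binomial log-likelihood, and the
#' small-sample-corrected information criterion AICc.
#'
#' @slot predictorNames predictor names (excluding the intercept).
#' @slot coefficients named numeric, intercept first.
#' @slot vcov coefficient covariance matrix.
#' @slot logLik maximized log-likelihood, nats.
#' @slot nObs number of observations.
#' @slot kParams number of estimated coefficients including the intercept.
#' @slot aicc AICc value; finite only when `nObs - kParams - 1 > 0`.
#' @slot converged logical, IRLS convergence flag.
#' @slot separation logical, `TRUE` when the data are completely separated.
#'
#' @exportClass FittedNicheModel
setClass("FittedNicheModel",
  slots = c(
    predictorNames = "character",
    coefficients = "numeric",
    vcov = "matrix",
    logLik = "numeric",
    nObs = "integer",
    kParams = "integer",
    aicc = "numeric",
    converged = "logical",
    separation = "logical"
  )
)

setValidity("FittedNicheModel", function(object) {
  msg <- character()
  if (object@kParams != length(object@coefficients)) {
    msg <- c(msg, "'kParams' must equal the number of coefficients")
  }
  if (length(object@predictorNames) != object@kParams - 1L) {
    msg <- c(msg, "'predictorNames' must exclude the intercept")
  }
  if (!all(dim(object@vcov) == object@kParams)) {
    msg <- c(msg, "'vcov' must be kParams x kParams")
  }
  if (length(msg)) msg else TRUE
})

#' HabitatProjection: thresholded habitat map with summaries
#'
#' @slot probability [ClimateGrid-class] of habitat probabilities in \[0, 1\].
#' @slot habitat logical matrix, `TRUE` where probability >= threshold
#'   (inclusive) inside the region mask.
#' @slot threshold probability cutoff.
#' @slot regionMask logical matrix restricting the analysis region
#'   (default: land north of 35 degN and east of 136 degE).
#' @slot habitatFraction habitat cells / masked cells.
#' @slot northernLimitLat maximum cell-centre latitude with habitat
#'   (`NA` when no habitat cell exists).
#'
#' @exportClass HabitatProjection
setClass("HabitatProjection",
  slots = c(
    probability = "ClimateGrid",
    habitat = "matrix",
    threshold = "numeric",
    regionMask = "matrix",
    habitatFraction = "numeric",
    northernLimitLat = "numeric"
  )
)

setValidity("HabitatProjection", function(object) {
  msg <- character()
  d <- dim(object@probability@values)
  if (!identical(dim(object@habitat), d) ||
      !identical(dim(object@regionMask), d)) {
    msg <- c(msg, "'habitat' and 'regionMask' must match the probability grid")
  }
  v <- object@probability@values
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    msg <- c(msg, "probabilities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' MESSSurface: multivariate environmental similarity surface
#'
#' Per-cell minimum similarity across variables (percent-like; negative
#' values flag climates outside the range of the reference points) and the
#' index of the most dissimilar variable.
#'
#' @slot similarity numeric matrix of minimum similarities.
#' @slot mdvIndex integer matrix indexing `variables` at each cell.
#' @slot variables variable names, in index order.
#' @slot lat,lon cell-centre coordinates.
#' @slot mask logical matrix of valid cells.
#' @slot reference single string describing the reference point set.
#'
#' @exportClass MESSSurface
setClass("MESSSurface",
  slots = c(
    similarity = "matrix",
    mdvIndex = "matrix",
    variables = "character",
    lat = "numeric",
    lon = "numeric",
    mask = "matrix",
    reference = "character"
  )
)

setValidity("MESSSurface", function(object) {
  d <- dim(object@similarity)
  if (!identical(dim(object@mdvIndex), d) || !identical(dim(object@mask), d)) {
    "'similarity', 'mdvIndex' and 'mask' must share one shape"
  } else if (d[1] != length(object@lat) || d[2] != length(object@lon)) {
    "coordinate lengths must match the similarity matrix"
  } else {
    TRUE
  }
})
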