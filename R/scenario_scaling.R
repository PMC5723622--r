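#' Construct a ClimateGrid
#'
#' @param values numeric matrix (rows = latitude, columns = longitude).
#' @param lat,lon cell-centre coordinates; `lat` strictly monotone.
#' @param mask logical matrix of valid cells; defaults to `!is.na(values)`.
#' @param variable,period label strings.
#' @return a [ClimateGrid-class].
#' @export
climateGrid <- function(values, lat, lon, mask = NULL,
                        variable = "temperature", period = "present") {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  values[!mask] <- NA_real_
  new("ClimateGrid", values = values, lat = as.numeric(lat),
      lon = as.numeric(lon), mask = mask, variable = variable,
      period = period)
}

sameGeometry <- function(a, b) {
  isTRUE(all.equal(a@lat, b@lat)) && isTRUE(all.equal(a@lon, b@lon)) &&
    identical(dim(a@values), dim(b@values)) && identical(a@mask, b@mask)
}

stopIfGeometryDiffers <- function(a, b) {
  if (!sameGeometry(a, b)) {
    stop("grids do not share geometry (shape, coordinates, mask)",
         call. = FALSE)
  }
}

#' Derive a per-degree scaling pattern from a present/future grid pair
#'
#' Divides the future-minus-present field by the global-mean temperature
#' difference of the driving simulation pair, yielding the local climate
#' change per 1 degC of global warming. Masked cells stay masked.
#'
#' @param present,future [ClimateGrid-class] pair with identical geometry.
#' @param globalDT global-mean warming between the two periods, degC (> 0);
#'   e.g. 3.49, 3.57, 3.50, 3.41 for a four-member SST ensemble.
#' @return a [ScalingPattern-class].
#' @export
computeScalingPattern <- function(present, future, globalDT) {
  stopIfGeometryDiffers(present, future)
  if (!is.finite(globalDT) || globalDT <= 0) {
    stop("'globalDT' must be a positive number", call. = FALSE)
  }
  new("ScalingPattern",
      values = (future@values - present@values) / globalDT,
      lat = present@lat, lon = present@lon, mask = present@mask,
      variable = present@variable,
      period = paste0(present@period, "->", future@period),
      globalDT = globalDT)
}

#' Build a warming-level climate scenario by pattern scaling
#'
#' Inflates a scaling pattern by `X - offset` degC — the target warming
#' above preindustrial minus the warming already realized at the baseline
#' period — and adds it to the baseline field:
#' `scenario = baseline + (X - offset) * pattern`, cellwise. At
#' `X == offset` the scenario is the baseline, bit-exactly.
#'
#' @param baseline [ClimateGrid-class] present-period field.
#' @param pattern [ScalingPattern-class] with the same geometry.
#' @param X target global warming above the preindustrial state, degC.
#' @param offset warming already realized at the baseline relative to
#'   preindustrial, degC (default 0.5).
#' @return a [ClimateGrid-class] labelled with the warming level.
#' @export
buildScenario <- function(baseline, pattern, X, offset = 0.5) {
  stopIfGeometryDiffers(baseline, pattern)
  if (X < offset) {
    warning("X below the baseline offset; extrapolating backwards",
            call. = FALSE)
  }
  v <- if (X == offset) baseline@values else
    baseline@values + (X - offset) * pattern@values
  climateGrid(v, baseline@lat, baseline@lon, mask = baseline@mask,
              variable = baseline@variable,
              period = sprintf("+%.1fC", X))
}

#' Centered running mean of an annual series
#'
#' Window means of consecutive values, labelled by the exact window centre
#' (half-integer years for even windows). Output length is
#' `length(x) - window + 1`.
#'
#' @param x numeric series.
#' @param window window length (default 20 years).
#' @param years optional year labels, same length as `x`; when given the
#'   result is a data.frame `(year, value)` instead of a vector.
#' @return numeric vector of window means, or a data.frame with centre
#'   years.
#' @export
runningMean <- function(x, window = 20, years = NULL) {
  n <- length(x)
  if (window < 1 || window > n) {
    stop("'window' must lie in [1, length(x)]", call. = FALSE)
  }
  # embed() lists each window back-to-front; restore forward order so the
  # summation order (and hence the floating-point result) matches a naive
  # left-to-right window sum
  m <- rowSums(stats::embed(x, window)[, window:1, drop = FALSE]) / window
  if (is.null(years)) return(m)
  stopifnot(length(years) == n)
  data.frame(year = years[seq_len(n - window + 1)] + (window - 1) / 2,
             value = m)
}

#' First year a global warming level is exceeded
#'
#' Returns the first year at which the smoothed global anomaly reaches
#' `X - preindustrialOffset` (inclusive), i.e. at which total warming above
#' the preindustrial state reaches `X`. Returns `NA` (with a message) when
#' the level is never reached within the series.
#'
#' @param series a [GlobalAnomalySeries-class].
#' @param X target warming above preindustrial, degC (must be at least the
#'   series' preindustrial offset).
#' @return the exceedance year, or `NA` if not exceeded.
#' @export
exceedanceYear <- function(series, X) {
  off <- series@preindustrialOffset
  if (X < off) {
    stop("'X' must be at least the preindustrial offset (", off, ")",
         call. = FALSE)
  }
  hit <- which(series@anomaly >= X - off)
  if (length(hit) == 0) {
    message(sprintf("warming level %.2f degC not exceeded within %g-%g",
                    X, min(series@years), max(series@years)))
    return(NA_real_)
  }
  series@years[hit[1]]
}

#' Mean-matching bias correction of a simulated field
#'
#' A simple per-cell correction aligning a simulated present-period field
#' with an observed reference: additive offsets for temperature
#' (corrected = simulated + (observed - simulated)), multiplicative factors
#' for radiation (corrected = simulated * observed/simulated), the latter
#' guarded against near-zero simulated values (such cells are flagged via
#' attribute `uncorrected` and left as simulated). The correction is
#' isolated behind this one interface so a more elaborate recipe (e.g.
#' quantile mapping) can replace it.
#'
#' @param simulated,observed [ClimateGrid-class] pair, identical geometry.
#' @param guard radiation denominators below this are not corrected
#'   (default 1e-6).
#' @return corrected [ClimateGrid-class]; for multiplicative correction the
#'   logical attribute matrix `uncorrected` marks guarded cells.
#' @export
biasCorrect <- function(simulated, observed, guard = 1e-6) {
  stopIfGeometryDiffers(simulated, observed)
  multiplicative <- identical(simulated@variable, "radiation")
  if (multiplicative) {
    bad <- simulated@mask & !is.na(simulated@values) &
      abs(simulated@values) < guard
    v <- simulated@values * (observed@values / simulated@values)
    v[bad] <- simulated@values[bad]
    out <- climateGrid(v, simulated@lat, simulated@lon,
                       mask = simulated@mask, variable = simulated@variable,
                       period = simulated@period)
    attr(out, "uncorrected") <- bad
    if (any(bad)) {
      warning(sum(bad), " cell(s) below the radiation guard left uncorrected",
              call. = FALSE)
    }
    out
  } else {
    climateGrid(simulated@values + (observed@values - simulated@values),
                simulated@lat, simulated@lon, mask = simulated@mask,
                variable = simulated@variable, period = simulated@period)
  }
}
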