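#' Specification of a synthetic study region
#'
#' Describes a synthetic network of weather stations along a combined
#' latitude-altitude temperature gradient, with a logistic presence model
#' whose true coefficients are known. The defaults emulate the study
#' conditions of the bamboo survey: 145 stations at 35.3-41.5 degN with a
#' presence fraction near 116/145, the logistic transition of occurrence
#' probability spanning roughly 7-11 degC mean annual temperature.
#'
#' @param nStations number of stations (>= 2).
#' @param latRange,lonRange station coordinate ranges, decimal degrees.
#' @param altRange altitude range, m; altitudes are drawn skewed towards
#'   low elevations (cubed-uniform), as station networks are.
#' @param lapseRate altitudinal temperature lapse rate, degC per km.
#' @param latGradient temperature change per degree latitude, degC.
#' @param baseTemp sea-level mean annual temperature at the southern edge,
#'   degC.
#' @param seasonalAmplitude half-range of the sinusoidal seasonal cycle of
#'   monthly mean temperature, degC.
#' @param trueCoefficients named vector `c(beta0, betaT, betaR)` of the
#'   logit-scale presence model
#'   `logit(p) = beta0 + betaT * tempMean + betaR * radiation`.
#' @param radiationRange sun radiation range, MJ m^-2 day^-1.
#' @param noiseSd station-level temperature noise, degC.
#' @param seed integer seed; every stochastic generator takes its
#'   randomness from here (no global state is consulted).
#' @return a `SyntheticWorldSpec` (classed list).
#' @export
syntheticWorldSpec <- function(nStations = 145L,
                               latRange = c(35.3, 41.5),
                               lonRange = c(137.6, 142.0),
                               altRange = c(0, 1100),
                               lapseRate = -6.5,
                               latGradient = -0.9,
                               baseTemp = 16.3,
                               seasonalAmplitude = 11,
                               trueCoefficients = c(beta0 = -12.0,
                                                    betaT = 1.1,
                                                    betaR = 0.15),
                               radiationRange = c(12, 16),
                               noiseSd = 0.4,
                               seed = 1L) {
  if (nStations < 2) stop("'nStations' must be >= 2", call. = FALSE)
  if (diff(range(latRange)) <= 0 && diff(range(altRange)) <= 0) {
    stop("degenerate spec: zero spread in both latitude and altitude",
         call. = FALSE)
  }
  if (length(trueCoefficients) != 3L) {
    stop("'trueCoefficients' must be (beta0, betaT, betaR)", call. = FALSE)
  }
  names(trueCoefficients) <- c("beta0", "betaT", "betaR")
  structure(
    list(
      nStations = as.integer(nStations), latRange = latRange,
      lonRange = lonRange, altRange = altRange, lapseRate = lapseRate,
      latGradient = latGradient, baseTemp = baseTemp,
      seasonalAmplitude = seasonalAmplitude,
      trueCoefficients = trueCoefficients,
      radiationRange = radiationRange, noiseSd = noiseSd,
      seed = as.integer(seed)
    ),
    class = "SyntheticWorldSpec"
  )
}

# monthly deviation from the annual mean: sinusoid peaking in July
seasonalCycle <- function(amplitude) {
  amplitude * sin(2 * pi * (1:12 - 4) / 12)
}

#' Generate a synthetic station table with known truth
#'
#' Builds a wide station table in the dialect of [readStationCsv()]. Each
#' station's mean annual temperature follows the latitude-altitude gradient
#' of the spec plus Gaussian noise; monthly means add a fixed sinusoidal
#' seasonal cycle (mean-zero over the year, so the annual mean is exact);
#' monthly precipitation is summer-peaked; annual extreme temperatures are
#' fixed offsets from the coldest/warmest monthly means. Presence is drawn
#' `Bernoulli(plogis(beta0 + betaT * tempMean + betaR * radiation))`; the
#' true probability is returned in column `true_prob` and the coefficients
#' as attribute `trueCoefficients`.
#'
#' @param spec a [syntheticWorldSpec()].
#' @return data.frame with columns `id, lat, lon, alt, t_01..t_12,
#'   p_01..p_12, tmin_year, tmax_year, radiation, forest, farmland,
#'   building, presence, true_prob`.
#' @export
makeStations <- function(spec = syntheticWorldSpec()) {
  stopifnot(inherits(spec, "SyntheticWorldSpec"))
  n <- spec$nStations
  out <- withSeed(spec$seed, {
    lat <- stats::runif(n, spec$latRange[1], spec$latRange[2])
    lon <- stats::runif(n, spec$lonRange[1], spec$lonRange[2])
    # cubic transform skews altitudes low, as real station networks are
    alt <- spec$altRange[1] + diff(spec$altRange) * stats::runif(n)^3
    tempMean <- spec$baseTemp +
      spec$latGradient * (lat - spec$latRange[1]) +
      spec$lapseRate * alt / 1000 +
      stats::rnorm(n, sd = spec$noiseSd)
    cyc <- seasonalCycle(spec$seasonalAmplitude)
    tmon <- outer(tempMean, cyc, `+`)
    pmon <- pmax(outer(rep(110, n), 60 * sin(2 * pi * (1:12 - 4) / 12), `+`) +
                   matrix(stats::rnorm(n * 12, sd = 10), n, 12), 0)
    radiation <- stats::runif(n, spec$radiationRange[1],
                              spec$radiationRange[2])
    forest <- stats::runif(n, 0.2, 0.8)
    farmland <- stats::runif(n, 0, 0.8) * (1 - forest)
    building <- stats::runif(n, 0, 0.5) * (1 - forest - farmland)
    b <- spec$trueCoefficients
    eta <- b["beta0"] + b["betaT"] * tempMean + b["betaR"] * radiation
    prob <- stats::plogis(eta)
    presence <- stats::rbinom(n, 1L, prob)
    df <- data.frame(
      id = sprintf("S%04d", seq_len(n)),
      lat = lat, lon = lon, alt = alt
    )
    df[sprintf("t_%02d", 1:12)] <- as.data.frame(tmon)
    df[sprintf("p_%02d", 1:12)] <- as.data.frame(pmon)
    df$tmin_year <- apply(tmon, 1, min) - 8
    df$tmax_year <- apply(tmon, 1, max) + 9
    df$radiation <- radiation
    df$forest <- forest
    df$farmland <- farmland
    df$building <- building
    df$presence <- presence
    df$true_prob <- unname(prob)
    df
  })
  attr(out, "trueCoefficients") <- spec$trueCoefficients
  out
}

#' Generate paired present/future climate grids with a known warming field
#'
#' Builds a synthetic present-day temperature and radiation grid over a
#' regular lat/lon lattice (temperature following the spec's latitudinal
#' gradient plus smooth spatial noise) and a future pair obtained by adding
#' a known warming field, so that the scaling pattern recovered by
#' [computeScalingPattern()] is exactly `warming / globalDT`.
#'
#' @param latRange,lonRange grid extents, degrees.
#' @param resolution cell size, degrees.
#' @param warming either a single number (uniform warming, degC) or a
#'   length-2 vector `c(south, north)` interpolated linearly in latitude.
#' @param globalDT the global-mean warming (degC) attributed to the pair.
#' @param spec a [syntheticWorldSpec()] supplying the temperature gradient
#'   and radiation level.
#' @param seed integer seed for the spatial noise field.
#' @param noiseSd standard deviation of the cellwise spatial noise added to
#'   the present temperature field, degC (0 gives a purely latitudinal
#'   field whose isotherms are analytically tractable).
#' @param maskFraction fraction of cells masked out as sea (taken from the
#'   eastern edge), between 0 and 0.5.
#' @return list with elements `present` and `future`, each a named list of
#'   [ClimateGrid-class] objects (`temperature`, `radiation`), plus
#'   `warming` (the warming matrix) and `globalDT`.
#' @export
makeGridWorld <- function(latRange = c(35, 45.5), lonRange = c(136, 142),
                          resolution = 0.25, warming = 2.0, globalDT = 3.49,
                          spec = syntheticWorldSpec(), seed = 1L,
                          noiseSd = 0.3, maskFraction = 0) {
  if (globalDT <= 0) stop("'globalDT' must be positive", call. = FALSE)
  lat <- seq(latRange[1] + resolution / 2, latRange[2], by = resolution)
  lon <- seq(lonRange[1] + resolution / 2, lonRange[2], by = resolution)
  nr <- length(lat); nc <- length(lon)
  noise <- if (noiseSd > 0) {
    withSeed(seed, matrix(stats::rnorm(nr * nc, sd = noiseSd), nr, nc))
  } else {
    matrix(0, nr, nc)
  }
  tempNow <- outer(spec$baseTemp +
                     spec$latGradient * (lat - spec$latRange[1]),
                   rep(0, nc), `+`) + noise
  radNow <- outer(mean(spec$radiationRange) -
                    0.15 * (lat - spec$latRange[1]), rep(0, nc), `+`)
  if (length(warming) == 1L) {
    w <- matrix(warming, nr, nc)
  } else if (length(warming) == 2L) {
    w <- outer(seq(warming[1], warming[2], length.out = nr), rep(1, nc))
  } else {
    stop("'warming' must have length 1 or 2", call. = FALSE)
  }
  mask <- matrix(TRUE, nr, nc)
  if (maskFraction > 0) {
    nSea <- floor(nc * maskFraction)
    if (nSea > 0) mask[, (nc - nSea + 1):nc] <- FALSE
  }
  tempNow[!mask] <- NA
  radNow[!mask] <- NA
  grid <- function(v, variable, period) {
    climateGrid(v, lat, lon, mask = mask, variable = variable,
                period = period)
  }
  wFut <- w
  wFut[!mask] <- NA
  # element names match the predictor columns of the station summary so a
  # fitted model can be applied to the grids directly
  list(
    present = list(temp_mean = grid(tempNow, "temperature", "present"),
                   radiation = grid(radNow, "radiation", "present")),
    future = list(temp_mean = grid(tempNow + wFut, "temperature", "future"),
                  radiation = grid(radNow, "radiation", "future")),
    warming = w, globalDT = globalDT
  )
}

#' Generate a smoothed global-mean temperature anomaly series
#'
#' Constructs a monotone non-decreasing global anomaly series (already in
#' running-mean form, window recorded) that is zero at the 1990 reference,
#' as a linear or logistic ramp.
#'
#' @param startYear,endYear series extent (`endYear > startYear`).
#' @param shape `"linear"` (anomaly = rate * (year - 1990)) or
#'   `"logistic"` (a saturating ramp with the same initial rate).
#' @param rate warming rate at the reference year, degC per year (>= 0).
#' @param saturation asymptotic anomaly of the logistic shape, degC.
#' @param window running-mean window length recorded on the object, years.
#' @param preindustrialOffset degC by which the 1990 reference exceeds the
#'   preindustrial state.
#' @return a [GlobalAnomalySeries-class].
#' @examples
#' s <- makeAnomalySeries(rate = 0.02)
#' exceedanceYear(s, 1.5) # 2040
#' @export
makeAnomalySeries <- function(startYear = 1990, endYear = 2090,
                              shape = c("linear", "logistic"), rate = 0.02,
                              saturation = 5, window = 20,
                              preindustrialOffset = 0.5) {
  shape <- match.arg(shape)
  if (endYear <= startYear) {
    stop("'endYear' must exceed 'startYear'", call. = FALSE)
  }
  if (rate < 0) stop("'rate' must be non-negative", call. = FALSE)
  years <- seq(startYear, endYear)
  refYear <- 1990
  a <- switch(shape,
    linear = rate * (years - refYear),
    logistic = {
      # logistic ramp through zero at the reference with slope `rate` there
      k <- 4 * rate / saturation
      f <- function(y) saturation / (1 + exp(-k * (y - refYear))) -
        saturation / 2
      f(years)
    }
  )
  new("GlobalAnomalySeries", years = as.numeric(years), anomaly = a,
      window = window, refYear = refYear,
      preindustrialOffset = preindustrialOffset)
}

# evaluate `expr` under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
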