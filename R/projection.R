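#' Map a fitted niche model onto climate grids
#'
#' Evaluates `logit^-1(beta . x)` cellwise, one [ClimateGrid-class] per
#' predictor, all sharing geometry. Masked cells propagate as `NA`.
#'
#' @param model a [FittedNicheModel-class].
#' @param grids named list of [ClimateGrid-class], one per model predictor.
#' @return [ClimateGrid-class] of presence probabilities.
#' @export
predictGrid <- function(model, grids) {
  need <- model@predictorNames
  miss <- setdiff(need, names(grids))
  if (length(miss)) {
    stop("missing predictor grid(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ref <- if (length(need)) grids[[need[1]]] else grids[[1]]
  eta <- matrix(model@coefficients[["(Intercept)"]],
                nrow(ref@values), ncol(ref@values))
  for (nm in need) {
    stopIfGeometryDiffers(ref, grids[[nm]])
    eta <- eta + model@coefficients[[nm]] * grids[[nm]]@values
  }
  climateGrid(stats::plogis(eta), ref@lat, ref@lon, mask = ref@mask,
              variable = "probability", period = ref@period)
}

#' Threshold a probability grid into a binary habitat map
#'
#' Habitat is declared where probability >= tau (inclusive), matching the
#' classification rule of the niche model.
#'
#' @param probability [ClimateGrid-class] of probabilities.
#' @param tau probability threshold.
#' @return [ClimateGrid-class] with 0/1 values (NA outside the mask).
#' @export
thresholdMap <- function(probability, tau) {
  v <- (probability@values >= tau) * 1
  climateGrid(v, probability@lat, probability@lon,
              mask = probability@mask, variable = "habitat",
              period = probability@period)
}

# region-of-interest mask: land cells at/above latMin and at/east of lonMin
regionMask <- function(grid, latMin = 35, lonMin = 136) {
  grid@mask &
    outer(grid@lat >= latMin, rep(TRUE, length(grid@lon))) &
    outer(rep(TRUE, length(grid@lat)), grid@lon >= lonMin)
}

#' Habitat-area fraction inside a region
#'
#' Fraction of masked region cells classified as habitat, by plain cell
#' counting (near-equal-area at mid-latitude 5-km grids); optional
#' cos(latitude) area weighting behind a flag.
#'
#' @param habitat [ClimateGrid-class] 0/1 habitat map (from
#'   [thresholdMap()]).
#' @param region logical matrix restricting the area (default: land at or
#'   north of `latMin` and at or east of `lonMin`).
#' @param latMin,lonMin inclusive region bounds used when `region` is NULL
#'   (defaults 35 degN, 136 degE).
#' @param areaWeight `"count"` (default) or `"coslat"`.
#' @return fraction in \[0, 1\].
#' @export
habitatFraction <- function(habitat, region = NULL, latMin = 35,
                            lonMin = 136,
                            areaWeight = c("count", "coslat")) {
  areaWeight <- match.arg(areaWeight)
  if (is.null(region)) region <- regionMask(habitat, latMin, lonMin)
  region <- region & habitat@mask
  if (!any(region)) stop("empty region mask", call. = FALSE)
  w <- if (areaWeight == "coslat") {
    outer(cos(habitat@lat * pi / 180), rep(1, length(habitat@lon)))
  } else {
    matrix(1, nrow(habitat@values), ncol(habitat@values))
  }
  sum(w[region] * (habitat@values[region] == 1)) / sum(w[region])
}

#' Northern limit of the habitat map
#'
#' The maximum cell-centre latitude among habitat cells; `NA` (with a
#' message) when the map holds no habitat.
#'
#' @inheritParams habitatFraction
#' @return latitude in degrees N, or `NA`.
#' @export
northernLimit <- function(habitat) {
  hit <- which(habitat@values == 1, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    message("no habitat cell; northern limit undefined")
    return(NA_real_)
  }
  max(habitat@lat[hit[, 1]])
}

#' Northward shift between two habitat limits
#'
#' Converts a latitude difference to kilometres with a fixed mean meridian
#' arc of 111.2 km per degree.
#'
#' @param baseLimit,scenarioLimit northern limits, degrees N.
#' @param kmPerDegree meridian arc length (default 111.2 km/deg).
#' @return shift in km (positive = northward).
#' @export
northwardShift <- function(baseLimit, scenarioLimit, kmPerDegree = 111.2) {
  (scenarioLimit - baseLimit) * kmPerDegree
}

# one variable's similarity surface against its reference values
messOneVariable <- function(v, ref) {
  rmin <- min(ref); rmax <- max(ref)
  n <- length(ref)
  if (rmax == rmin) {
    warning("degenerate reference (single value); similarity 0 off-value",
            call. = FALSE)
    return(ifelse(v == rmin, 100, 0))
  }
  # f: percentage of reference points strictly below the cell value
  f <- 100 * vapply(v, function(x) sum(ref < x), numeric(1)) / n
  out <- numeric(length(v))
  out[f == 0] <- 100 * (v[f == 0] - rmin) / (rmax - rmin)
  sel <- f > 0 & f <= 50
  out[sel] <- 2 * f[sel]
  sel <- f > 50 & f < 100
  out[sel] <- 2 * (100 - f[sel])
  out[f == 100] <- 100 * (rmax - v[f == 100]) / (rmax - rmin)
  out[is.na(v)] <- NA
  out
}

#' Multivariate environmental similarity surface
#'
#' For each cell and variable, similarity follows the published MESS
#' definition: with `f` the percentage of reference points strictly below
#' the cell value and `(min, max)` the reference extremes,
#' `f = 0 -> 100 (v - min)/(max - min)`; `0 < f <= 50 -> 2 f`;
#' `50 < f < 100 -> 2 (100 - f)`; `f = 100 -> 100 (max - v)/(max - min)`.
#' The cell's similarity is the minimum over variables; negative values
#' flag climates outside the reference range (extrapolation), and the most
#' dissimilar variable is recorded.
#'
#' @param grids named list of [ClimateGrid-class], one per variable,
#'   shared geometry.
#' @param reference data.frame of reference-point values with the same
#'   variable names (>= 2 points per variable).
#' @param description label for the reference set.
#' @return a [MESSSurface-class].
#' @export
messSurface <- function(grids, reference,
                        description = sprintf("%d reference points",
                                              nrow(reference))) {
  vars <- names(grids)
  miss <- setdiff(vars, names(reference))
  if (length(miss)) {
    stop("reference lacks variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reference) < 2) {
    stop("need at least 2 reference points", call. = FALSE)
  }
  ref1 <- grids[[1]]
  sims <- lapply(vars, function(nm) {
    stopIfGeometryDiffers(ref1, grids[[nm]])
    matrix(messOneVariable(as.vector(grids[[nm]]@values),
                           reference[[nm]]),
           nrow(ref1@values), ncol(ref1@values))
  })
  arr <- simplify2array(sims)          # nr x nc x nvar
  sim <- apply(arr, c(1, 2), function(s) {
    if (all(is.na(s))) NA_real_ else min(s, na.rm = TRUE)
  })
  mdv <- apply(arr, c(1, 2), function(s) {
    if (all(is.na(s))) NA_integer_ else which.min(s)
  })
  new("MESSSurface", similarity = sim, mdvIndex = mdv, variables = vars,
      lat = ref1@lat, lon = ref1@lon, mask = ref1@mask,
      reference = description)
}

#' Project habitat under a set of warming levels and ensemble members
#'
#' Runs the projection chain — pattern-scaled scenario, probability map,
#' thresholded habitat, area fraction, northern limit and shift, MESS
#' novelty fraction — for every combination of warming level and ensemble
#' member, and summarises the across-member range per level.
#'
#' @param model a [FittedNicheModel-class].
#' @param tau probability threshold for habitat.
#' @param baseline named list of baseline [ClimateGrid-class], one per
#'   model predictor.
#' @param patterns named list of ensemble members; each member is a named
#'   list of [ScalingPattern-class], one per predictor.
#' @param warmingLevels warming levels X above preindustrial, degC
#'   (default `c(0.5, 1.5, 2, 3, 4)`; 0.5 is the baseline level).
#' @param offset preindustrial offset of the baseline, degC.
#' @param latMin,lonMin inclusive region bounds for the area fraction.
#' @param reference optional reference-point data.frame for MESS (columns =
#'   predictor names); when NULL the MESS column is `NA`.
#' @return data.frame with columns `warming_X, member, fraction,
#'   northern_limit_lat, shift_km, mess_negative_fraction`; the
#'   across-member min-max of the fraction per level is attached as
#'   attribute `"range"`.
#' @export
projectReport <- function(model, tau, baseline, patterns,
                          warmingLevels = c(0.5, 1.5, 2, 3, 4),
                          offset = 0.5, latMin = 35, lonMin = 136,
                          reference = NULL) {
  vars <- model@predictorNames
  baseProb <- predictGrid(model, baseline)
  baseHab <- thresholdMap(baseProb, tau)
  baseLimit <- suppressMessages(northernLimit(baseHab))
  rows <- list()
  for (X in warmingLevels) {
    members <- if (X == offset) list(baseline = NULL) else patterns
    for (m in names(members)) {
      scen <- if (X == offset) baseline else
        stats::setNames(lapply(vars, function(nm) {
          buildScenario(baseline[[nm]], patterns[[m]][[nm]], X, offset)
        }), vars)
      prob <- predictGrid(model, scen)
      hab <- thresholdMap(prob, tau)
      messNeg <- NA_real_
      if (!is.null(reference)) {
        ms <- suppressWarnings(messSurface(scen[vars], reference))
        s <- ms@similarity[ms@mask]
        messNeg <- mean(s < 0, na.rm = TRUE)
      }
      lim <- suppressMessages(northernLimit(hab))
      rows[[length(rows) + 1L]] <- data.frame(
        warming_X = X, member = m,
        fraction = habitatFraction(hab, latMin = latMin, lonMin = lonMin),
        northern_limit_lat = lim,
        shift_km = northwardShift(baseLimit, lim),
        mess_negative_fraction = messNeg
      )
    }
  }
  out <- do.call(rbind, rows)
  rng <- do.call(rbind, lapply(split(out, out$warming_X), function(d) {
    data.frame(warming_X = d$warming_X[1], fraction_min = min(d$fraction),
               fraction_max = max(d$fraction))
  }))
  rownames(rng) <- NULL
  attr(out, "range") <- rng
  out
}
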