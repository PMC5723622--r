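#' Kira's warmth index
#'
#' Annual sum of positive excesses of monthly mean temperature over +5 degC,
#' a classical heat-supply measure for plant growth (degC month).
#'
#' @param monthlyMeanTemp numeric vector of exactly 12 monthly mean
#'   temperatures, degC, January to December.
#' @return non-negative warmth index, degC month.
#' @seealso [coldnessIndex()], [seasonalPrecipSplit()]
#' @examples
#' warmthIndex(c(0, 0, 2, 6, 12, 18, 22, 24, 20, 14, 8, 2)) # 84
#' @export
warmthIndex <- function(monthlyMeanTemp) {
  checkMonthly(monthlyMeanTemp, "monthlyMeanTemp")
  sum(pmax(monthlyMeanTemp - 5, 0))
}

#' Kira's coldness index
#'
#' Annual sum of negative deficits of monthly mean temperature below +5 degC.
#' Stored with its negative sign (CI <= 0), so that
#' `warmthIndex(t) + coldnessIndex(t) == 12 * (mean(t) - 5)` exactly.
#'
#' @inheritParams warmthIndex
#' @return non-positive coldness index, degC month.
#' @examples
#' coldnessIndex(rep(0, 12)) # -60
#' @export
coldnessIndex <- function(monthlyMeanTemp) {
  checkMonthly(monthlyMeanTemp, "monthlyMeanTemp")
  sum(pmin(monthlyMeanTemp - 5, 0))
}

#' Split annual precipitation into growing and non-growing season
#'
#' Growing-season precipitation is the total over months whose mean
#' temperature is at least +5 degC (boundary inclusive); the remainder is
#' non-growing-season precipitation. The two always sum to the annual total.
#'
#' @inheritParams warmthIndex
#' @param monthlyPrecip numeric vector of 12 non-negative monthly
#'   precipitation totals, mm.
#' @return named numeric vector `c(growing = , nongrowing = )`, mm.
#' @export
seasonalPrecipSplit <- function(monthlyMeanTemp, monthlyPrecip) {
  checkMonthly(monthlyMeanTemp, "monthlyMeanTemp")
  checkMonthly(monthlyPrecip, "monthlyPrecip")
  if (any(monthlyPrecip < 0)) {
    stop("'monthlyPrecip' must be non-negative", call. = FALSE)
  }
  growing <- monthlyMeanTemp >= 5
  c(growing = sum(monthlyPrecip[growing]),
    nongrowing = sum(monthlyPrecip[!growing]))
}

checkMonthly <- function(x, name) {
  if (!is.numeric(x) || length(x) != 12L || anyNA(x)) {
    stop(sprintf("'%s' must be 12 non-missing numeric values", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Summarize a station climatology into niche-model predictors
#'
#' Collapses one station's monthly climatology into the predictor set used
#' for niche modelling: mean annual temperature, warmth and coldness
#' indices, annual / growing-season / non-growing-season precipitation, and
#' sun radiation. Provided annual extreme temperatures are carried through
#' after a consistency check against the monthly means.
#'
#' @param monthlyMeanTemp,monthlyPrecip 12 monthly values each (degC, mm).
#' @param tminYear,tmaxYear annual minimum/maximum air temperature, degC
#'   (taken as provided; derived from sub-daily records upstream). Optional.
#' @param radiation sun radiation, MJ m^-2 day^-1. Optional.
#' @return named list with elements `temp_mean`, `wi`, `ci`,
#'   `precip_annual`, `precip_growing`, `precip_nongrowing`, `tmin_year`,
#'   `tmax_year`, `radiation`.
#' @examples
#' summarizeClimatology(rep(5, 12), rep(100, 12))
#' @export
summarizeClimatology <- function(monthlyMeanTemp, monthlyPrecip,
                                 tminYear = NA_real_, tmaxYear = NA_real_,
                                 radiation = NA_real_) {
  checkMonthly(monthlyMeanTemp, "monthlyMeanTemp")
  checkMonthly(monthlyPrecip, "monthlyPrecip")
  if (!is.na(tminYear) && tminYear > min(monthlyMeanTemp) + 1e-9) {
    stop("'tminYear' exceeds the coldest monthly mean", call. = FALSE)
  }
  if (!is.na(tmaxYear) && tmaxYear < max(monthlyMeanTemp) - 1e-9) {
    stop("'tmaxYear' is below the warmest monthly mean", call. = FALSE)
  }
  split <- seasonalPrecipSplit(monthlyMeanTemp, monthlyPrecip)
  list(
    temp_mean = mean(monthlyMeanTemp),
    wi = warmthIndex(monthlyMeanTemp),
    ci = coldnessIndex(monthlyMeanTemp),
    precip_annual = sum(monthlyPrecip),
    precip_growing = unname(split["growing"]),
    precip_nongrowing = unname(split["nongrowing"]),
    tmin_year = tminYear,
    tmax_year = tmaxYear,
    radiation = radiation
  )
}

#' Summarize a station table into predictor columns
#'
#' Applies [summarizeClimatology()] to every row of a wide station table
#' (columns `t_01..t_12`, `p_01..p_12`, `tmin_year`, `tmax_year`,
#' `radiation`; see [readStationCsv()] for the full dictionary). When the
#' table holds several years per station (a `year` column is present),
#' indices are computed per station-year first and then averaged over the
#' window, not computed on averaged months.
#'
#' @param stations station data.frame in the wide dialect.
#' @return the input with summary columns `temp_mean`, `wi`, `ci`,
#'   `precip_annual`, `precip_growing`, `precip_nongrowing` appended; with
#'   a `year` column, one averaged row per station.
#' @export
summarizeStations <- function(stations) {
  tcols <- sprintf("t_%02d", 1:12)
  pcols <- sprintf("p_%02d", 1:12)
  missing <- setdiff(c(tcols, pcols), names(stations))
  if (length(missing)) {
    stop("missing monthly columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  one <- function(i) {
    s <- summarizeClimatology(
      as.numeric(stations[i, tcols]), as.numeric(stations[i, pcols]),
      tminYear = if ("tmin_year" %in% names(stations))
        stations$tmin_year[i] else NA_real_,
      tmaxYear = if ("tmax_year" %in% names(stations))
        stations$tmax_year[i] else NA_real_,
      radiation = if ("radiation" %in% names(stations))
        stations$radiation[i] else NA_real_
    )
    unlist(s[c("temp_mean", "wi", "ci", "precip_annual", "precip_growing",
               "precip_nongrowing")])
  }
  summ <- t(vapply(seq_len(nrow(stations)), one, numeric(6)))
  out <- cbind(stations, as.data.frame(summ))
  if ("year" %in% names(out) && anyDuplicated(out$id)) {
    # multi-year input: average the per-year summaries (and the per-year
    # monthly and extreme-temperature columns) within each station
    avg_cols <- intersect(
      c(tcols, pcols, "tmin_year", "tmax_year", "radiation",
        colnames(summ)),
      names(out)
    )
    keep <- setdiff(names(out), c(avg_cols, "year"))
    agg <- stats::aggregate(out[avg_cols], by = list(id = out$id), FUN = mean)
    first <- out[!duplicated(out$id), keep, drop = FALSE]
    out <- merge(first, agg, by = "id", sort = FALSE)
  }
  out
}
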