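stationMandatory <- c(
  "id", "lat", "lon", "alt",
  sprintf("t_%02d", 1:12), sprintf("p_%02d", 1:12),
  "tmin_year", "tmax_year", "radiation",
  "forest", "farmland", "building", "presence"
)

#' Read and validate a station occurrence table
#'
#' The station CSV is UTF-8, comma-separated, `.` decimal, header
#' mandatory. One row per station, wide form; mandatory columns:
#' `id` (unique), `lat`, `lon` (decimal degrees WGS84), `alt` (m),
#' `t_01..t_12` (monthly mean temperature, degC), `p_01..p_12` (monthly
#' precipitation, mm, non-negative), `tmin_year`, `tmax_year` (annual
#' extreme temperatures, degC), `radiation` (MJ m^-2 day^-1), land-use
#' ratios `forest`, `farmland`, `building` (each in \[0, 1\]), and binary
#' `presence`. Extra columns are preserved. Malformed rows are reported
#' with their line numbers.
#'
#' @param path CSV file path.
#' @return validated station data.frame.
#' @export
readStationCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(stationMandatory, names(df))
  if (length(miss)) {
    stop("station table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validateStations(df)
  df
}

validateStations <- function(df) {
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- character()
  if (anyDuplicated(df$id)) {
    bad <- c(bad, paste("duplicate station id(s):",
                        paste(unique(df$id[duplicated(df$id)]),
                              collapse = ", ")))
  }
  for (col in c("forest", "farmland", "building")) {
    out <- which(df[[col]] < 0 | df[[col]] > 1)
    if (length(out)) {
      bad <- c(bad, sprintf("%s outside [0,1] at line(s) %s", col,
                            paste(line[out], collapse = ", ")))
    }
  }
  pcols <- sprintf("p_%02d", 1:12)
  neg <- which(apply(df[pcols] < 0, 1, any))
  if (length(neg)) {
    bad <- c(bad, sprintf("negative precipitation at line(s) %s",
                          paste(line[neg], collapse = ", ")))
  }
  if (!all(df$presence %in% c(0, 1))) {
    out <- which(!df$presence %in% c(0, 1))
    bad <- c(bad, sprintf("non-binary presence at line(s) %s",
                          paste(line[out], collapse = ", ")))
  }
  if (length(bad)) {
    stop("invalid station table:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(df)
}

#' @rdname readStationCsv
#' @param stations validated station data.frame.
#' @export
writeStationCsv <- function(stations, path) {
  validateStations(stations)
  utils::write.csv(stations, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write a grid in ESRI ASCII format
#'
#' Plain-text raster interchange (the `.asc` dialect used throughout
#' species distribution modelling): a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' of cell values from the northernmost row down. Cell-centre coordinates
#' are reconstructed from the lower-left corner and cell size; NODATA cells
#' become masked `NA`s. Variable and period labels travel in a JSON
#' sidecar (`<path>.json`) when present.
#'
#' @param path `.asc` file path.
#' @param variable,period labels used if no sidecar exists.
#' @return [ClimateGrid-class] with latitude descending (row 1 = north).
#' @export
readAsciiGrid <- function(path, variable = "temperature",
                          period = "present") {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  lat <- hdr$yllcorner + (rev(seq_len(nr)) - 0.5) * hdr$cellsize
  lon <- hdr$xllcorner + (seq_len(nc) - 0.5) * hdr$cellsize
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    variable <- meta$variable %||% variable
    period <- meta$period %||% period
  }
  climateGrid(m, lat, lon, variable = variable, period = period)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readAsciiGrid
#' @param grid a [ClimateGrid-class]; its latitude/longitude spacing must
#'   be uniform and equal (square cells).
#' @param nodata value written for masked cells (default -9999).
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  lat <- grid@lat; lon <- grid@lon
  cs <- unique(round(c(abs(diff(lat)), diff(lon)), 10))
  if (length(cs) != 1) {
    stop("ASCII grids need uniform square cells", call. = FALSE)
  }
  v <- grid@values
  if (lat[1] < lat[length(lat)]) {          # stored south-up: flip
    v <- v[rev(seq_along(lat)), , drop = FALSE]
    lat <- rev(lat)
  }
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", length(lon)),
    sprintf("nrows %d", length(lat)),
    sprintf("xllcorner %.10g", min(lon) - cs / 2),
    sprintf("yllcorner %.10g", min(lat) - cs / 2),
    sprintf("cellsize %.10g", cs),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(variable = grid@variable, period = grid@period),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read/write a global anomaly series as two-column CSV
#'
#' Columns `year` and `anomaly` (degC relative to the reference year).
#'
#' @param path CSV path.
#' @param window,refYear,preindustrialOffset metadata of the series (the
#'   CSV stores only years and values).
#' @return [GlobalAnomalySeries-class].
#' @export
readAnomalyCsv <- function(path, window = 20, refYear = 1990,
                           preindustrialOffset = 0.5) {
  df <- utils::read.csv(path)
  if (!all(c("year", "anomaly") %in% names(df))) {
    stop("anomaly CSV needs columns 'year' and 'anomaly'", call. = FALSE)
  }
  new("GlobalAnomalySeries", years = as.numeric(df$year),
      anomaly = as.numeric(df$anomaly), window = window, refYear = refYear,
      preindustrialOffset = preindustrialOffset)
}

#' @rdname readAnomalyCsv
#' @param series a [GlobalAnomalySeries-class].
#' @export
writeAnomalyCsv <- function(series, path) {
  utils::write.csv(
    data.frame(year = series@years, anomaly = series@anomaly),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Materialize a small versioned fixture world
#'
#' Writes a complete synthetic input set — station CSV, baseline and
#' future grids per ensemble member (ESRI ASCII), anomaly CSV, and a
#' pipeline config YAML — into a directory, all derived from one seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param resolution grid cell size in degrees (default 0.5; coarse keeps
#'   the fixture small).
#' @param globalDTs named vector of global-mean warming divisors per
#'   ensemble member.
#' @return the config file path, invisibly.
#' @export
writeFixtureWorld <- function(dir, seed = 1L, resolution = 0.5,
                              globalDTs = c(ensemble_mean = 3.49,
                                            cluster1 = 3.57,
                                            cluster2 = 3.50,
                                            cluster3 = 3.41)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- syntheticWorldSpec(seed = seed)
  stations <- makeStations(spec)
  writeStationCsv(stations, file.path(dir, "stations.csv"))
  members <- list()
  for (i in seq_along(globalDTs)) {
    m <- names(globalDTs)[i]
    world <- makeGridWorld(resolution = resolution,
                           warming = c(1.8, 2.6) + 0.1 * (i - 1),
                           globalDT = globalDTs[[i]], spec = spec,
                           seed = seed)
    if (i == 1) {
      writeAsciiGrid(world$present$temp_mean,
                     file.path(dir, "present_temp.asc"))
      writeAsciiGrid(world$present$radiation,
                     file.path(dir, "present_rad.asc"))
    }
    writeAsciiGrid(world$future$temp_mean,
                   file.path(dir, sprintf("future_temp_%s.asc", m)))
    writeAsciiGrid(world$future$radiation,
                   file.path(dir, sprintf("future_rad_%s.asc", m)))
    members[[m]] <- list(
      global_dT = globalDTs[[i]],
      future = list(
        temp_mean = sprintf("future_temp_%s.asc", m),
        radiation = sprintf("future_rad_%s.asc", m)
      )
    )
  }
  writeAnomalyCsv(makeAnomalySeries(rate = 0.02),
                  file.path(dir, "anomaly.csv"))
  config <- list(
    stations = "stations.csv",
    anomaly = "anomaly.csv",
    out_dir = "out",
    predictors = c("temp_mean", "radiation"),
    warming_levels = c(1.5, 2, 3, 4),
    preindustrial_offset = 0.5,
    threshold = NULL,
    region = list(lat_min = 35, lon_min = 136),
    seed = as.integer(seed),
    grids = list(
      baseline = list(temp_mean = "present_temp.asc",
                      radiation = "present_rad.asc"),
      members = members
    )
  )
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  invisible(cfgPath)
}
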