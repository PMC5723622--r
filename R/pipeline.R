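#' Read and validate a pipeline configuration
#'
#' YAML configuration with keys: `stations` (station CSV), `anomaly`
#' (anomaly CSV), `grids` (`baseline`: predictor -> .asc path; `members`:
#' member -> `global_dT` + `future` predictor -> path), `predictors`
#' (model predictor columns; when omitted the model is selected by
#' [rankGlobalModels()]), `warming_levels`, `preindustrial_offset`,
#' `threshold` (fixed cutoff, or null for Youden-from-LOOCV), `region`
#' (`lat_min`, `lon_min`), `out_dir`, `seed`. Relative paths resolve
#' against the config file's directory; all referenced paths must exist at
#' validation time, and warming levels must be at least the offset.
#'
#' @param path YAML config path.
#' @return validated config list (classed `PipelineConfig`).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    full <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
    bad <- !file.exists(full)
    if (any(bad)) {
      stop("config references missing file(s): ",
           paste(full[bad], collapse = ", "), call. = FALSE)
    }
    full
  }
  cfg$stations <- resolve(cfg$stations)
  cfg$anomaly <- resolve(cfg$anomaly)
  cfg$grids$baseline <- lapply(cfg$grids$baseline, resolve)
  cfg$grids$members <- lapply(cfg$grids$members, function(m) {
    m$future <- lapply(m$future, resolve)
    m
  })
  cfg$warming_levels <- as.numeric(cfg$warming_levels %||% c(1.5, 2, 3, 4))
  cfg$preindustrial_offset <- cfg$preindustrial_offset %||% 0.5
  if (any(cfg$warming_levels < cfg$preindustrial_offset)) {
    stop("warming levels must be at least the preindustrial offset",
         call. = FALSE)
  }
  cfg$region <- cfg$region %||% list(lat_min = 35, lon_min = 136)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "out"
  if (!grepl("^(/|[A-Za-z]:)", cfg$out_dir)) {
    cfg$out_dir <- file.path(base, cfg$out_dir)
  }
  structure(cfg, class = "PipelineConfig")
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full niche-modelling and projection pipeline
#'
#' Orchestrates the stages in order: station ingestion, climatic indices,
#' collinearity screen, model selection or fit, LOOCV validation with
#' Youden threshold and metrics, pattern-scaled scenarios per ensemble
#' member, habitat projection, MESS, and report assembly. Deterministic
#' given the config and its seed; every stage logs its parameters. Outputs
#' (`model.json`, `metrics.json`, `screen.csv`, `report.csv`,
#' `report.json`, `exceedance.csv`) are written under the config's
#' `out_dir`.
#'
#' @param config a [readPipelineConfig()] result, or a path to one.
#' @return (invisibly) list with elements `stations`, `screen`, `model`,
#'   `scores`, `metrics`, `report`, `exceedance`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline halted at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  stations <- runStage("indices", {
    stageLog("indices", "reading %s", config$stations)
    summarizeStations(readStationCsv(config$stations))
  })

  screen <- runStage("screen", {
    vars <- intersect(c("temp_mean", "tmin_year", "tmax_year", "wi", "ci",
                        "precip_annual", "precip_growing",
                        "precip_nongrowing", "radiation"),
                      names(stations))
    collinearityScreen(stations[vars])
  })
  stageLog("screen", "%d collinear pair(s) flagged", sum(screen$flagged))

  model <- runStage("fit", {
    if (is.null(config$predictors)) {
      ranked <- rankGlobalModels(stations)
      best <- strsplit(ranked$terms[1], " \\+ ")[[1]]
      if (identical(best, "1")) best <- character()
      stageLog("fit", "AICc-selected terms: %s", ranked$terms[1])
      fitNicheModel(stations[best], stations$presence)
    } else {
      stageLog("fit", "fixed predictors: %s",
               paste(config$predictors, collapse = " + "))
      fitNicheModel(stations[unlist(config$predictors)],
                    stations$presence)
    }
  })

  val <- runStage("validate", {
    scores <- loocvScores(stations[model@predictorNames],
                          stations$presence)
    keep <- !is.na(scores)
    auc <- rocAuc(scores[keep], stations$presence[keep])
    tau <- if (is.null(config$threshold)) {
      youdenThreshold(scores[keep], stations$presence[keep])$threshold
    } else {
      config$threshold
    }
    counts <- confusionCounts(scores, stations$presence, tau)
    list(scores = scores,
         metrics = classificationMetrics(counts, auc = auc,
                                         threshold = tau))
  })
  stageLog("validate", "AUC %.3f, tau %.3f, MCC %.3f",
           val$metrics$auc, val$metrics$threshold, val$metrics$mcc)

  proj <- runStage("project", {
    preds <- model@predictorNames
    baseline <- stats::setNames(lapply(preds, function(nm) {
      readAsciiGrid(config$grids$baseline[[nm]])
    }), preds)
    patterns <- lapply(config$grids$members, function(m) {
      stats::setNames(lapply(preds, function(nm) {
        computeScalingPattern(baseline[[nm]],
                              readAsciiGrid(m$future[[nm]]),
                              m$global_dT)
      }), preds)
    })
    projectReport(
      model, val$metrics$threshold, baseline, patterns,
      warmingLevels = unique(c(config$preindustrial_offset,
                               config$warming_levels)),
      offset = config$preindustrial_offset,
      latMin = config$region$lat_min, lonMin = config$region$lon_min,
      reference = stations[preds]
    )
  })

  exceed <- runStage("exceedance", {
    if (is.null(config$anomaly)) return(NULL)
    series <- readAnomalyCsv(
      config$anomaly, preindustrialOffset = config$preindustrial_offset
    )
    data.frame(
      warming_X = config$warming_levels,
      year = vapply(config$warming_levels, function(X) {
        suppressMessages(exceedanceYear(series, X))
      }, numeric(1))
    )
  })

  runStage("report", {
    od <- config$out_dir
    jsonlite::write_json(
      list(predictors = model@predictorNames,
           coefficients = as.list(coef(model)),
           logLik = model@logLik, aicc = model@aicc, n = model@nObs),
      file.path(od, "model.json"), auto_unbox = TRUE, digits = NA
    )
    jsonlite::write_json(as.list(val$metrics),
                         file.path(od, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(screen, file.path(od, "screen.csv"),
                     row.names = FALSE)
    utils::write.csv(proj, file.path(od, "report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(report = proj, range = attr(proj, "range")),
      file.path(od, "report.json"), digits = NA
    )
    if (!is.null(exceed)) {
      utils::write.csv(exceed, file.path(od, "exceedance.csv"),
                       row.names = FALSE)
    }
    stageLog("report", "outputs written to %s", od)
  })

  invisible(list(stations = stations, screen = screen, model = model,
                 scores = val$scores, metrics = val$metrics,
                 report = proj, exceedance = exceed))
}
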