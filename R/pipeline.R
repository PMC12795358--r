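#' @include synthetic.R
NULL

#' Construct a pipeline configuration
#'
#' Defaults hold the study constants: years 2001-2023, repetitive threshold
#' 2 burn years, slope threshold 15 degrees (strict), majority fraction 0.5,
#' slope binarized before aggregation.
#'
#' @param burnPath directory of burn-date .asc rasters named with a 4-digit
#'   year (\code{burn_2001.asc}) and, in monthly mode, a 2-digit month
#'   (\code{burn_2001_07.asc}).
#' @param demPath,protectedPath,regionsPath,boundaryPath input file paths.
#' @param outputDir artifact directory.
#' @param burnPeriod "annual" or "monthly".
#' @param yearRange integer(2), default \code{c(2001, 2023)}.
#' @param repetitiveThreshold minimum burn years, default 2.
#' @param slopeThresholdDeg default 15.
#' @param steepFractionThreshold default 0.5.
#' @param slopeOrder "threshold_then_average" (default) or
#'   "average_then_threshold".
#' @param crsId analysis CRS identifier inputs must match.
#' @param regionNameField region-name attribute in the regions file.
#' @param allowGaps tolerate missing burn years (treated as no recorded
#'   burns), default FALSE.
#' @param seed recorded scenario seed (provenance only).
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(burnPath = "", demPath = "", protectedPath = "",
                           regionsPath = "", boundaryPath = "",
                           outputDir = "out", burnPeriod = "annual",
                           yearRange = c(2001L, 2023L),
                           repetitiveThreshold = 2L,
                           slopeThresholdDeg = 15,
                           steepFractionThreshold = 0.5,
                           slopeOrder = "threshold_then_average",
                           crsId = "EPSG:2100",
                           regionNameField = "region_name",
                           allowGaps = FALSE, seed = NA_integer_) {
  new("PipelineConfig",
      burnPath = burnPath, burnPeriod = burnPeriod, demPath = demPath,
      protectedPath = protectedPath, regionsPath = regionsPath,
      boundaryPath = boundaryPath, outputDir = outputDir,
      yearRange = as.integer(yearRange),
      repetitiveThreshold = as.integer(repetitiveThreshold),
      slopeThresholdDeg = as.numeric(slopeThresholdDeg),
      steepFractionThreshold = as.numeric(steepFractionThreshold),
      slopeOrder = slopeOrder, crsId = crsId,
      regionNameField = regionNameField,
      allowGaps = isTRUE(allowGaps), seed = as.integer(seed))
}

.configSlotNames <- function() {
  c("burnPath", "burnPeriod", "demPath", "protectedPath", "regionsPath",
    "boundaryPath", "outputDir", "yearRange", "repetitiveThreshold",
    "slopeThresholdDeg", "steepFractionThreshold", "slopeOrder", "crsId",
    "regionNameField", "allowGaps", "seed")
}

.configAsList <- function(config) {
  out <- lapply(.configSlotNames(), function(s) slot(config, s))
  stats::setNames(out, .configSlotNames())
}

#' Write a configuration file (YAML)
#' @param config a [PipelineConfig-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' Read a configuration file (YAML), with optional overrides
#'
#' @param path YAML file of configuration keys (as written by
#'   [writePipelineConfig()]); unknown keys are an error.
#' @param ... named overrides taking precedence over file keys (the CLI
#'   maps its flags here).
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .configSlotNames())
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipelineConfig, vals)
}

.burnFilePattern <- "burn_([0-9]{4})(_([0-9]{2}))?\\.asc$"

.listBurnFiles <- function(config) {
  files <- list.files(config@burnPath, pattern = .burnFilePattern,
                      full.names = TRUE)
  if (!length(files)) return(data.frame(path = character(), year = integer(),
                                        month = integer()))
  m <- regmatches(basename(files), regexec(.burnFilePattern, basename(files)))
  df <- data.frame(
    path = files,
    year = as.integer(vapply(m, `[`, character(1), 2)),
    month = suppressWarnings(as.integer(vapply(m, `[`, character(1), 4))),
    stringsAsFactors = FALSE
  )
  df <- df[df$year >= config@yearRange[1] & df$year <= config@yearRange[2], ]
  df[order(df$year, df$month), ]
}

#' Validate a pipeline configuration against its inputs
#'
#' Checks input existence, CRS consistency, grid alignment, burn-series
#' year coverage and the region-name attribute, without running any stage.
#'
#' @param config a [PipelineConfig-class].
#' @return list with \code{findings} (data.frame of \code{level}
#'   ("fatal"/"warning") and \code{message}) and \code{ok} (TRUE when no
#'   fatal finding).
#' @export
validateConfig <- function(config) {
  lvl <- character(); msg <- character()
  add <- function(level, message) {
    lvl <<- c(lvl, level); msg <<- c(msg, message)
  }
  bf <- .listBurnFiles(config)
  if (!nrow(bf)) {
    add("fatal", paste0("no burn rasters matching '", .burnFilePattern,
                        "' in ", config@burnPath))
  } else {
    wantYears <- seq(config@yearRange[1], config@yearRange[2])
    missing <- setdiff(wantYears, bf$year)
    if (length(missing)) {
      add(if (config@allowGaps) "warning" else "fatal",
          paste("year gap in burn series:", paste(missing, collapse = ", "),
                if (config@allowGaps) "(allowed; treated as no recorded burns)"
                else "(use allowGaps to proceed)"))
    }
    if (config@burnPeriod == "monthly" && anyNA(bf$month))
      add("fatal", "monthly mode but some burn filenames lack a month token")
    r1 <- tryCatch(readAsciiGrid(bf$path[1]), error = function(e) NULL)
    if (is.null(r1)) {
      add("fatal", paste("cannot read burn raster", bf$path[1]))
    } else if (!identical(r1@grid@crsId, config@crsId)) {
      add("fatal", sprintf("burn raster CRS '%s' does not match analysis CRS '%s'",
                           r1@grid@crsId, config@crsId))
    }
  }
  if (!file.exists(config@demPath)) {
    add("fatal", paste("missing DEM:", config@demPath))
  } else {
    dem <- tryCatch(readAsciiGrid(config@demPath), error = function(e) NULL)
    if (is.null(dem)) add("fatal", paste("cannot read DEM", config@demPath))
    else if (!identical(dem@grid@crsId, config@crsId))
      add("fatal", sprintf("DEM CRS '%s' does not match analysis CRS '%s'",
                           dem@grid@crsId, config@crsId))
  }
  for (p in c(protected = config@protectedPath, regions = config@regionsPath,
              boundary = config@boundaryPath)) {
    if (!file.exists(p)) add("fatal", paste("missing vector input:", p))
  }
  if (file.exists(config@regionsPath)) {
    reg <- tryCatch(readGeoJSON(config@regionsPath), error = function(e) NULL)
    if (is.null(reg)) {
      add("fatal", paste("cannot read regions file", config@regionsPath))
    } else {
      if (!(config@regionNameField %in% names(reg@attrs)))
        add("fatal", sprintf(
          "regions file lacks the region_name_field attribute '%s'",
          config@regionNameField))
      else if (anyDuplicated(reg@attrs[[config@regionNameField]]))
        add("fatal", "duplicate region names in regions file")
    }
  }
  findings <- data.frame(level = lvl, message = msg, stringsAsFactors = FALSE)
  list(findings = findings, ok = !any(findings$level == "fatal"))
}

.readRegions <- function(config) {
  reg <- readGeoJSON(config@regionsPath)
  if (!(config@regionNameField %in% names(reg@attrs)))
    stop("regions file lacks attribute '", config@regionNameField, "'")
  attrs <- reg@attrs
  attrs$region_name <- attrs[[config@regionNameField]]
  polygonSet(reg@geometries, attrs, crsId = reg@crsId, class_ = "RegionSet")
}

#' Run the full prioritization pipeline
#'
#' Executes fire history, terrain, protected areas and the overlay on the
#' configured inputs, writing all artifacts to \code{outputDir}:
#' \code{frequency.asc}, \code{repetitive_mask.asc}, \code{steep_mask.asc},
#' \code{protected_mask.asc}, \code{criteria_count.asc},
#' \code{preselection.asc}, \code{final_priority.asc},
#' \code{region_table.csv} (TOTAL row last), \code{area_by_frequency.csv},
#' \code{protected_inventory.csv}, \code{summary.txt} and
#' \code{run_log.json} (config echo, input checksums, per-stage pixel and
#' km2 chain, package version).  Any stage error aborts with the stage name
#' and removes partial outputs.
#'
#' @param config a [PipelineConfig-class].
#' @return a [PriorityResult-class], invisibly.
#' @export
runPipeline <- function(config) {
  outDir <- config@outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(obj, name) {
    p <- file.path(outDir, name)
    if (grepl("\\.asc$", name)) {
      writeAsciiGrid(obj, p)
      written <<- c(written, p, .prjPath(p))
    } else if (grepl("\\.csv$", name)) {
      utils::write.csv(obj, p, row.names = FALSE, quote = FALSE)
      written <<- c(written, p)
    }
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log <- list(
    package = "firepriority",
    version = as.character(utils::packageVersion("firepriority")),
    config = .configAsList(config),
    cell_size_policy = paste(
      "single pre-declared analysis grid; the 30 m product is aggregated",
      "explicitly by area-weighted averaging (no tool-driven max-of-inputs",
      "cell-size resampling)"),
    stages = list()
  )

  # --- fire history ------------------------------------------------------
  freq <- stage("fire_history", {
    bf <- .listBurnFiles(config)
    if (!nrow(bf)) stop("no burn rasters found in ", config@burnPath)
    composites <- if (config@burnPeriod == "monthly") {
      lapply(split(bf, bf$year), function(grp) {
        monthly <- lapply(grp$path, readAsciiGrid, bandMeaning = "burn day-of-year")
        annualComposite(monthly, grp$year[1])
      })
    } else {
      lapply(seq_len(nrow(bf)), function(i) {
        r <- readAsciiGrid(bf$path[i], bandMeaning = "burn day-of-year")
        new("BurnDateRaster", grid = r@grid, values = r@values,
            bandMeaning = r@bandMeaning, year = bf$year[i])
      })
    }
    wantYears <- seq(config@yearRange[1], config@yearRange[2])
    haveYears <- vapply(composites, function(r) r@year, integer(1))
    missing <- setdiff(wantYears, haveYears)
    if (length(missing)) {
      if (!config@allowGaps)
        stop("year gap in burn series: ", paste(missing, collapse = ", "))
      g <- composites[[1]]@grid
      zero <- matrix(0, g@nRows, g@nCols)
      composites <- c(composites, lapply(missing, function(y)
        new("BurnDateRaster", grid = g, values = zero,
            bandMeaning = "burn day-of-year (gap fill)", year = as.integer(y))))
    }
    if (!identical(composites[[1]]@grid@crsId, config@crsId))
      stop("burn raster CRS '", composites[[1]]@grid@crsId,
           "' does not match analysis CRS '", config@crsId, "'")
    burnFrequency(composites)
  })
  analysisGrid <- freq@grid
  fireMask <- repetitiveMask(freq, config@repetitiveThreshold)
  anyMask <- burnedAnyMask(freq)
  emit(freq, "frequency.asc")
  emit(fireMask, "repetitive_mask.asc")
  emit(frequencyAreaTable(freq), "area_by_frequency.csv")
  log$stages$fire_history <- list(
    years = as.list(config@yearRange),
    burned_any_km2 = maskAreaKm2(anyMask),
    repetitive_km2 = maskAreaKm2(fireMask),
    repetitive_pixels = sum(fireMask@values == 1, na.rm = TRUE)
  )

  # --- terrain -----------------------------------------------------------
  steep <- stage("terrain", {
    if (!file.exists(config@demPath))
      stop("missing DEM input: ", config@demPath)
    demR <- readAsciiGrid(config@demPath, bandMeaning = "elevation m")
    dem <- new("DEMRaster", grid = demR@grid, values = demR@values,
               bandMeaning = demR@bandMeaning)
    if (!identical(dem@grid@crsId, config@crsId))
      stop("DEM CRS '", dem@grid@crsId, "' does not match analysis CRS '",
           config@crsId, "'")
    slope <- computeSlope(dem)
    steepMask(slope, analysisGrid,
              thresholdDeg = config@slopeThresholdDeg,
              fractionThreshold = config@steepFractionThreshold,
              order = config@slopeOrder)
  })
  emit(steep, "steep_mask.asc")
  log$stages$terrain <- list(
    slope_threshold_deg = config@slopeThresholdDeg,
    steep_km2 = maskAreaKm2(steep),
    steep_pixels = sum(steep@values == 1, na.rm = TRUE)
  )

  # --- protected areas ---------------------------------------------------
  protStage <- stage("protected", {
    boundary <- readGeoJSON(config@boundaryPath)
    pas <- loadProtected(config@protectedPath, boundary, crsId = config@crsId)
    list(pas = pas, mask = rasterizeMask(pas, analysisGrid))
  })
  protMask <- protStage$mask
  emit(protMask, "protected_mask.asc")
  emit(protectedInventory(protStage$pas), "protected_inventory.csv")
  log$stages$protected <- list(
    n_polygons = length(protStage$pas@geometries),
    protected_km2 = maskAreaKm2(protMask),
    protected_pixels = sum(protMask@values == 1, na.rm = TRUE)
  )

  # --- overlay and tabulation -------------------------------------------
  result <- stage("prioritize", {
    regions <- .readRegions(config)
    if (!identical(regions@crsId, config@crsId))
      stop("regions CRS '", regions@crsId, "' does not match analysis CRS '",
           config@crsId, "'")
    prioritize(criteriaStack(fireMask, steep, protMask), regions)
  })
  emit(result@criteriaCount, "criteria_count.asc")
  emit(result@preselection, "preselection.asc")
  emit(result@final, "final_priority.asc")
  summ <- summarizeResult(result)
  emit(summ$table, "region_table.csv")
  writeLines(summ$text, file.path(outDir, "summary.txt"))
  written <- c(written, file.path(outDir, "summary.txt"))
  log$stages$prioritize <- list(
    preselection_km2 = maskAreaKm2(result@preselection),
    final_km2 = result@totalAreaKm2,
    final_pixels = sum(result@final@values == 1, na.rm = TRUE),
    regions_selected = summ$regionsSelected,
    consistency = summ$consistency
  )

  inputs <- c(.listBurnFiles(config)$path, config@demPath,
              config@protectedPath, config@regionsPath, config@boundaryPath)
  log$input_checksums <- as.list(tools::md5sum(inputs[file.exists(inputs)]))
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, file.path(outDir, "run_log.json"))
  ok <- TRUE
  invisible(result)
}
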