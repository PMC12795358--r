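#' @include prioritize.R
#' @include terrain.R
#' @include io-raster.R
#' @include io-geojson.R
NULL

# Self-contained study scenarios with planted ground truth.  The generator
# emulates the real inputs (a multi-year burn-date series on a 500 m grid,
# a 30 m DEM, protected-area and region polygons) closely enough to
# exercise every pipeline stage, while forcing known pixels to satisfy
# exactly 3 (planted), 2, 1 or 0 (decoys) criteria so the end-to-end final
# mask is known in advance.

.defaultDecoys <- function() list(
  fire_slope = matrix(c(20L, 20L), 1, 2),
  fire_protected = matrix(c(45L, 10L), 1, 2),
  slope_protected = matrix(c(15L, 45L), 1, 2),
  fire = matrix(c(50L, 50L), 1, 2),
  slope = matrix(c(5L, 30L), 1, 2),
  protected = matrix(c(55L, 20L), 1, 2),
  none = matrix(c(30L, 30L), 1, 2)
)

#' Construct a synthetic scenario
#'
#' Defaults describe the package's reference test scenario: a 60 x 60
#' analysis grid at 500 m nested over a 1000 x 1000 fine grid at 30 m
#' (same 30 km extent), a 23-year burn record (2001-2023), background burn
#' probability 0.05 per pixel-year with spatial clustering (correlation
#' length 5 cells) and one elevated-probability hotspot, a 5-degree base
#' terrain ramp with gentle Gaussian hills (compound slope everywhere below
#' 15 degrees except on forced steep patches of 25 degrees), protected
#' rectangles snapped to cell footprints, and a named 2 x 2 region
#' partition.
#'
#' Planted pixels are forced to burn in two distinct years, sit on a steep
#' patch and lie inside a protected rectangle; each decoy class is forced
#' to satisfy only its named criteria (the \code{slope_protected} decoys
#' burn exactly once, so lowering the repetitive threshold to 1 promotes
#' them into the final mask).
#'
#' @param seed master seed of the scenario's single RNG stream.
#' @param nAnalysis analysis grid rows = cols (500 m cells).
#' @param nFine fine grid rows = cols (30 m cells).
#' @param years integer(2), inclusive burn-record years.
#' @param burnProbBase background per-pixel-year burn probability.
#' @param smoothingLen correlation length (cells) of burn-probability
#'   clustering.
#' @param hotspots data.frame(row, col, radius_cells, prob).
#' @param planted integer matrix (row, col) of all-3-criteria pixels.
#' @param decoys named list of (row, col) matrices; names are criterion
#'   combinations from \{fire, slope, protected\} joined by "_", or "none".
#' @param crsId analysis CRS identifier.
#' @return a [SyntheticScenario-class].
#' @examples
#' s <- syntheticScenario(seed = 7)
#' s
#' @export
syntheticScenario <- function(seed = 1L, nAnalysis = 60L, nFine = 1000L,
                              years = c(2001L, 2023L),
                              burnProbBase = 0.05, smoothingLen = 5,
                              hotspots = data.frame(row = 28, col = 15,
                                                    radius_cells = 6, prob = 0.3),
                              planted = matrix(c(10L, 10L, 40L, 40L), 2, 2,
                                               byrow = TRUE),
                              decoys = .defaultDecoys(),
                              crsId = "EPSG:2100") {
  cellA <- 500; cellF <- 30
  extent <- nAnalysis * cellA
  ag <- gridSpec(nAnalysis, nAnalysis, cellSize = cellA,
                 originX = 0, originY = extent, crsId = crsId)
  nFineRows <- as.integer(ceiling(extent / cellF))
  if (nFine < nFineRows)
    stop("nFine must cover the analysis extent (need >= ", nFineRows, ")")
  fg <- gridSpec(nFine, nFine, cellSize = cellF,
                 originX = 0, originY = nFine * cellF, crsId = crsId)
  demSpec <- list(
    baseGradient = tan(5 * pi / 180),     # gentle eastward ramp
    hills = data.frame(cx = 15000, cy = 15000, sigma = 3000, amplitude = 120),
    steepGradient = tan(25 * pi / 180)    # forced steep patches
  )
  protectedSpec <- list(
    extras = list(
      list(type = "rect", name = "Synthetic reserve (lowland)",
           designation = "Wildlife Refuge", iucn_category = "Not Reported",
           xmin = 20000, ymin = 1000, xmax = 24000, ymax = 5000),
      list(type = "circle", name = "Synthetic park (circular)",
           designation = "National Park", iucn_category = "II",
           cx = 26000, cy = 26000, r = 1500)
    )
  )
  half <- nAnalysis %/% 2L
  regionsSpec <- data.frame(
    region_name = c("Northwest", "Northeast", "Southwest", "Southeast"),
    row0 = c(1L, 1L, half + 1L, half + 1L),
    row1 = c(half, half, nAnalysis, nAnalysis),
    col0 = c(1L, half + 1L, 1L, half + 1L),
    col1 = c(half, nAnalysis, half, nAnalysis),
    stringsAsFactors = FALSE
  )
  new("SyntheticScenario",
      seed = as.integer(seed), analysisGrid = ag, fineGrid = fg,
      years = as.integer(years), burnProbBase = burnProbBase,
      hotspots = hotspots, smoothingLen = as.numeric(smoothingLen),
      demSpec = demSpec, protectedSpec = protectedSpec,
      regionsSpec = regionsSpec,
      planted = planted, decoys = decoys)
}

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario (seed", object@seed, ")\n")
  cat("  analysis grid:", .fmtGrid(object@analysisGrid), "\n")
  cat("  fine grid:    ", .fmtGrid(object@fineGrid), "\n")
  cat("  years:", object@years[1], "-", object@years[2],
      "| base burn prob:", object@burnProbBase, "\n")
  cat("  planted pixels:", nrow(object@planted),
      "| decoy classes:", paste(names(object@decoys), collapse = ", "), "\n")
})

# which special pixels carry each forced criterion
.specialsWith <- function(s, what) {
  res <- list(s@planted)
  for (nm in names(s@decoys)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (what %in% parts) res <- c(res, list(s@decoys[[nm]]))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

.allSpecials <- function(s) {
  rbind(s@planted, do.call(rbind, c(s@decoys, list(matrix(integer(), 0, 2)))))
}

# moving-average smoother with edge renormalization (square window)
.boxSmooth <- function(m, len) {
  w <- max(1L, as.integer(round(len)))
  if (w <= 1L) return(m)
  k <- rep(1, w)
  sm1 <- function(x) {
    n <- length(x)
    num <- stats::filter(x, k, sides = 2)
    den <- stats::filter(rep(1, n), k, sides = 2)
    # filter() leaves NA at edges; fall back to shrinking windows
    na <- which(is.na(num))
    for (i in na) {
      lo <- max(1L, i - w %/% 2L); hi <- min(n, i + w %/% 2L)
      num[i] <- sum(x[lo:hi]); den[i] <- hi - lo + 1L
    }
    as.numeric(num / den)
  }
  m <- apply(m, 2L, sm1)
  t(apply(m, 1L, sm1))
}

# deterministic forced burn years for the k-th special pixel
.forcedYears <- function(k, years, nBurnYears) {
  ny <- years[2] - years[1] + 1L
  if (nBurnYears == 0L) return(integer())
  y1 <- years[1] + ((k - 1L) %% ny)
  if (nBurnYears == 1L) return(y1)
  y2 <- years[1] + ((k - 1L + ny %/% 2L) %% ny)
  if (y2 == y1) y2 <- years[1] + (k %% ny)
  c(y1, y2)
}

.monthBreaks <- c(0, 31, 60, 91, 121, 152, 182, 213, 244, 274, 305, 335, 366)

#' Generate the synthetic burn-date raster series
#'
#' One RNG stream seeded once; consumption order is documented and fixed:
#' first the spatial clustering noise field, then for each year the burn
#' draws, then that year's day-of-year draws.  Forced burns at planted and
#' decoy pixels are deterministic functions of the pixel index and consume
#' no randomness, so changing the planted layout does not perturb the
#' background fire realization.
#'
#' @param s a [SyntheticScenario-class].
#' @param period \code{"annual"} (default) for one [BurnDateRaster-class]
#'   per year, or \code{"monthly"} for 12 monthly rasters per year (the
#'   annual maximum-composite of which reproduces the annual series).
#' @return for \code{"annual"}, a list of [BurnDateRaster-class]; for
#'   \code{"monthly"}, a named list (one element per year) of lists of 12
#'   [GeoRaster-class] monthly burn-date rasters.
#' @export
makeFireSeries <- function(s, period = c("annual", "monthly")) {
  period <- match.arg(period)
  g <- s@analysisGrid
  n <- g@nRows * g@nCols
  years <- seq(s@years[1], s@years[2])
  set.seed(s@seed)
  noise <- matrix(stats::runif(n), g@nRows, g@nCols)
  field <- .boxSmooth(noise, s@smoothingLen)
  # modulate through the complement power so the degenerate probabilities 0
  # and 1 stay exact and small probabilities scale ~ linearly with the field
  w <- field / mean(field)
  p <- 1 - (1 - s@burnProbBase)^w
  if (nrow(s@hotspots)) {
    rows <- matrix(seq_len(g@nRows), g@nRows, g@nCols)
    cols <- matrix(rep(seq_len(g@nCols), each = g@nRows), g@nRows, g@nCols)
    for (h in seq_len(nrow(s@hotspots))) {
      d2 <- (rows - s@hotspots$row[h])^2 + (cols - s@hotspots$col[h])^2
      inside <- d2 <= s@hotspots$radius_cells[h]^2
      p[inside] <- pmax(p[inside], s@hotspots$prob[h])
    }
  }
  p <- pmin(pmax(p, 0), 1)

  specials <- .allSpecials(s)
  specialIdx <- if (nrow(specials))
    specials[, 1] + (specials[, 2] - 1L) * g@nRows else integer()
  # forced burn-year map: specials with "fire" burn in 2 years, the
  # slope_protected decoys in exactly 1, all other specials in none
  forced <- new.env()
  addForced <- function(px, nBurn, offset) {
    if (is.null(px) || !nrow(px)) return()
    for (k in seq_len(nrow(px))) {
      key <- paste(px[k, 1], px[k, 2])
      assign(key, .forcedYears(k + offset, s@years, nBurn), envir = forced)
    }
  }
  addForced(s@planted, 2L, 0L)
  off <- nrow(s@planted)
  for (nm in names(s@decoys)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    nBurn <- if ("fire" %in% parts) 2L else if (nm == "slope_protected") 1L else 0L
    addForced(s@decoys[[nm]], nBurn, off)
    off <- off + nrow(s@decoys[[nm]])
  }

  out <- vector("list", length(years))
  names(out) <- years
  for (yi in seq_along(years)) {
    burn <- matrix(stats::runif(n), g@nRows, g@nCols) < p
    doy <- ceiling(matrix(stats::runif(n), g@nRows, g@nCols) * 366)
    if (nrow(specials)) {
      for (k in seq_len(nrow(specials))) {
        key <- paste(specials[k, 1], specials[k, 2])
        fy <- get(key, envir = forced)
        hit <- years[yi] %in% fy
        burn[specials[k, 1], specials[k, 2]] <- hit
        if (hit)  # deterministic DOY for forced burns
          doy[specials[k, 1], specials[k, 2]] <- 100 + (7 * k) %% 250
      }
    }
    annual <- ifelse(burn, doy, 0)
    if (period == "annual") {
      out[[yi]] <- new("BurnDateRaster", grid = g, values = annual,
                       bandMeaning = "burn day-of-year",
                       year = years[yi])
    } else {
      months <- vector("list", 12L)
      for (m in 1:12) {
        inMonth <- annual > .monthBreaks[m] & annual <= .monthBreaks[m + 1]
        months[[m]] <- geoRaster(ifelse(inMonth, annual, 0), g,
                                 bandMeaning = sprintf("burn day-of-year (month %02d)", m))
      }
      out[[yi]] <- months
    }
  }
  out
}

#' Generate the synthetic DEM
#'
#' Deterministic terrain on the fine grid: a planar base ramp plus Gaussian
#' hills (compound gradient kept below the steep threshold), overwritten by
#' local 25-degree planes on the footprints of every pixel that must
#' satisfy the steep-slope criterion (planted pixels and slope-bearing
#' decoys).  Horn's estimator is exact on planes, so the slope inside each
#' patch is analytically known.
#'
#' @param s a [SyntheticScenario-class].
#' @return a [DEMRaster-class] on the fine grid.
#' @export
makeDEM <- function(s) {
  fg <- s@fineGrid
  ctr <- cellCenters(fg)
  X <- matrix(rep(ctr$x, each = fg@nRows), fg@nRows, fg@nCols)
  Y <- matrix(rep(ctr$y, times = fg@nCols), fg@nRows, fg@nCols)
  z <- s@demSpec$baseGradient * X
  hills <- s@demSpec$hills
  if (!is.null(hills) && nrow(hills)) {
    for (h in seq_len(nrow(hills))) {
      z <- z + hills$amplitude[h] *
        exp(-((X - hills$cx[h])^2 + (Y - hills$cy[h])^2) / (2 * hills$sigma[h]^2))
    }
  }
  steepPx <- .specialsWith(s, "slope")
  ag <- s@analysisGrid
  sg <- s@demSpec$steepGradient
  if (nrow(steepPx)) {
    for (k in seq_len(nrow(steepPx))) {
      r <- steepPx[k, 1]; cl <- steepPx[k, 2]
      x0 <- ag@originX + (cl - 1) * ag@cellSizeX
      x1 <- x0 + ag@cellSizeX
      y1 <- ag@originY - (r - 1) * ag@cellSizeY
      y0 <- y1 - ag@cellSizeY
      inFoot <- X >= x0 & X < x1 & Y > y0 & Y <= y1
      xc <- (x0 + x1) / 2; yc <- (y0 + y1) / 2
      zc <- s@demSpec$baseGradient * xc
      z[inFoot] <- zc + sg * (X[inFoot] - xc)
    }
  }
  new("DEMRaster", grid = fg, values = z, bandMeaning = "elevation m")
}

#' Generate the synthetic vector inputs
#'
#' Protected rectangles snapped exactly to the footprints of every pixel
#' that must satisfy the protected-area criterion, plus the scenario's
#' extra shapes; regions as a rectangular partition of the grid; land
#' boundary as the grid envelope.
#'
#' @param s a [SyntheticScenario-class].
#' @return list with \code{protected} ([ProtectedAreaSet-class]),
#'   \code{regions} ([RegionSet-class]) and \code{boundary} (single-feature
#'   [PolygonSet-class]).
#' @export
makeVectors <- function(s) {
  ag <- s@analysisGrid
  footRect <- function(r, cl) {
    x0 <- ag@originX + (cl - 1) * ag@cellSizeX
    y1 <- ag@originY - (r - 1) * ag@cellSizeY
    rectRing(x0, y1 - ag@cellSizeY, x0 + ag@cellSizeX, y1)
  }
  protPx <- .specialsWith(s, "protected")
  geoms <- list(); nm <- ch <- iu <- character()
  if (nrow(protPx)) {
    for (k in seq_len(nrow(protPx))) {
      geoms <- c(geoms, list(footRect(protPx[k, 1], protPx[k, 2])))
      nm <- c(nm, sprintf("Synthetic PA %02d", k))
      ch <- c(ch, "Protected Landscape")
      iu <- c(iu, "V")
    }
  }
  for (e in s@protectedSpec$extras) {
    ring <- if (e$type == "rect") rectRing(e$xmin, e$ymin, e$xmax, e$ymax)
            else circleRing(e$cx, e$cy, e$r)
    geoms <- c(geoms, list(ring))
    nm <- c(nm, e$name); ch <- c(ch, e$designation); iu <- c(iu, e$iucn_category)
  }
  protected <- polygonSet(
    geoms,
    data.frame(name = nm, designation = ch, iucn_category = iu,
               marine_flag = rep(FALSE, length(nm)), stringsAsFactors = FALSE),
    crsId = ag@crsId, class_ = "ProtectedAreaSet"
  )

  rs <- s@regionsSpec
  cover <- matrix(0L, ag@nRows, ag@nCols)
  for (k in seq_len(nrow(rs)))
    cover[rs$row0[k]:rs$row1[k], rs$col0[k]:rs$col1[k]] <-
      cover[rs$row0[k]:rs$row1[k], rs$col0[k]:rs$col1[k]] + 1L
  if (any(cover != 1L))
    stop("regionsSpec rectangles must partition the analysis grid exactly ",
         "(found overlap or gap)")
  regionGeoms <- lapply(seq_len(nrow(rs)), function(k) {
    x0 <- ag@originX + (rs$col0[k] - 1) * ag@cellSizeX
    x1 <- ag@originX + rs$col1[k] * ag@cellSizeX
    y1 <- ag@originY - (rs$row0[k] - 1) * ag@cellSizeY
    y0 <- ag@originY - rs$row1[k] * ag@cellSizeY
    rectRing(x0, y0, x1, y1)
  })
  regions <- polygonSet(regionGeoms,
                        data.frame(region_name = rs$region_name,
                                   stringsAsFactors = FALSE),
                        crsId = ag@crsId, class_ = "RegionSet")

  env <- rectRing(ag@originX, ag@originY - ag@nRows * ag@cellSizeY,
                  ag@originX + ag@nCols * ag@cellSizeX, ag@originY)
  boundary <- polygonSet(list(env), data.frame(name = "land",
                                               stringsAsFactors = FALSE),
                         crsId = ag@crsId)
  list(protected = protected, regions = regions, boundary = boundary)
}

#' Ground truth of a scenario
#'
#' @param s a [SyntheticScenario-class].
#' @return list with \code{planted} (matrix of all-3-criteria pixels) and
#'   \code{decoys} (named list of matrices by criterion combination).
#' @export
scenarioTruth <- function(s) list(planted = s@planted, decoys = s@decoys)

#' Write a scenario to disk as pipeline-ready inputs
#'
#' Emits burn-date rasters (one .asc per year, or 12 per year in monthly
#' mode), the DEM, protected / region / land-boundary GeoJSON, the ground
#' truth (\code{truth.json}) and a ready-to-run pipeline configuration
#' (\code{config.yaml}).
#'
#' @param s a [SyntheticScenario-class].
#' @param dir output directory (created if missing).
#' @param period \code{"annual"} (default) or \code{"monthly"}.
#' @return the directory path, invisibly.
#' @export
writeScenario <- function(s, dir, period = c("annual", "monthly")) {
  period <- match.arg(period)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  burnDir <- file.path(dir, "burn")
  dir.create(burnDir, showWarnings = FALSE)
  series <- makeFireSeries(s, period = period)
  if (period == "annual") {
    for (r in series)
      writeAsciiGrid(r, file.path(burnDir, sprintf("burn_%d.asc", r@year)))
  } else {
    for (yr in names(series)) {
      for (m in seq_len(12L))
        writeAsciiGrid(series[[yr]][[m]],
                       file.path(burnDir, sprintf("burn_%s_%02d.asc", yr, m)))
    }
  }
  writeAsciiGrid(makeDEM(s), file.path(dir, "dem.asc"))
  vec <- makeVectors(s)
  writeGeoJSON(vec$protected, file.path(dir, "protected.geojson"))
  writeGeoJSON(vec$regions, file.path(dir, "regions.geojson"))
  writeGeoJSON(vec$boundary, file.path(dir, "boundary.geojson"))
  tr <- scenarioTruth(s)
  jsonlite::write_json(
    list(planted = unname(apply(tr$planted, 1L, function(p) as.list(p),
                                simplify = FALSE)),
         decoys = lapply(tr$decoys, function(m)
           unname(apply(m, 1L, function(p) as.list(p), simplify = FALSE)))),
    file.path(dir, "truth.json"), auto_unbox = TRUE
  )
  cfg <- pipelineConfig(
    burnPath = burnDir, burnPeriod = period,
    demPath = file.path(dir, "dem.asc"),
    protectedPath = file.path(dir, "protected.geojson"),
    regionsPath = file.path(dir, "regions.geojson"),
    boundaryPath = file.path(dir, "boundary.geojson"),
    outputDir = file.path(dir, "out"),
    yearRange = s@years, crsId = s@analysisGrid@crsId, seed = s@seed
  )
  writePipelineConfig(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
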