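#' @import methods
NULL

#' Analysis grid geometry
#'
#' A \code{GridSpec} fixes the geometry every raster in a run must share: a
#' projected coordinate reference system (CRS), the coordinates of the outer
#' (top-left) corner of pixel (1,1), the pixel edge lengths in meters, the
#' raster dimensions, and the nodata sentinel used when the raster is written
#' to disk.  Rows run north to south, columns west to east.  In memory,
#' nodata cells are represented as \code{NA}; the sentinel only matters at
#' the file boundary.
#'
#' Two grids are \emph{aligned} when they share the CRS id and cell sizes and
#' their origins differ by integer multiples of the cell size (tolerance
#' 1e-6 of a cell, to absorb floating-point transforms).  All overlay
#' operations refuse unaligned inputs.
#'
#' @slot crsId character(1), identifier of a projected CRS (e.g. "EPSG:2100").
#'   Geographic (degree-unit) identifiers such as "EPSG:4326" are accepted by
#'   the container but refused by area computations.
#' @slot originX,originY numeric(1), map coordinates (meters) of the
#'   top-left corner of the top-left pixel.
#' @slot cellSizeX,cellSizeY numeric(1), positive pixel edge lengths (m).
#' @slot nRows,nCols integer(1), positive raster dimensions.
#' @slot nodata numeric(1), sentinel written for \code{NA} cells on disk.
#'
#' @seealso [gridSpec()], [isAligned()], [pixelAreaKm2()]
#' @exportClass GridSpec
setClass("GridSpec",
  representation(
    crsId = "character",
    originX = "numeric", originY = "numeric",
    cellSizeX = "numeric", cellSizeY = "numeric",
    nRows = "integer", nCols = "integer",
    nodata = "numeric"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@crsId) != 1L || is.na(object@crsId) || !nzchar(object@crsId))
    msg <- c(msg, "crsId must be a single non-empty string")
  for (s in c("originX", "originY", "cellSizeX", "cellSizeY", "nodata")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste(s, "must be a single finite number"))
  }
  if (length(object@cellSizeX) == 1L && is.finite(object@cellSizeX) && object@cellSizeX <= 0)
    msg <- c(msg, "cellSizeX must be > 0")
  if (length(object@cellSizeY) == 1L && is.finite(object@cellSizeY) && object@cellSizeY <= 0)
    msg <- c(msg, "cellSizeY must be > 0")
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 1L)
    msg <- c(msg, "nRows must be a positive integer")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 1L)
    msg <- c(msg, "nCols must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Raster on a GridSpec
#'
#' The basic raster container: a numeric matrix of dimension
#' \code{nRows x nCols} carried on a [GridSpec-class], with \code{NA}
#' marking nodata cells and a free-text band label.  Specialised rasters
#' (burn-date composites, fire frequency, DEM, slope, criterion masks)
#' extend this class.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric matrix, \code{dim == c(nRows, nCols)} of the grid.
#' @slot bandMeaning character(1) label, e.g. \code{"slope degrees"}.
#'
#' @seealso [geoRaster()], [rasterValues()], [gridGeometry()]
#' @exportClass GeoRaster
setClass("GeoRaster",
  representation(
    grid = "GridSpec",
    values = "matrix",
    bandMeaning = "character"
  )
)

setValidity("GeoRaster", function(object) {
  msg <- character()
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (!identical(dim(object@values), c(object@grid@nRows, object@grid@nCols)))
    msg <- c(msg, sprintf(
      "values dimensions (%d x %d) do not match grid (%d x %d)",
      nrow(object@values), ncol(object@values),
      object@grid@nRows, object@grid@nCols
    ))
  if (length(object@bandMeaning) != 1L)
    msg <- c(msg, "bandMeaning must be a single string")
  if (length(msg)) msg else TRUE
})

#' Annual burn-date composite
#'
#' Per-pixel day-of-year (1..366) of the most recent burn within one calendar
#' year, 0 for pixels that did not burn that year, \code{NA} where the source
#' record is unmapped (water, permanent fill).
#'
#' @slot year integer(1), the calendar year of the composite.
#' @exportClass BurnDateRaster
setClass("BurnDateRaster",
  contains = "GeoRaster",
  representation(year = "integer")
)

setValidity("BurnDateRaster", function(object) {
  v <- object@values
  ok <- is.na(v) | v == 0 | (v >= 1 & v <= 366)
  if (!all(ok)) return("burn-date values must be 0, 1..366 or NA")
  if (length(object@year) != 1L || is.na(object@year)) return("year must be a single integer")
  TRUE
})

#' Fire-frequency raster
#'
#' Per-pixel count of years (within an inclusive year range) in which the
#' annual burn composite was positive.
#'
#' @slot yearRange integer(2), first and last year, inclusive.
#' @exportClass FireFrequencyRaster
setClass("FireFrequencyRaster",
  contains = "GeoRaster",
  representation(yearRange = "integer")
)

setValidity("FireFrequencyRaster", function(object) {
  if (length(object@yearRange) != 2L || any(is.na(object@yearRange)) ||
      object@yearRange[2] < object@yearRange[1])
    return("yearRange must be two ordered years")
  nyears <- object@yearRange[2] - object@yearRange[1] + 1L
  v <- object@values
  ok <- is.na(v) | (v >= 0 & v <= nyears)
  if (!all(ok)) return(sprintf("frequency values must lie in 0..%d or NA", nyears))
  TRUE
})

#' Digital elevation model raster
#'
#' Elevation in meters above the reference surface, on a fine (e.g. 30 m)
#' projected grid.
#' @exportClass DEMRaster
setClass("DEMRaster", contains = "GeoRaster")

#' Slope raster
#'
#' Terrain slope in degrees, \code{[0, 90)} where not nodata.
#' @exportClass SlopeRaster
setClass("SlopeRaster", contains = "GeoRaster")

setValidity("SlopeRaster", function(object) {
  v <- object@values
  ok <- is.na(v) | (v >= 0 & v < 90)
  if (!all(ok)) return("slope values must lie in [0, 90) or be NA")
  TRUE
})

.CRITERION_LABELS <- c("repetitive_fire", "steep_slope", "protected_area")

#' Boolean criterion mask
#'
#' A raster of \{0, 1, NA\} on the shared analysis grid, labelled with the
#' prioritization criterion it encodes: \code{"repetitive_fire"},
#' \code{"steep_slope"} or \code{"protected_area"}.
#'
#' @slot criterionLabel character(1), one of the three criterion labels.
#' @exportClass CriterionMask
setClass("CriterionMask",
  contains = "GeoRaster",
  representation(criterionLabel = "character")
)

setValidity("CriterionMask", function(object) {
  v <- object@values
  if (!all(is.na(v) | v %in% c(0, 1)))
    return("criterion mask values must be 0, 1 or NA")
  if (length(object@criterionLabel) != 1L ||
      !(object@criterionLabel %in% .CRITERION_LABELS))
    return(sprintf("criterionLabel must be one of: %s",
                   paste(.CRITERION_LABELS, collapse = ", ")))
  TRUE
})

#' Stack of the three criterion masks
#'
#' Exactly three [CriterionMask-class] objects with distinct labels covering
#' the full criterion set, mutually aligned on the analysis grid.
#'
#' @slot masks list of three \code{CriterionMask}.
#' @seealso [criteriaStack()], [criteriaCount()]
#' @exportClass CriteriaStack
setClass("CriteriaStack", representation(masks = "list"))

setValidity("CriteriaStack", function(object) {
  m <- object@masks
  if (length(m) != 3L || !all(vapply(m, is, logical(1), "CriterionMask")))
    return("masks must be a list of exactly three CriterionMask objects")
  labs <- vapply(m, function(x) x@criterionLabel, character(1))
  if (!setequal(labs, .CRITERION_LABELS) || anyDuplicated(labs))
    return("mask labels must be exactly {repetitive_fire, steep_slope, protected_area}")
  if (!(isAligned(m[[1]], m[[2]]) && isAligned(m[[1]], m[[3]])))
    return("all masks must share an aligned grid")
  TRUE
})

#' Polygon feature set
#'
#' A light container for polygon features in the analysis CRS.  Each
#' geometry is a list of rings; a ring is an n x 2 coordinate matrix
#' (unclosed).  The first ring of a polygon is its exterior; interior
#' rings are interpreted by the even-odd rule, so holes and multi-part
#' polygons are both expressed as extra rings.  Feature attributes live in a
#' parallel data.frame.
#'
#' @slot geometries list; element i is the list of rings of feature i.
#' @slot attrs data.frame with one row per feature.
#' @slot crsId character(1) CRS identifier.
#' @exportClass PolygonSet
setClass("PolygonSet",
  representation(geometries = "list", attrs = "data.frame", crsId = "character")
)

setValidity("PolygonSet", function(object) {
  if (nrow(object@attrs) != length(object@geometries))
    return("attrs must have one row per geometry")
  for (g in object@geometries) {
    if (!is.list(g) || !length(g))
      return("each geometry must be a non-empty list of rings")
    for (r in g) {
      if (!is.matrix(r) || ncol(r) != 2L || nrow(r) < 3L)
        return("each ring must be an n x 2 matrix with n >= 3")
      if (!all(is.finite(r))) return("ring coordinates must be finite")
    }
  }
  TRUE
})

#' Protected-area polygons
#'
#' A [PolygonSet-class] whose attributes carry the inventory fields of a
#' protected-area database export: \code{name}, \code{designation},
#' \code{iucn_category} (possibly "Not Reported") and \code{marine_flag}.
#' @exportClass ProtectedAreaSet
setClass("ProtectedAreaSet", contains = "PolygonSet")

setValidity("ProtectedAreaSet", function(object) {
  need <- c("name", "designation", "iucn_category")
  miss <- setdiff(need, names(object@attrs))
  if (length(miss))
    return(paste("missing attribute columns:", paste(miss, collapse = ", ")))
  TRUE
})

#' Administrative region polygons
#'
#' A [PolygonSet-class] with a unique \code{region_name} per feature.  The
#' feature order is the stable tie-break order used when a pixel center lies
#' on a shared boundary during zonal tabulation.
#' @exportClass RegionSet
setClass("RegionSet", contains = "PolygonSet")

setValidity("RegionSet", function(object) {
  if (!("region_name" %in% names(object@attrs)))
    return("attrs must contain a region_name column")
  nm <- object@attrs$region_name
  if (anyDuplicated(nm)) return("region names must be unique")
  TRUE
})

#' Result of the prioritization overlay
#'
#' Bundles the criteria-count raster (0..3 satisfied criteria per pixel),
#' the preselection mask (at least two criteria), the final priority mask
#' (all three), the per-region area table and the total selected area.
#'
#' @slot criteriaCount [GeoRaster-class] of integer counts 0..3.
#' @slot preselection,final boolean [GeoRaster-class] masks.
#' @slot regionTable data.frame with columns \code{region},
#'   \code{pixel_count}, \code{area_km2} (one row per region, plus
#'   \code{_unassigned} when selected pixels fall outside every region).
#' @slot totalAreaKm2 numeric(1), final mask pixel count times pixel area.
#' @seealso [prioritize()], [summarizeResult()]
#' @exportClass PriorityResult
setClass("PriorityResult",
  representation(
    criteriaCount = "GeoRaster",
    preselection = "GeoRaster",
    final = "GeoRaster",
    regionTable = "data.frame",
    totalAreaKm2 = "numeric"
  )
)

setValidity("PriorityResult", function(object) {
  pre <- object@preselection@values
  fin <- object@final@values
  bad <- !is.na(fin) & fin == 1 & (is.na(pre) | pre != 1)
  if (any(bad)) return("final mask must be a subset of the preselection mask")
  need <- c("region", "pixel_count", "area_km2")
  if (!all(need %in% names(object@regionTable)))
    return("regionTable must have columns region, pixel_count, area_km2")
  TRUE
})

#' Synthetic study scenario
#'
#' Parameter bundle from which all synthetic inputs (burn-date series, DEM,
#' protected/region polygons, land boundary) are rebuilt deterministically.
#' Planted pixels are forced to satisfy all three criteria; decoy pixels are
#' forced to satisfy exactly 0, 1 or 2 named criteria, so an end-to-end run
#' has an exactly known final mask.
#'
#' Pixel coordinates in \code{planted} and \code{decoys} are rows of
#' \code{(row, col)} matrices on the analysis grid (1-based, row 1 = north).
#' \code{decoys} is a named list keyed by criterion combination, e.g.
#' \code{"fire_slope"}, \code{"protected"}, \code{"none"}.
#'
#' @slot seed integer(1), master seed of the single RNG stream.
#' @slot analysisGrid,fineGrid [GridSpec-class] for the 500 m analysis grid
#'   and the nested fine (DEM) grid.
#' @slot years integer(2), first and last burn-record year, inclusive.
#' @slot burnProbBase numeric(1), background per-pixel-year burn probability.
#' @slot hotspots data.frame (row, col, radius_cells, prob) of elevated-burn
#'   foci on the analysis grid.
#' @slot smoothingLen numeric(1), correlation length (analysis cells) of the
#'   spatial clustering of burn probability.
#' @slot demSpec list describing deterministic terrain: base ramp gradient /
#'   azimuth, Gaussian hills, and the gradient used for steep patches.
#' @slot protectedSpec list of rectangles/circles (map units) rasterized as
#'   protected areas, beyond the auto-generated covers of planted pixels.
#' @slot regionsSpec data.frame naming a rectangular partition of the grid
#'   into regions (row/col ranges).
#' @slot planted integer matrix of pixels forced to meet all 3 criteria.
#' @slot decoys named list of integer matrices of pixels forced to meet the
#'   named subset of criteria only.
#' @seealso [syntheticScenario()], [makeFireSeries()], [makeDEM()],
#'   [makeVectors()]
#' @exportClass SyntheticScenario
setClass("SyntheticScenario",
  representation(
    seed = "integer",
    analysisGrid = "GridSpec",
    fineGrid = "GridSpec",
    years = "integer",
    burnProbBase = "numeric",
    hotspots = "data.frame",
    smoothingLen = "numeric",
    demSpec = "list",
    protectedSpec = "list",
    regionsSpec = "data.frame",
    planted = "matrix",
    decoys = "list"
  )
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@burnProbBase < 0 || object@burnProbBase > 1)
    msg <- c(msg, "burnProbBase must lie in [0,1]")
  if (length(object@years) != 2L || object@years[2] < object@years[1])
    msg <- c(msg, "years must be an ordered pair")
  g <- object@analysisGrid
  inGrid <- function(px) {
    nrow(px) == 0L ||
      all(px[, 1] >= 1 & px[, 1] <= g@nRows & px[, 2] >= 1 & px[, 2] <= g@nCols)
  }
  if (!inGrid(object@planted)) msg <- c(msg, "planted pixels outside analysis grid")
  allDecoys <- do.call(rbind, c(object@decoys, list(matrix(integer(), 0, 2))))
  if (!inGrid(allDecoys)) msg <- c(msg, "decoy pixels outside analysis grid")
  special <- rbind(object@planted, allDecoys)
  if (nrow(special) && anyDuplicated(paste(special[, 1], special[, 2])))
    msg <- c(msg, "planted and decoy pixel sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' All paths and thresholds needed for an end-to-end run.  Defaults encode
#' the study configuration: years 2001-2023, repetitive threshold 2 burn
#' years ("twice or more"), slope threshold 15 degrees (strict), majority
#' fraction 0.5 for the 30 m to 500 m mask aggregation, slope binarized
#' before aggregation.
#'
#' @slot burnPath character(1), directory of burn-date rasters (.asc) whose
#'   filenames carry a 4-digit year token (and a 2-digit month token in
#'   monthly mode).
#' @slot burnPeriod character(1), \code{"annual"} or \code{"monthly"}.
#' @slot demPath,protectedPath,regionsPath,boundaryPath character(1) input
#'   file paths (.asc raster / .geojson vectors).
#' @slot outputDir character(1), directory for all artifacts.
#' @slot yearRange integer(2).
#' @slot repetitiveThreshold integer(1), minimum burn years (default 2).
#' @slot slopeThresholdDeg numeric(1), default 15.
#' @slot steepFractionThreshold numeric(1), default 0.5.
#' @slot slopeOrder character(1), \code{"threshold_then_average"} (default)
#'   or \code{"average_then_threshold"}.
#' @slot crsId character(1), analysis CRS id the inputs must match.
#' @slot regionNameField character(1), attribute holding region names.
#' @slot allowGaps logical(1), tolerate missing years in the burn series.
#' @slot seed integer(1), recorded for synthetic provenance.
#' @seealso [pipelineConfig()], [runPipeline()], [validateConfig()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    burnPath = "character", burnPeriod = "character",
    demPath = "character", protectedPath = "character",
    regionsPath = "character", boundaryPath = "character",
    outputDir = "character",
    yearRange = "integer",
    repetitiveThreshold = "integer",
    slopeThresholdDeg = "numeric",
    steepFractionThreshold = "numeric",
    slopeOrder = "character",
    crsId = "character",
    regionNameField = "character",
    allowGaps = "logical",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@repetitiveThreshold < 1L) msg <- c(msg, "repetitiveThreshold must be >= 1")
  if (object@slopeThresholdDeg <= 0) msg <- c(msg, "slopeThresholdDeg must be positive")
  if (object@steepFractionThreshold < 0 || object@steepFractionThreshold > 1)
    msg <- c(msg, "steepFractionThreshold must lie in [0,1]")
  if (!(object@slopeOrder %in% c("threshold_then_average", "average_then_threshold")))
    msg <- c(msg, "slopeOrder must be 'threshold_then_average' or 'average_then_threshold'")
  if (!(object@burnPeriod %in% c("annual", "monthly")))
    msg <- c(msg, "burnPeriod must be 'annual' or 'monthly'")
  if (length(object@yearRange) != 2L || object@yearRange[2] < object@yearRange[1])
    msg <- c(msg, "yearRange must be an ordered pair")
  if (length(msg)) msg else TRUE
})
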