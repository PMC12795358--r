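#' @include grid-core.R
NULL

# Burned-area time-series compositing: monthly burn-date rasters -> annual
# composites -> multi-year fire frequency -> criterion masks.

.stackValues <- function(rasters) {
  npix <- length(rasters[[1]]@values)
  matrix(vapply(rasters, function(r) as.vector(r@values), numeric(npix)),
         nrow = npix, ncol = length(rasters))
}

.checkAlignedList <- function(rasters, what) {
  for (k in seq_along(rasters)[-1]) {
    if (!isAligned(rasters[[1]], rasters[[k]]))
      stop(what, " rasters are not mutually aligned (element ", k, ")")
  }
}

#' Composite monthly burn-date rasters into one annual raster
#'
#' Per pixel, the maximum positive burn day-of-year across the year's
#' monthly rasters — i.e. the most recent fire event of the year — else 0.
#' Non-positive special codes (water / unmapped fill in burned-area
#' products) are treated as "no burn this month"; a pixel is nodata only
#' when every month is nodata.
#'
#' @param monthly list of aligned [GeoRaster-class] burn-date rasters for
#'   one calendar year.
#' @param year integer, the calendar year.
#' @return a [BurnDateRaster-class].
#' @examples
#' g <- gridSpec(1, 1, cellSize = 500)
#' m <- lapply(c(32, 0, 240), function(v) geoRaster(matrix(v, 1, 1), g))
#' rasterValues(annualComposite(m, 2021))  # 240: the later burn wins
#' @export
annualComposite <- function(monthly, year) {
  if (!length(monthly)) stop("at least one monthly raster is required")
  .checkAlignedList(monthly, "monthly burn-date")
  M <- .stackValues(monthly)
  allNA <- rowSums(!is.na(M)) == 0L
  M[is.na(M)] <- 0
  M[M < 0] <- 0                       # special codes -> unburned
  v <- apply(M, 1L, max)
  v[allNA] <- NA_real_
  g <- monthly[[1]]@grid
  new("BurnDateRaster",
      grid = g, values = matrix(v, g@nRows, g@nCols),
      bandMeaning = "burn day-of-year", year = as.integer(year))
}

#' Count burn years per pixel across annual composites
#'
#' @param composites list of [BurnDateRaster-class], one per year of a
#'   consecutive year range (any order, no duplicates).
#' @return a [FireFrequencyRaster-class]; per pixel, the number of years
#'   with a positive composite.  A year's nodata counts as unburned for
#'   that year; a pixel is nodata only if nodata in every year.
#' @export
burnFrequency <- function(composites) {
  if (!length(composites)) stop("at least one annual composite is required")
  years <- vapply(composites, function(r) r@year, integer(1))
  if (anyDuplicated(years)) stop("duplicate years in composites: ",
                                 paste(years[duplicated(years)], collapse = ", "))
  yr <- range(years)
  missing <- setdiff(seq(yr[1], yr[2]), years)
  if (length(missing))
    stop("composites must cover consecutive years; missing: ",
         paste(missing, collapse = ", "))
  .checkAlignedList(composites, "annual composite")
  M <- .stackValues(composites)
  allNA <- rowSums(!is.na(M)) == 0L
  cnt <- rowSums(M > 0, na.rm = TRUE)
  cnt[allNA] <- NA_real_
  g <- composites[[1]]@grid
  new("FireFrequencyRaster",
      grid = g, values = matrix(cnt, g@nRows, g@nCols),
      bandMeaning = "burn-year count",
      yearRange = as.integer(yr))
}

#' Mask of pixels burned at least once
#'
#' @param freq a [FireFrequencyRaster-class].
#' @return boolean [GeoRaster-class]: 1 where the burn-year count is >= 1.
#' @export
burnedAnyMask <- function(freq) {
  thresholdMask(freq, 1, strict = FALSE)
}

#' Repetitive-fire criterion mask
#'
#' Pixels burned in \code{minYears} or more distinct years of the record
#' ("twice or more" in the default configuration).
#'
#' @param freq a [FireFrequencyRaster-class].
#' @param minYears minimum burn-year count, default 2.
#' @return a [CriterionMask-class] labelled \code{"repetitive_fire"}.
#' @export
repetitiveMask <- function(freq, minYears = 2) {
  m <- thresholdMask(freq, minYears, strict = FALSE)
  new("CriterionMask", grid = m@grid, values = m@values,
      bandMeaning = sprintf("burned in >= %g years", minYears),
      criterionLabel = "repetitive_fire")
}

#' Area by fire-frequency class
#'
#' @param freq a [FireFrequencyRaster-class].
#' @return data.frame with columns \code{frequency}, \code{pixel_count},
#'   \code{area_km2}, one row per observed count (0 included).
#' @export
frequencyAreaTable <- function(freq) {
  v <- freq@values[!is.na(freq@values)]
  px <- pixelAreaKm2(freq@grid)
  tab <- table(factor(v, levels = 0:max(c(v, 0))))
  data.frame(
    frequency = as.integer(names(tab)),
    pixel_count = as.integer(tab),
    area_km2 = as.integer(tab) * px,
    row.names = NULL
  )
}
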