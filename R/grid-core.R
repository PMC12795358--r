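#' @include AllGenerics.R
NULL

#' Construct a GridSpec
#'
#' @param nRows,nCols raster dimensions.
#' @param cellSize pixel edge length in meters; give \code{cellSizeX} /
#'   \code{cellSizeY} instead for non-square cells.
#' @param originX,originY map coordinates (m) of the top-left corner of the
#'   top-left pixel.
#' @param crsId projected CRS identifier recorded with the grid.
#' @param cellSizeX,cellSizeY explicit edge lengths, default \code{cellSize}.
#' @param nodata sentinel written for NA cells on disk.
#' @return a [GridSpec-class].
#' @examples
#' gridSpec(nRows = 60, nCols = 60, cellSize = 500, crsId = "EPSG:2100")
#' @export
gridSpec <- function(nRows, nCols, cellSize = 500, originX = 0, originY = nRows * cellSizeY,
                     crsId = "EPSG:2100", cellSizeX = cellSize, cellSizeY = cellSize,
                     nodata = -9999) {
  new("GridSpec",
    crsId = as.character(crsId), originX = as.numeric(originX),
    originY = as.numeric(originY), cellSizeX = as.numeric(cellSizeX),
    cellSizeY = as.numeric(cellSizeY), nRows = as.integer(nRows),
    nCols = as.integer(nCols), nodata = as.numeric(nodata)
  )
}

#' Construct a GeoRaster
#'
#' @param values numeric matrix (NA = nodata) of dim \code{nRows x nCols}.
#' @param grid a [GridSpec-class].
#' @param bandMeaning free-text band label.
#' @return a [GeoRaster-class].
#' @export
geoRaster <- function(values, grid, bandMeaning = "") {
  storage.mode(values) <- "double"
  new("GeoRaster", grid = grid, values = values,
      bandMeaning = as.character(bandMeaning))
}

.alignTol <- 1e-6

.gridsAligned <- function(ga, gb) {
  if (!identical(ga@crsId, gb@crsId)) return(FALSE)
  sameSize <- function(a, b) abs(a - b) <= .alignTol * max(a, b)
  if (!sameSize(ga@cellSizeX, gb@cellSizeX) || !sameSize(ga@cellSizeY, gb@cellSizeY))
    return(FALSE)
  offMult <- function(off, cell) {
    k <- off / cell
    abs(k - round(k)) <= .alignTol
  }
  offMult(ga@originX - gb@originX, ga@cellSizeX) &&
    offMult(ga@originY - gb@originY, ga@cellSizeY)
}

#' @rdname isAligned
#' @export
setMethod("isAligned", signature("GridSpec", "GridSpec"),
          function(a, b) .gridsAligned(a, b))

#' @rdname isAligned
#' @export
setMethod("isAligned", signature("GeoRaster", "GeoRaster"),
          function(a, b) .gridsAligned(a@grid, b@grid))

#' @rdname isAligned
#' @export
setMethod("isAligned", signature("GeoRaster", "GridSpec"),
          function(a, b) .gridsAligned(a@grid, b))

#' @rdname isAligned
#' @export
setMethod("isAligned", signature("GridSpec", "GeoRaster"),
          function(a, b) .gridsAligned(a, b@grid))

#' @rdname gridGeometry
#' @export
setMethod("gridGeometry", "GeoRaster", function(x) x@grid)

#' @rdname rasterValues
#' @export
setMethod("rasterValues", "GeoRaster", function(x) x@values)

#' @rdname criterionLabel
#' @export
setMethod("criterionLabel", "CriterionMask", function(x) x@criterionLabel)

.isGeographicCrs <- function(crsId) {
  # degree-unit identifiers this package refuses for metric math
  grepl("^EPSG:(4326|4258|4269|4230)$", crsId, ignore.case = TRUE) ||
    grepl("longlat|WGS ?84$|CRS84", crsId, ignore.case = TRUE)
}

#' @rdname pixelAreaKm2
#' @export
setMethod("pixelAreaKm2", "GridSpec", function(grid) {
  if (.isGeographicCrs(grid@crsId))
    stop("grid CRS '", grid@crsId, "' is geographic (degrees); ",
         "reproject inputs to a projected, meter-unit CRS before area computation")
  grid@cellSizeX * grid@cellSizeY / 1e6
})

#' @rdname pixelAreaKm2
#' @export
setMethod("pixelAreaKm2", "GeoRaster", function(grid) pixelAreaKm2(grid@grid))

#' Area covered by the 1-pixels of a boolean mask
#'
#' Every reported area in the pipeline is pixel count times pixel area, so
#' areas on a 500 m grid are exact multiples of 0.25 km^2.
#'
#' @param mask a boolean [GeoRaster-class] (values 0/1/NA).
#' @return numeric(1), km^2.
#' @export
maskAreaKm2 <- function(mask) {
  sum(mask@values == 1, na.rm = TRUE) * pixelAreaKm2(mask@grid)
}

#' Map coordinates of pixel centers
#'
#' @param grid a [GridSpec-class].
#' @return list with \code{x} (length nCols, west to east) and \code{y}
#'   (length nRows, north to south).
#' @export
cellCenters <- function(grid) {
  list(
    x = grid@originX + (seq_len(grid@nCols) - 0.5) * grid@cellSizeX,
    y = grid@originY - (seq_len(grid@nRows) - 0.5) * grid@cellSizeY
  )
}

# 1-D area-overlap weight matrix between coarse intervals and fine intervals.
# Row i: coarse cell i; column j: fine cell j; entry = overlap length (m).
.overlapWeights <- function(coarseOrigin, coarseCell, nCoarse,
                            fineOrigin, fineCell, nFine, descending = FALSE) {
  sgn <- if (descending) -1 else 1
  cb <- coarseOrigin + sgn * coarseCell * (0:nCoarse)     # coarse breakpoints
  fb <- fineOrigin + sgn * fineCell * (0:nFine)
  if (descending) { cb <- -cb; fb <- -fb }                # work on ascending axis
  W <- matrix(0, nCoarse, nFine)
  for (i in seq_len(nCoarse)) {
    lo <- cb[i]; hi <- cb[i + 1]
    j0 <- max(1L, ceiling((lo - fb[1]) / fineCell + 1e-9))
    j1 <- min(nFine, floor((hi - fb[1]) / fineCell - 1e-9) + 1L)
    if (j1 < j0) next
    js <- j0:j1
    W[i, js] <- pmin(hi, fb[js + 1]) - pmax(lo, fb[js])
  }
  W
}

#' Aggregate a fine raster onto a coarser grid by area-weighted averaging
#'
#' Each coarse cell receives the area-weighted mean of all fine cells
#' overlapping its footprint ("spatial averaging").  Non-integer cell-size
#' ratios (e.g. 30 m to 500 m) are handled exactly through fractional
#' overlap weights.  Nodata fine cells are ignored; a coarse cell whose
#' footprint is entirely nodata (or entirely outside the fine raster) is
#' nodata.
#'
#' @param fine a numeric [GeoRaster-class] on the fine grid.
#' @param coarseGrid target [GridSpec-class]; must share the CRS and have
#'   strictly larger cells.
#' @return a [GeoRaster-class] on \code{coarseGrid}.
#' @examples
#' fine <- geoRaster(matrix(1, 10, 10), gridSpec(10, 10, cellSize = 30))
#' coarse <- gridSpec(1, 1, cellSize = 300)
#' rasterValues(aggregateMean(fine, coarse))  # 1
#' @export
aggregateMean <- function(fine, coarseGrid) {
  gf <- fine@grid
  if (!identical(gf@crsId, coarseGrid@crsId))
    stop("CRS mismatch: fine raster is '", gf@crsId,
         "', target grid is '", coarseGrid@crsId, "'")
  if (coarseGrid@cellSizeX <= gf@cellSizeX || coarseGrid@cellSizeY <= gf@cellSizeY)
    stop("target grid cells must be strictly larger than fine cells")
  Wx <- .overlapWeights(coarseGrid@originX, coarseGrid@cellSizeX, coarseGrid@nCols,
                        gf@originX, gf@cellSizeX, gf@nCols)
  Wy <- .overlapWeights(coarseGrid@originY, coarseGrid@cellSizeY, coarseGrid@nRows,
                        gf@originY, gf@cellSizeY, gf@nRows, descending = TRUE)
  V <- fine@values
  valid <- !is.na(V)
  V0 <- ifelse(valid, V, 0)
  num <- Wy %*% V0 %*% t(Wx)
  den <- Wy %*% (valid + 0) %*% t(Wx)
  out <- ifelse(den > 0, num / den, NA_real_)
  geoRaster(out, coarseGrid, bandMeaning = fine@bandMeaning)
}

#' Binarize a raster at a threshold
#'
#' @param r numeric [GeoRaster-class].
#' @param threshold cut value.
#' @param strict if TRUE (default) cells must exceed the threshold
#'   (\code{>}); if FALSE, equal cells pass (\code{>=}).
#' @return boolean [GeoRaster-class] (1 above threshold, 0 otherwise, NA
#'   propagated).
#' @examples
#' r <- geoRaster(matrix(c(14, 15, 16, NA), 2, 2), gridSpec(2, 2))
#' rasterValues(thresholdMask(r, 15))          # strict: only 16 passes
#' rasterValues(thresholdMask(r, 15, FALSE))   # 15 and 16 pass
#' @export
thresholdMask <- function(r, threshold, strict = TRUE) {
  v <- r@values
  out <- if (strict) (v > threshold) + 0 else (v >= threshold) + 0
  geoRaster(out, r@grid,
            bandMeaning = sprintf("mask: %s %s %g", r@bandMeaning,
                                  if (strict) ">" else ">=", threshold))
}

.fmtGrid <- function(g) {
  sprintf("%d x %d @ %g x %g m, origin (%g, %g), %s",
          g@nRows, g@nCols, g@cellSizeX, g@cellSizeY,
          g@originX, g@originY, g@crsId)
}

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", .fmtGrid(object), "\n")
  cat("  nodata sentinel:", object@nodata, "\n")
})

setMethod("show", "GeoRaster", function(object) {
  v <- object@values
  cat(class(object), "|", .fmtGrid(object@grid), "\n")
  if (nzchar(object@bandMeaning)) cat("  band:", object@bandMeaning, "\n")
  fin <- v[!is.na(v)]
  cat(sprintf("  values: %d cells, %d nodata", length(v), sum(is.na(v))))
  if (length(fin)) cat(sprintf(", range [%g, %g]", min(fin), max(fin)))
  cat("\n")
})

setMethod("show", "CriterionMask", function(object) {
  callNextMethod()
  cat("  criterion:", object@criterionLabel, "|",
      sum(object@values == 1, na.rm = TRUE), "pixels set\n")
})

setMethod("show", "CriteriaStack", function(object) {
  cat("CriteriaStack of 3 masks on",
      .fmtGrid(object@masks[[1]]@grid), "\n")
  for (m in object@masks)
    cat(sprintf("  %-16s %d pixels\n", m@criterionLabel,
                sum(m@values == 1, na.rm = TRUE)))
})

setMethod("show", "PriorityResult", function(object) {
  cat("PriorityResult on", .fmtGrid(object@final@grid), "\n")
  cat("  preselection (>=2 criteria):",
      sum(object@preselection@values == 1, na.rm = TRUE), "pixels,",
      maskAreaKm2(object@preselection), "km^2\n")
  cat("  final (all 3 criteria):     ",
      sum(object@final@values == 1, na.rm = TRUE), "pixels,",
      object@totalAreaKm2, "km^2\n")
  nz <- sum(object@regionTable$pixel_count > 0 &
              object@regionTable$region != "_unassigned")
  cat("  regions with selected area:", nz, "\n")
})
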