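#' @include AllClasses.R
NULL

#' Test whether two rasters (or grids) are aligned
#'
#' Alignment requires the same CRS id, identical cell sizes and origins
#' offset by integer multiples of the cell size (tolerance 1e-6 cell).
#' Overlay operations refuse unaligned inputs.
#'
#' @param a,b [GridSpec-class] or [GeoRaster-class] objects.
#' @return logical(1).
#' @examples
#' g <- gridSpec(nRows = 4, nCols = 4, cellSize = 500)
#' isAligned(g, g)
#' @export
setGeneric("isAligned", function(a, b) standardGeneric("isAligned"))

#' Grid geometry accessor
#' @param x a raster-like object.
#' @return the [GridSpec-class] of \code{x}.
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' Raster cell values accessor
#' @param x a raster-like object.
#' @return the numeric value matrix (NA = nodata).
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' Criterion label accessor
#' @param x a [CriterionMask-class].
#' @return character(1) criterion label.
#' @export
setGeneric("criterionLabel", function(x) standardGeneric("criterionLabel"))

#' Area of one pixel in square kilometers
#'
#' Projected cell area, \code{cellSizeX * cellSizeY / 1e6}.  Refuses
#' geographic (degree-unit) CRS ids: reproject to an equal-area or national
#' projected CRS first.
#'
#' @param grid a [GridSpec-class] or raster carrying one.
#' @return numeric(1), km^2 per pixel.
#' @examples
#' pixelAreaKm2(gridSpec(nRows = 1, nCols = 1, cellSize = 500))  # 0.25
#' @export
setGeneric("pixelAreaKm2", function(grid) standardGeneric("pixelAreaKm2"))
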