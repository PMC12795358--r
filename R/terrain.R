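#' @include grid-core.R
NULL

#' Slope in degrees from a DEM (Horn's method)
#'
#' Horn's 3x3 weighted finite-difference estimator, the algorithm behind
#' standard GIS slope tools.  For the kernel
#' \preformatted{ a b c
#'  d e f
#'  g h i }
#' the gradients are \code{dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8 dx)}
#' and \code{dz/dy = ((g + 2h + i) - (a + 2b + c)) / (8 dy)}, and slope is
#' \code{atan(sqrt((dz/dx)^2 + (dz/dy)^2))} in degrees.  The estimator is
#' exact on planar surfaces.  Border pixels are computed after edge
#' replication (keeps coastal cells usable); a pixel is nodata when any
#' cell of its 3x3 neighborhood is nodata.
#'
#' @param dem a [DEMRaster-class] (or any [GeoRaster-class] of elevations,
#'   meters) on a projected meter-unit grid with at least 3 rows and
#'   columns.
#' @return a [SlopeRaster-class] in degrees.
#' @examples
#' g <- gridSpec(5, 5, cellSize = 30)
#' z <- outer(rep(1, 5), (1:5 - 0.5) * 30)          # z = x: 45 degree plane
#' rasterValues(computeSlope(geoRaster(z, g)))[3, 3]
#' @export
computeSlope <- function(dem) {
  g <- dem@grid
  if (.isGeographicCrs(g@crsId))
    stop("DEM CRS '", g@crsId, "' is geographic (degrees); ",
         "slope requires a projected, meter-unit grid")
  if (g@nRows < 3L || g@nCols < 3L)
    stop("DEM must be at least 3 x 3 for the slope kernel")
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  # edge-replicated padding
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); cc <- sh(0, 2)
  d <- sh(1, 0);                f <- sh(1, 2)
  gg <- sh(2, 0); h <- sh(2, 1); i <- sh(2, 2)
  anyNA9 <- is.na(a) | is.na(b) | is.na(cc) | is.na(d) | is.na(sh(1, 1)) |
    is.na(f) | is.na(gg) | is.na(h) | is.na(i)
  gx <- ((cc + 2 * f + i) - (a + 2 * d + gg)) / (8 * g@cellSizeX)
  gy <- ((gg + 2 * h + i) - (a + 2 * b + cc)) / (8 * g@cellSizeY)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[anyNA9] <- NA_real_
  new("SlopeRaster", grid = g, values = slope, bandMeaning = "slope degrees")
}

#' Steep-slope criterion mask on the analysis grid
#'
#' Default order (\code{"threshold_then_average"}): binarize slope strictly
#' above \code{thresholdDeg} on the fine grid, aggregate the binary mask to
#' the analysis grid by area-weighted averaging, and re-binarize at the
#' majority fraction \code{fractionThreshold} (>= rule).  The alternative
#' order (\code{"average_then_threshold"}) aggregates the slope values
#' first and thresholds the averaged slope, for sensitivity runs.
#'
#' @param slope a [SlopeRaster-class] on the fine grid.
#' @param analysisGrid target [GridSpec-class] (coarser or equal; when the
#'   grids are aligned and equal-sized, no aggregation is performed).
#' @param thresholdDeg slope threshold in degrees, default 15 (strict
#'   inequality: exactly 15 is excluded).
#' @param fractionThreshold majority fraction for re-binarization, default
#'   0.5.
#' @param order one of \code{"threshold_then_average"} (default),
#'   \code{"average_then_threshold"}.
#' @return a [CriterionMask-class] labelled \code{"steep_slope"} on
#'   \code{analysisGrid}.
#' @export
steepMask <- function(slope, analysisGrid, thresholdDeg = 15,
                      fractionThreshold = 0.5,
                      order = c("threshold_then_average", "average_then_threshold")) {
  order <- match.arg(order)
  sameGrid <- isAligned(slope@grid, analysisGrid) &&
    slope@grid@nRows == analysisGrid@nRows &&
    slope@grid@nCols == analysisGrid@nCols
  if (order == "threshold_then_average") {
    fine <- thresholdMask(slope, thresholdDeg, strict = TRUE)
    coarseFrac <- if (sameGrid) fine else aggregateMean(fine, analysisGrid)
    m <- thresholdMask(coarseFrac, fractionThreshold, strict = FALSE)
  } else {
    coarseSlope <- if (sameGrid) slope else aggregateMean(slope, analysisGrid)
    m <- thresholdMask(coarseSlope, thresholdDeg, strict = TRUE)
  }
  new("CriterionMask", grid = m@grid, values = m@values,
      bandMeaning = sprintf("slope > %g deg (%s)", thresholdDeg, order),
      criterionLabel = "steep_slope")
}
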