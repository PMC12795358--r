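#' @include geometry.R
#' @include grid-core.R
NULL

#' Load protected-area polygons and clip them to the land boundary
#'
#' Reads a polygon GeoJSON, validates the CRS against the analysis CRS,
#' clips every feature to the (convex) terrestrial land boundary — marine
#' parts are dropped, coastal polygons keep their land part — and preserves
#' the inventory attributes.  Overlapping designations are retained as
#' separate records; rasterization performs the boolean union.
#'
#' @param path GeoJSON file of protected-area polygons with \code{name},
#'   \code{designation}, \code{iucn_category} properties (missing
#'   properties are filled with "Not Reported").
#' @param landBoundary convex ring (n x 2 matrix) or single-feature
#'   [PolygonSet-class] of the terrestrial extent.
#' @param crsId analysis CRS the file must match; NULL skips the check.
#' @param iucnCategories optional character vector; when given, only
#'   features whose \code{iucn_category} is listed are kept (the default
#'   keeps everything, including "Not Reported").
#' @return a [ProtectedAreaSet-class] of land-clipped polygons.
#' @export
loadProtected <- function(path, landBoundary, crsId = NULL,
                          iucnCategories = NULL) {
  ps <- readGeoJSON(path, class_ = "PolygonSet")
  if (!is.null(crsId) && !identical(ps@crsId, crsId))
    stop("protected-area CRS '", ps@crsId, "' does not match analysis CRS '",
         crsId, "'")
  if (identical(ps@crsId, "unknown"))
    stop("protected-area file ", path, " carries no CRS identifier")
  attrs <- ps@attrs
  for (col in c("name", "designation", "iucn_category")) {
    if (!(col %in% names(attrs))) attrs[[col]] <- "Not Reported"
    attrs[[col]][is.na(attrs[[col]])] <- "Not Reported"
  }
  if (!is.null(iucnCategories)) {
    keep <- attrs$iucn_category %in% iucnCategories
    ps@geometries <- ps@geometries[keep]
    attrs <- attrs[keep, , drop = FALSE]
  }
  if (is(landBoundary, "PolygonSet"))
    landBoundary <- landBoundary@geometries[[1]][[1]]
  clipped <- lapply(ps@geometries, clipPolygon, boundary = landBoundary)
  keep <- vapply(clipped, length, integer(1)) > 0L
  if (!any(keep))
    stop("no protected-area polygon intersects the land boundary")
  attrs <- attrs[keep, , drop = FALSE]
  attrs$marine_flag <- FALSE  # marine parts removed by the clip
  geoms <- clipped[keep]
  attrs$clipped_area_km2 <- vapply(geoms, polygonArea, numeric(1)) / 1e6
  rownames(attrs) <- NULL
  polygonSet(geoms, attrs, crsId = ps@crsId, class_ = "ProtectedAreaSet")
}

#' Rasterize polygons to a boolean mask by the pixel-center rule
#'
#' A pixel is 1 iff its center point falls inside any polygon of the set
#' (even-odd rule; overlapping polygons union to 1).  This reproduces the
#' default behavior of standard feature-to-raster tools and avoids
#' inflating areas the way an all-touched rule would.
#'
#' @param ps a [PolygonSet-class] (or subclass), same CRS as \code{grid}.
#' @param grid target [GridSpec-class].
#' @param label criterion label for the returned mask, default
#'   \code{"protected_area"}.
#' @return a [CriterionMask-class].
#' @export
rasterizeMask <- function(ps, grid, label = "protected_area") {
  if (!identical(ps@crsId, grid@crsId))
    stop("polygon CRS '", ps@crsId, "' does not match grid CRS '",
         grid@crsId, "'")
  ctr <- cellCenters(grid)
  xs <- rep(ctr$x, each = grid@nRows)
  ys <- rep(ctr$y, times = grid@nCols)
  inside <- rep(FALSE, length(xs))
  for (geom in ps@geometries) {
    # bounding-box prefilter per polygon keeps the point tests cheap
    allPts <- do.call(rbind, geom)
    bx <- range(allPts[, 1]); by <- range(allPts[, 2])
    cand <- which(!inside & xs >= bx[1] & xs <= bx[2] &
                    ys >= by[1] & ys <= by[2])
    if (!length(cand)) next
    inside[cand] <- pointsInPolygon(xs[cand], ys[cand], geom)
  }
  new("CriterionMask",
      grid = grid,
      values = matrix(inside + 0, grid@nRows, grid@nCols),
      bandMeaning = "polygon cover (center rule)",
      criterionLabel = label)
}

#' Protected-area inventory table
#'
#' @param pas a [ProtectedAreaSet-class] from [loadProtected()].
#' @return data.frame with name, designation, iucn_category,
#'   clipped_area_km2.
#' @export
protectedInventory <- function(pas) {
  pas@attrs[, c("name", "designation", "iucn_category", "clipped_area_km2")]
}
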