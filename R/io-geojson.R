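#' @include geometry.R
NULL

# GeoJSON read/write for Polygon / MultiPolygon FeatureCollections via
# jsonlite.  Coordinates are in the analysis (projected) CRS; the CRS id is
# carried in the legacy top-level "crs" member so round-trips preserve it.

.geomToRings <- function(geom) {
  toRing <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    .ringUnclose(m)
  }
  switch(geom$type,
    Polygon = lapply(geom$coordinates, toRing),
    MultiPolygon = unlist(lapply(geom$coordinates,
                                 function(poly) lapply(poly, toRing)),
                          recursive = FALSE),
    stop("unsupported GeoJSON geometry type: ", geom$type)
  )
}

#' Read a GeoJSON FeatureCollection of polygons
#'
#' @param path file path.
#' @param class_ PolygonSet subclass to build ("PolygonSet",
#'   "ProtectedAreaSet", "RegionSet").
#' @return an object of \code{class_}; feature properties become attribute
#'   columns.
#' @export
readGeoJSON <- function(path, class_ = "PolygonSet") {
  j <- jsonlite::read_json(path)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection in ", path)
  feats <- j$features
  if (!length(feats)) stop("no features in ", path)
  polyFeats <- Filter(function(f)
    !is.null(f$geometry) && f$geometry$type %in% c("Polygon", "MultiPolygon"),
    feats)
  if (!length(polyFeats)) stop("no polygon features in ", path)
  geoms <- lapply(polyFeats, function(f) .geomToRings(f$geometry))
  propNames <- unique(unlist(lapply(polyFeats, function(f) names(f$properties))))
  if (length(propNames)) {
    cols <- lapply(stats::setNames(propNames, propNames), function(nm) {
      sapply(polyFeats, function(f) {
        v <- f$properties[[nm]]
        if (is.null(v)) NA else v
      })
    })
    attrs <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    attrs <- data.frame(row.names = seq_along(geoms))
  }
  crsId <- "unknown"
  if (!is.null(j$crs$properties$name)) crsId <- j$crs$properties$name
  polygonSet(geoms, attrs, crsId = crsId, class_ = class_)
}

#' Write a PolygonSet as GeoJSON
#'
#' Each feature is written as a Polygon (single ring) or MultiPolygon-style
#' Polygon with multiple rings; rings are closed on output.
#'
#' @param ps a [PolygonSet-class] (or subclass).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeoJSON <- function(ps, path) {
  feats <- lapply(seq_along(ps@geometries), function(i) {
    rings <- lapply(ps@geometries[[i]], function(r) {
      rc <- .ringClose(r)
      lapply(seq_len(nrow(rc)), function(k) c(rc[k, 1], rc[k, 2]))
    })
    props <- if (ncol(ps@attrs)) as.list(ps@attrs[i, , drop = FALSE]) else
      stats::setNames(list(), character())
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = ps@crsId)),
    features = feats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
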