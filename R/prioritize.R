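#' @include protected.R
#' @include fire-history.R
NULL

#' Bundle the three criterion masks
#'
#' @param ... three [CriterionMask-class] objects (any order) with labels
#'   \code{repetitive_fire}, \code{steep_slope}, \code{protected_area}, or a
#'   single list of them.
#' @return a [CriteriaStack-class]; masks are stored in canonical label
#'   order so downstream outputs do not depend on the call order.
#' @export
criteriaStack <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1]]) && !is(masks[[1]], "CriterionMask"))
    masks <- masks[[1]]
  if (length(masks) != 3L || !all(vapply(masks, is, logical(1), "CriterionMask")))
    stop("criteriaStack needs exactly three CriterionMask objects")
  labs <- vapply(masks, criterionLabel, character(1))
  ord <- match(.CRITERION_LABELS, labs)
  if (anyNA(ord))
    stop("mask labels must be exactly {",
         paste(.CRITERION_LABELS, collapse = ", "), "}; got {",
         paste(labs, collapse = ", "), "}")
  new("CriteriaStack", masks = masks[ord])
}

#' Count satisfied criteria per pixel
#'
#' Sum of the three binary masks.  Nodata in a mask counts as "criterion
#' not met" (0) for that pixel; a pixel that is nodata in all three masks
#' is nodata in the count.
#'
#' @param stack a [CriteriaStack-class].
#' @return [GeoRaster-class] of integers 0..3.
#' @export
criteriaCount <- function(stack) {
  ms <- stack@masks
  M <- .stackValues(ms)
  allNA <- rowSums(!is.na(M)) == 0L
  cnt <- rowSums(M == 1, na.rm = TRUE)
  cnt[allNA] <- NA_real_
  g <- ms[[1]]@grid
  geoRaster(matrix(cnt, g@nRows, g@nCols), g,
            bandMeaning = "criteria satisfied (0-3)")
}

#' Select preselection or final priority pixels from the criteria count
#'
#' Preselection keeps pixels meeting at least two of the three criteria;
#' the final priority map keeps pixels meeting all three.
#'
#' @param count criteria-count raster from [criteriaCount()].
#' @param mode \code{"preselect"} (count >= 2) or \code{"final"}
#'   (count == 3).
#' @return boolean [GeoRaster-class].
#' @export
selectPriority <- function(count, mode = c("preselect", "final")) {
  mode <- match.arg(mode)
  v <- count@values
  bad <- !is.na(v) & (v < 0 | v > 3)
  if (any(bad))
    stop("criteria count contains values outside 0..3")
  out <- if (mode == "preselect") (v >= 2) + 0 else (v == 3) + 0
  geoRaster(out, count@grid,
            bandMeaning = if (mode == "preselect")
              "preselection (>= 2 criteria)" else "final priority (all 3 criteria)")
}

#' Tabulate mask area by administrative region
#'
#' Counts mask-1 pixels whose centers fall inside each region polygon
#' (pixel centers on a shared boundary go to the first containing region in
#' the stable feature order, so the regions partition the selected pixels).
#' Regions with no selected pixels are reported with 0; selected pixels
#' outside every region are reported under \code{"_unassigned"}.
#'
#' @param mask boolean [GeoRaster-class].
#' @param regions a [RegionSet-class] in the same CRS.
#' @return data.frame with columns \code{region}, \code{pixel_count},
#'   \code{area_km2}, in region order (plus \code{_unassigned} last when
#'   nonzero).
#' @export
zonalTabulate <- function(mask, regions) {
  if (!identical(regions@crsId, mask@grid@crsId))
    stop("regions CRS '", regions@crsId, "' does not match mask CRS '",
         mask@grid@crsId, "'")
  g <- mask@grid
  sel <- which(mask@values == 1)
  ctr <- cellCenters(g)
  ij <- arrayInd(sel, dim(mask@values))
  xs <- ctr$x[ij[, 2]]
  ys <- ctr$y[ij[, 1]]
  nms <- regions@attrs$region_name
  counts <- stats::setNames(integer(length(nms)), nms)
  assigned <- rep(FALSE, length(sel))
  for (k in seq_along(nms)) {
    if (!length(sel)) break
    cand <- which(!assigned)
    if (!length(cand)) break
    inside <- pointsInPolygon(xs[cand], ys[cand], regions@geometries[[k]])
    counts[k] <- sum(inside)
    assigned[cand[inside]] <- TRUE
  }
  unassigned <- if (length(sel)) sum(!assigned) else 0L
  px <- pixelAreaKm2(g)
  tab <- data.frame(
    region = nms,
    pixel_count = as.integer(counts),
    area_km2 = as.integer(counts) * px,
    stringsAsFactors = FALSE
  )
  if (unassigned > 0L)
    tab <- rbind(tab, data.frame(region = "_unassigned",
                                 pixel_count = unassigned,
                                 area_km2 = unassigned * px))
  rownames(tab) <- NULL
  tab
}

#' Run the full overlay: counts, preselection, final map, region table
#'
#' @param stack a [CriteriaStack-class].
#' @param regions a [RegionSet-class] for the zonal tabulation.
#' @return a [PriorityResult-class].
#' @export
prioritize <- function(stack, regions) {
  cnt <- criteriaCount(stack)
  pre <- selectPriority(cnt, "preselect")
  fin <- selectPriority(cnt, "final")
  tab <- zonalTabulate(fin, regions)
  new("PriorityResult",
      criteriaCount = cnt, preselection = pre, final = fin,
      regionTable = tab,
      totalAreaKm2 = sum(fin@values == 1, na.rm = TRUE) * pixelAreaKm2(cnt@grid))
}

#' Accessors for PriorityResult
#' @param x a [PriorityResult-class].
#' @return the requested component.
#' @name priority-accessors
NULL

#' @rdname priority-accessors
#' @export
regionTable <- function(x) x@regionTable

#' @rdname priority-accessors
#' @export
finalMask <- function(x) x@final

#' @rdname priority-accessors
#' @export
preselectionMask <- function(x) x@preselection

#' @rdname priority-accessors
#' @export
countRaster <- function(x) x@criteriaCount

#' @rdname priority-accessors
#' @export
totalAreaKm2 <- function(x) x@totalAreaKm2

#' Summarize a prioritization result
#'
#' @param result a [PriorityResult-class].
#' @return list with \code{table} (per-region rows sorted by area
#'   descending, zero rows included, final TOTAL row), \code{text} (the
#'   human-readable summary lines), \code{regionsSelected} (count of
#'   regions with nonzero area) and \code{consistency} ("OK" when regional
#'   areas sum to the final-mask area, otherwise "MISMATCH").
#' @export
summarizeResult <- function(result) {
  tab <- result@regionTable
  body <- tab[order(-tab$area_km2, match(tab$region, tab$region)), ]
  total <- data.frame(region = "TOTAL",
                      pixel_count = sum(tab$pixel_count),
                      area_km2 = sum(tab$area_km2))
  out <- rbind(body, total)
  rownames(out) <- NULL
  nzRegions <- sum(tab$pixel_count > 0 & tab$region != "_unassigned")
  consistent <- isTRUE(all.equal(sum(tab$area_km2), result@totalAreaKm2)) &&
    sum(tab$pixel_count) == sum(result@final@values == 1, na.rm = TRUE)
  txt <- c(
    sprintf("Final priority area: %.2f km2 (%d pixels at %.4f km2/pixel)",
            result@totalAreaKm2,
            sum(result@final@values == 1, na.rm = TRUE),
            pixelAreaKm2(result@final@grid)),
    sprintf("%d regions selected", nzRegions),
    sprintf("Consistency (regions vs mask): %s",
            if (consistent) "OK" else "MISMATCH"),
    sprintf("  %-28s %8s %10s", "region", "pixels", "area_km2"),
    sprintf("  %-28s %8d %10.2f", out$region, out$pixel_count, out$area_km2)
  )
  list(table = out, text = txt, regionsSelected = nzRegions,
       consistency = if (consistent) "OK" else "MISMATCH")
}

#' Final-mask area inside a focus polygon
#'
#' Supports site-level reporting: the area of the final priority mask whose
#' pixel centers fall inside a user-supplied polygon.
#'
#' @param result a [PriorityResult-class] (or a boolean [GeoRaster-class]).
#' @param polygon list of rings, a ring matrix, or a single-feature
#'   [PolygonSet-class].
#' @return list with \code{pixel_count} and \code{area_km2}.
#' @export
focusArea <- function(result, polygon) {
  mask <- if (is(result, "PriorityResult")) result@final else result
  if (is(polygon, "PolygonSet")) polygon <- polygon@geometries[[1]]
  if (is.matrix(polygon)) polygon <- list(polygon)
  g <- mask@grid
  sel <- which(mask@values == 1)
  ctr <- cellCenters(g)
  ij <- arrayInd(sel, dim(mask@values))
  n <- if (length(sel))
    sum(pointsInPolygon(ctr$x[ij[, 2]], ctr$y[ij[, 1]], polygon)) else 0L
  list(pixel_count = as.integer(n), area_km2 = n * pixelAreaKm2(g))
}
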