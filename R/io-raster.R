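#' @include grid-core.R
NULL

# Plain-text raster interchange: ESRI ASCII grid (.asc).  Header keys
# NCOLS/NROWS/XLLCORNER/YLLCORNER then CELLSIZE (square cells) or DX/DY,
# optional NODATA_VALUE; data rows run north to south.  The CRS id travels
# in a sidecar .prj file holding the identifier string.

.prjPath <- function(path) sub("\\.[^.]+$", ".prj", path)

#' Write a raster as an ESRI ASCII grid
#'
#' NA cells are written as the grid's nodata sentinel.  The CRS identifier
#' is written to a sidecar \code{.prj} file next to the raster.
#'
#' @param r a [GeoRaster-class].
#' @param path output file path (conventionally \code{.asc}).
#' @param digits significant digits for cell values (default 10; integers
#'   are written exactly).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(r, path, digits = 10) {
  g <- r@grid
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", g@nCols),
    sprintf("NROWS %d", g@nRows),
    sprintf("XLLCORNER %.10g", g@originX),
    sprintf("YLLCORNER %.10g", g@originY - g@nRows * g@cellSizeY)
  ), con)
  if (isTRUE(all.equal(g@cellSizeX, g@cellSizeY))) {
    writeLines(sprintf("CELLSIZE %.10g", g@cellSizeX), con)
  } else {
    writeLines(c(sprintf("DX %.10g", g@cellSizeX),
                 sprintf("DY %.10g", g@cellSizeY)), con)
  }
  writeLines(sprintf("NODATA_VALUE %.10g", g@nodata), con)
  v <- r@values
  v[is.na(v)] <- g@nodata
  allInt <- all(v == round(v))
  fmt <- if (allInt) "%d" else paste0("%.", digits, "g")
  for (i in seq_len(nrow(v))) {
    row <- if (allInt) sprintf(fmt, as.integer(v[i, ])) else sprintf(fmt, v[i, ])
    writeLines(paste(row, collapse = " "), con)
  }
  writeLines(r@grid@crsId, .prjPath(path))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crsId CRS id to record; default reads the sidecar \code{.prj} if
#'   present, else "unknown".
#' @param bandMeaning band label for the returned raster.
#' @return a [GeoRaster-class]; nodata cells are NA.
#' @export
readAsciiGrid <- function(path, crsId = NULL, bandMeaning = "") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- toupper(parts[1])
    if (key %in% c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER",
                   "CELLSIZE", "DX", "DY", "NODATA_VALUE")) {
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  for (k in c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  dx <- if (!is.null(hdr$CELLSIZE)) hdr$CELLSIZE else hdr$DX
  dy <- if (!is.null(hdr$CELLSIZE)) hdr$CELLSIZE else hdr$DY
  if (is.null(dx) || is.null(dy))
    stop("malformed ASCII grid header: missing CELLSIZE (or DX/DY)")
  nodata <- if (is.null(hdr$NODATA_VALUE)) -9999 else hdr$NODATA_VALUE
  nr <- as.integer(hdr$NROWS); nc <- as.integer(hdr$NCOLS)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(crsId)) {
    prj <- .prjPath(path)
    crsId <- if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else "unknown"
  }
  g <- gridSpec(
    nRows = nr, nCols = nc, cellSizeX = dx, cellSizeY = dy,
    originX = hdr$XLLCORNER, originY = hdr$YLLCORNER + nr * dy,
    crsId = crsId, nodata = nodata
  )
  geoRaster(m, g, bandMeaning = bandMeaning)
}
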