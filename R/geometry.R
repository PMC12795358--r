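#' @include AllClasses.R
NULL

# Plane-geometry helpers for the package's light polygon model.  A polygon
# is a list of unclosed n x 2 rings interpreted by the even-odd rule.

.ringUnclose <- function(m) {
  if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m[-nrow(m), , drop = FALSE] else m
}

.ringClose <- function(m) rbind(m, m[1, , drop = FALSE])

# Signed shoelace area of one ring (positive = counter-clockwise).
.ringSignedArea <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Area of a polygon (even-odd rule)
#'
#' Exterior rings add, hole rings subtract, per the even-odd interpretation
#' used throughout the package.
#'
#' @param rings list of n x 2 coordinate matrices.
#' @return numeric(1) area in squared map units.
#' @export
polygonArea <- function(rings) {
  if (!length(rings)) return(0)
  a <- vapply(rings, function(r) abs(.ringSignedArea(.ringUnclose(r))), numeric(1))
  # even-odd: largest ring is exterior; rings nested inside an odd number of
  # others subtract.  For the package's geometries (disjoint parts + simple
  # holes) depth alternation reduces to exterior-minus-holes:
  if (length(rings) == 1L) return(a)
  depth <- vapply(seq_along(rings), function(i) {
    p <- .ringUnclose(rings[[i]])[1, ]
    sum(vapply(seq_along(rings), function(j) {
      if (i == j) return(FALSE)
      r <- .ringUnclose(rings[[j]])
      pracma::inpolygon(p[1], p[2], r[, 1], r[, 2])
    }, logical(1)))
  }, integer(1))
  sum(a * ifelse(depth %% 2 == 0, 1, -1))
}

#' Point-in-polygon test (even-odd over rings)
#'
#' @param x,y coordinate vectors of query points.
#' @param rings list of n x 2 ring matrices.
#' @return logical vector; TRUE where the point is inside (boundary points
#'   count as inside).
#' @export
pointsInPolygon <- function(x, y, rings) {
  inside <- rep(FALSE, length(x))
  for (r in rings) {
    r <- .ringUnclose(r)
    inside <- xor(inside, pracma::inpolygon(x, y, r[, 1], r[, 2],
                                            boundary = TRUE))
  }
  inside
}

# Sutherland-Hodgman: clip one subject ring to a convex clip ring.
# Returns an n x 2 matrix (possibly 0 rows).
.clipRingConvex <- function(subject, clip) {
  clip <- .ringUnclose(clip)
  if (.ringSignedArea(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]  # force CCW
  out <- .ringUnclose(subject)
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1])  # >=0 is inside (left)
    inp <- out; out <- matrix(numeric(), 0, 2)
    n <- nrow(inp)
    sides <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p <- inp[i, ]; q <- inp[j, ]
      pin <- sides[i] >= -1e-12; qin <- sides[j] >= -1e-12
      if (pin) out <- rbind(out, p)
      if (pin != qin) {
        t <- sides[i] / (sides[i] - sides[j])
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  if (nrow(out) >= 3L) out else matrix(numeric(), 0, 2)
}

#' Clip polygons to a convex boundary
#'
#' Ring-wise Sutherland-Hodgman clipping.  The clip polygon (typically the
#' terrestrial land boundary, a grid envelope) must be convex; each ring of
#' each subject polygon is clipped independently, which preserves the
#' even-odd interpretation.
#'
#' @param rings list of subject rings.
#' @param boundary single convex ring (n x 2 matrix).
#' @return list of clipped rings (possibly empty).
#' @export
clipPolygon <- function(rings, boundary) {
  out <- lapply(rings, .clipRingConvex, clip = boundary)
  Filter(function(r) nrow(r) >= 3L && abs(.ringSignedArea(r)) > 1e-9, out)
}

#' Rectangle ring
#' @param xmin,ymin,xmax,ymax corner coordinates.
#' @return a 4 x 2 ring matrix.
#' @export
rectRing <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Regular-polygon approximation of a circle
#' @param cx,cy center; @param r radius; @param n vertex count.
#' @return an n x 2 ring matrix.
#' @export
circleRing <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Construct a PolygonSet (or subclass)
#'
#' @param geometries list of polygons (each a list of rings, or a single
#'   ring matrix which is wrapped).
#' @param attrs data.frame of feature attributes.
#' @param crsId CRS identifier.
#' @param class_ class to instantiate ("PolygonSet", "ProtectedAreaSet",
#'   "RegionSet").
#' @return an object of \code{class_}.
#' @export
polygonSet <- function(geometries, attrs, crsId = "EPSG:2100", class_ = "PolygonSet") {
  geometries <- lapply(geometries, function(g) {
    if (is.matrix(g)) list(.ringUnclose(g)) else lapply(g, .ringUnclose)
  })
  new(class_, geometries = geometries, attrs = attrs, crsId = as.character(crsId))
}

setMethod("show", "PolygonSet", function(object) {
  cat(class(object), "with", length(object@geometries), "features,",
      object@crsId, "\n")
  if (nrow(object@attrs)) {
    cat("  attributes:", paste(names(object@attrs), collapse = ", "), "\n")
  }
})
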