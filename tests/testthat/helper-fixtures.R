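# Shared fixtures: small grids, random masks, a compact synthetic scenario.

grid500 <- function(n = 4, nCols = n, ...) {
  gridSpec(nRows = n, nCols = nCols, cellSize = 500, ...)
}

rasterOf <- function(values, grid, ...) {
  if (!is.matrix(values))
    values <- matrix(values, grid@nRows, grid@nCols)
  geoRaster(values, grid, ...)
}

maskOf <- function(values, grid, label) {
  if (!is.matrix(values))
    values <- matrix(values, grid@nRows, grid@nCols)
  new("CriterionMask", grid = grid, values = values,
      bandMeaning = label, criterionLabel = label)
}

randomStack <- function(grid, pNA = 0) {
  n <- grid@nRows * grid@nCols
  draw <- function(label) {
    v <- sample(c(0, 1), n, replace = TRUE)
    if (pNA > 0) v[stats::runif(n) < pNA] <- NA
    maskOf(matrix(v, grid@nRows, grid@nCols), grid, label)
  }
  criteriaStack(draw("repetitive_fire"), draw("steep_slope"),
                draw("protected_area"))
}

# compact scenario: 24 x 24 analysis cells (12 km extent), 400 x 400 fine
smallScenario <- function(seed = 11L, ...) {
  syntheticScenario(
    seed = seed, nAnalysis = 24L, nFine = 400L,
    hotspots = data.frame(row = 12, col = 6, radius_cells = 3, prob = 0.3),
    planted = matrix(c(5L, 5L, 18L, 16L), 2, 2, byrow = TRUE),
    decoys = list(
      fire_slope = matrix(c(8L, 8L), 1, 2),
      fire_protected = matrix(c(20L, 4L), 1, 2),
      slope_protected = matrix(c(6L, 19L), 1, 2),
      fire = matrix(c(21L, 21L), 1, 2),
      slope = matrix(c(2L, 12L), 1, 2),
      protected = matrix(c(22L, 9L), 1, 2),
      none = matrix(c(12L, 12L), 1, 2)
    ),
    ...
  )
}

# brute-force area-weighted aggregation (independent of aggregateMean)
bruteAggregate <- function(fine, coarseGrid) {
  gf <- fine@grid
  out <- matrix(NA_real_, coarseGrid@nRows, coarseGrid@nCols)
  for (I in seq_len(coarseGrid@nRows)) {
    for (J in seq_len(coarseGrid@nCols)) {
      cx0 <- coarseGrid@originX + (J - 1) * coarseGrid@cellSizeX
      cx1 <- cx0 + coarseGrid@cellSizeX
      cy1 <- coarseGrid@originY - (I - 1) * coarseGrid@cellSizeY
      cy0 <- cy1 - coarseGrid@cellSizeY
      num <- 0; den <- 0
      for (i in seq_len(gf@nRows)) {
        fy1 <- gf@originY - (i - 1) * gf@cellSizeY
        fy0 <- fy1 - gf@cellSizeY
        oy <- min(cy1, fy1) - max(cy0, fy0)
        if (oy <= 0) next
        for (j in seq_len(gf@nCols)) {
          v <- fine@values[i, j]
          if (is.na(v)) next
          fx0 <- gf@originX + (j - 1) * gf@cellSizeX
          fx1 <- fx0 + gf@cellSizeX
          ox <- min(cx1, fx1) - max(cx0, fx0)
          if (ox <= 0) next
          w <- ox * oy
          num <- num + w * v
          den <- den + w
        }
      }
      if (den > 0) out[I, J] <- num / den
    }
  }
  out
}
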