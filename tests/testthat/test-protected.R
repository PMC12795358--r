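paSet <- function(geoms, n = length(geoms), crsId = "EPSG:2100") {
  polygonSet(geoms,
             data.frame(name = sprintf("PA %d", seq_len(n)),
                        designation = "Reserve", iucn_category = "V",
                        marine_flag = FALSE, stringsAsFactors = FALSE),
             crsId = crsId, class_ = "ProtectedAreaSet")
}

test_that("center-rule rasterization sets exactly the covered cell block", {
  g <- gridSpec(4, 4, cellSize = 500)
  # square exactly covering the 2x2 block rows 2-3 / cols 2-3
  ps <- paSet(list(rectRing(500, 500, 1500, 1500)))
  m <- rasterValues(rasterizeMask(ps, g))
  expect_equal(sum(m), 4)
  expect_equal(unname(m[2:3, 2:3]), matrix(1, 2, 2))
})

test_that("a polygon missing the cell center leaves the cell unset", {
  g <- gridSpec(1, 1, cellSize = 500)
  # covers 49% of the cell area (x in [0, 245]) but not the center (250, 250)
  ps <- paSet(list(rectRing(0, 0, 245, 500)))
  expect_equal(rasterValues(rasterizeMask(ps, g))[1, 1], 0)
  # brute-force oracle: explicit point-in-polygon test of the center
  expect_false(pointsInPolygon(250, 250, list(rectRing(0, 0, 245, 500))))
  # extend past the center and the cell flips
  ps2 <- paSet(list(rectRing(0, 0, 255, 500)))
  expect_equal(rasterValues(rasterizeMask(ps2, g))[1, 1], 1)
})

test_that("overlapping polygons union to 1 and order does not matter", {
  g <- gridSpec(3, 3, cellSize = 500)
  a <- rectRing(0, 0, 1500, 750)
  b <- rectRing(0, 0, 750, 1500)
  mAB <- rasterValues(rasterizeMask(paSet(list(a, b)), g))
  mBA <- rasterValues(rasterizeMask(paSet(list(b, a)), g))
  expect_true(all(mAB %in% c(0, 1)))
  expect_equal(mAB, mBA)
  # union semantics: elementwise OR of the single-polygon masks
  mA <- rasterValues(rasterizeMask(paSet(list(a)), g))
  mB <- rasterValues(rasterizeMask(paSet(list(b)), g))
  expect_equal(mAB, pmax(mA, mB))
})

test_that("splitting a polygon into touching halves leaves the mask unchanged", {
  g <- gridSpec(4, 4, cellSize = 500)
  whole <- paSet(list(rectRing(0, 0, 2000, 1000)))
  halves <- paSet(list(rectRing(0, 0, 1200, 1000), rectRing(1200, 0, 2000, 1000)))
  expect_equal(rasterValues(rasterizeMask(whole, g)),
               rasterValues(rasterizeMask(halves, g)))
})

test_that("rasterized area converges to polygon area with finer cells", {
  rect <- rectRing(400, 300, 2100, 1800)  # 1700 x 1500 m = 2.55 km2
  errs <- vapply(c(500, 100, 20), function(cs) {
    n <- as.integer(3000 / cs)
    g <- gridSpec(n, n, cellSize = cs, originY = 3000)
    got <- maskAreaKm2(rasterizeMask(paSet(list(rect)), g))
    abs(got - 2.55)
  }, numeric(1))
  expect_equal(errs[3], 0, tolerance = 1e-9)   # 20 m cells tile it exactly
  expect_true(errs[2] <= errs[1] + 1e-9)       # error shrinks with cell size
})

test_that("rasterization refuses CRS mismatches", {
  ps <- paSet(list(rectRing(0, 0, 500, 500)), crsId = "EPSG:3035")
  expect_error(rasterizeMask(ps, gridSpec(2, 2, cellSize = 500)),
               "does not match grid CRS")
})

test_that("loadProtected clips to land, drops marine polygons, keeps records", {
  dir <- withr::local_tempdir()
  land <- rectRing(0, 0, 3000, 3000)
  polys <- polygonSet(
    list(
      rectRing(500, 500, 1500, 1500),      # fully on land
      rectRing(2500, 1000, 4000, 2000),    # coastal: half off the east edge
      rectRing(5000, 5000, 6000, 6000),    # wholly at sea
      rectRing(600, 600, 1400, 1400)       # overlaps the first (kept separate)
    ),
    data.frame(name = c("Inland", "Coastal", "Marine", "Nested"),
               designation = c("Park", "Refuge", "Marine Park", "Park"),
               iucn_category = c("II", "Not Reported", "IV", "II"),
               stringsAsFactors = FALSE),
    crsId = "EPSG:2100"
  )
  path <- file.path(dir, "pa.geojson")
  writeGeoJSON(polys, path)
  pas <- loadProtected(path, land, crsId = "EPSG:2100")
  inv <- protectedInventory(pas)
  expect_setequal(inv$name, c("Inland", "Coastal", "Nested"))  # marine gone
  expect_equal(inv$clipped_area_km2[inv$name == "Inland"], 1)
  # coastal polygon keeps only its land part: 500 x 1000 m
  expect_equal(inv$clipped_area_km2[inv$name == "Coastal"], 0.5)
  # overlapping records are retained, not dissolved
  expect_equal(nrow(inv), 3)
  # optional category filter
  pas2 <- loadProtected(path, land, crsId = "EPSG:2100", iucnCategories = "II")
  expect_setequal(protectedInventory(pas2)$name, c("Inland", "Nested"))
})

test_that("loadProtected validates CRS and polygon presence", {
  dir <- withr::local_tempdir()
  land <- rectRing(0, 0, 3000, 3000)
  ps <- polygonSet(list(rectRing(0, 0, 100, 100)),
                   data.frame(name = "X", stringsAsFactors = FALSE),
                   crsId = "EPSG:3035")
  path <- file.path(dir, "pa.geojson")
  writeGeoJSON(ps, path)
  expect_error(loadProtected(path, land, crsId = "EPSG:2100"),
               "does not match analysis CRS")
  # all-marine input: nothing survives the clip
  ps2 <- polygonSet(list(rectRing(9000, 9000, 9500, 9500)),
                    data.frame(name = "Sea", stringsAsFactors = FALSE),
                    crsId = "EPSG:2100")
  writeGeoJSON(ps2, path)
  expect_error(loadProtected(path, land, crsId = "EPSG:2100"),
               "no protected-area polygon intersects")
})

test_that("polygon area handles holes by the even-odd rule", {
  outer_ <- rectRing(0, 0, 1000, 1000)
  hole <- rectRing(250, 250, 750, 750)
  expect_equal(polygonArea(list(outer_)), 1e6)
  expect_equal(polygonArea(list(outer_, hole)), 1e6 - 250000)
  # a point inside the hole is outside the polygon
  expect_false(pointsInPolygon(500, 500, list(outer_, hole)))
  expect_true(pointsInPolygon(100, 100, list(outer_, hole)))
})
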