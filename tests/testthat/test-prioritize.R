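test_that("criteria count sums the binary masks with nodata scored as unmet", {
  g <- grid500(2)
  st <- criteriaStack(
    maskOf(matrix(c(1, 1, 0, NA), 2, 2), g, "repetitive_fire"),
    maskOf(matrix(c(1, 0, 0, NA), 2, 2), g, "steep_slope"),
    maskOf(matrix(c(1, 1, 0, NA), 2, 2), g, "protected_area")
  )
  cnt <- rasterValues(criteriaCount(st))
  expect_equal(cnt[1, 1], 3)
  expect_equal(cnt[2, 1], 2)
  expect_equal(cnt[1, 2], 0)
  expect_true(is.na(cnt[2, 2]))  # nodata in all three criteria
  # nodata in one criterion only counts as "not met"
  st2 <- criteriaStack(
    maskOf(matrix(c(1, 1, NA, NA), 2, 2), g, "repetitive_fire"),
    maskOf(matrix(c(1, 1, 1, NA), 2, 2), g, "steep_slope"),
    maskOf(matrix(c(1, 1, 1, NA), 2, 2), g, "protected_area")
  )
  expect_equal(rasterValues(criteriaCount(st2))[1, 2], 2)
})

test_that("the stack constructor enforces labels and alignment", {
  g <- grid500(2)
  m <- function(lab) maskOf(matrix(1, 2, 2), g, lab)
  expect_error(criteriaStack(m("repetitive_fire"), m("repetitive_fire"),
                             m("steep_slope")),
               "labels")
  shifted <- new("CriterionMask",
                 grid = gridSpec(2, 2, cellSize = 500, originX = 250),
                 values = matrix(1, 2, 2), bandMeaning = "",
                 criterionLabel = "protected_area")
  expect_error(criteriaStack(m("repetitive_fire"), m("steep_slope"), shifted),
               "aligned")
})

test_that("preselection keeps two-of-three, final requires all three", {
  g <- grid500(2)
  cnt <- rasterOf(matrix(c(0, 1, 2, 3), 2, 2), g)
  pre <- rasterValues(selectPriority(cnt, "preselect"))
  fin <- rasterValues(selectPriority(cnt, "final"))
  expect_equal(pre[1, 2], 1)   # count 2 preselects ...
  expect_equal(fin[1, 2], 0)   # ... but is not final
  expect_equal(pre[2, 2], 1)   # count 3 selected in both modes
  expect_equal(fin[2, 2], 1)
  expect_equal(pre[1, 1] + fin[1, 1], 0)
  expect_error(selectPriority(rasterOf(4, g), "final"), "outside 0..3")
})

test_that("selection agrees with per-pixel brute-force logic on random stacks", {
  set.seed(20)
  g <- gridSpec(20, 20, cellSize = 500)
  mismatches <- 0L
  for (rep in 1:10) {
    st <- randomStack(g, pNA = 0.05)
    cnt <- criteriaCount(st)
    fin <- rasterValues(selectPriority(cnt, "final"))
    pre <- rasterValues(selectPriority(cnt, "preselect"))
    m1 <- rasterValues(st@masks[[1]]); m2 <- rasterValues(st@masks[[2]])
    m3 <- rasterValues(st@masks[[3]])
    for (i in 1:20) for (j in 1:20) {
      v <- c(m1[i, j], m2[i, j], m3[i, j])
      if (all(is.na(v))) {
        if (!is.na(fin[i, j]) || !is.na(pre[i, j])) mismatches <- mismatches + 1L
        next
      }
      hits <- sum(v == 1, na.rm = TRUE)
      if ((fin[i, j] == 1) != (hits == 3)) mismatches <- mismatches + 1L
      if ((pre[i, j] == 1) != (hits >= 2)) mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("stack order does not change outputs and enlargement is monotone", {
  set.seed(21)
  g <- gridSpec(10, 10, cellSize = 500)
  st <- randomStack(g)
  perm <- criteriaStack(st@masks[[3]], st@masks[[1]], st@masks[[2]])
  expect_equal(rasterValues(criteriaCount(st)), rasterValues(criteriaCount(perm)))
  # enlarging one mask never shrinks the selections
  bigger <- st@masks[[2]]
  v <- bigger@values; v[v == 0][1:10] <- 1
  bigger@values <- v
  st2 <- criteriaStack(st@masks[[1]], bigger, st@masks[[3]])
  expect_true(all(rasterValues(selectPriority(criteriaCount(st2), "final")) >=
                    rasterValues(selectPriority(criteriaCount(st), "final"))))
  expect_true(all(rasterValues(selectPriority(criteriaCount(st2), "preselect")) >=
                    rasterValues(selectPriority(criteriaCount(st), "preselect"))))
})

regions2 <- function() {
  # two regions splitting a 10x10 analysis grid at x = 2500
  polygonSet(
    list(rectRing(0, 0, 2500, 5000), rectRing(2500, 0, 5000, 5000)),
    data.frame(region_name = c("West", "East"), stringsAsFactors = FALSE),
    crsId = "EPSG:2100", class_ = "RegionSet"
  )
}

test_that("zonal tabulation counts pixel centers per region exactly", {
  g <- gridSpec(10, 10, cellSize = 500)
  v <- matrix(0, 10, 10)
  v[1:10, 1:5] <- 1            # 50 pixels in the west half
  v[1, 6] <- 1                 # 1 pixel in the east half
  tab <- zonalTabulate(geoRaster(v, g), regions2())
  expect_equal(tab$pixel_count[tab$region == "West"], 50)
  expect_equal(tab$pixel_count[tab$region == "East"], 1)
  expect_equal(tab$area_km2, tab$pixel_count * 0.25)
  # 91 selected pixels in one region -> 22.75 km2
  g14 <- gridSpec(14, 14, cellSize = 500)
  v3 <- matrix(0, 14, 14); v3[seq_len(91)] <- 1
  regAll <- polygonSet(list(rectRing(0, 0, 7000, 7000)),
                       data.frame(region_name = "Only", stringsAsFactors = FALSE),
                       crsId = "EPSG:2100", class_ = "RegionSet")
  tab3 <- zonalTabulate(geoRaster(v3, g14), regAll)
  expect_equal(tab3$pixel_count, 91)
  expect_equal(tab3$area_km2, 22.75)
})

test_that("zonal tabulation reports empty masks, unassigned pixels and conserves counts", {
  g <- gridSpec(10, 10, cellSize = 500)
  tab0 <- zonalTabulate(geoRaster(matrix(0, 10, 10), g), regions2())
  expect_equal(tab0$pixel_count, c(0, 0))
  # regions covering only y < 2500: top half pixels are unassigned
  regHalf <- polygonSet(
    list(rectRing(0, 0, 2500, 2500), rectRing(2500, 0, 5000, 2500)),
    data.frame(region_name = c("SW", "SE"), stringsAsFactors = FALSE),
    crsId = "EPSG:2100", class_ = "RegionSet"
  )
  v <- matrix(1, 10, 10)
  tab <- zonalTabulate(geoRaster(v, g), regHalf)
  expect_equal(sum(tab$pixel_count), 100)     # conservation incl. _unassigned
  expect_equal(tab$pixel_count[tab$region == "_unassigned"], 50)
})

test_that("a center on a shared boundary lands in exactly one region", {
  # 1x2 grid with 1000 m cells: centers at x = 500 and 1500; regions split
  # exactly through the first center
  g <- gridSpec(1, 2, cellSize = 1000, originY = 1000)
  regSplit <- polygonSet(
    list(rectRing(0, 0, 500, 1000), rectRing(500, 0, 2000, 1000)),
    data.frame(region_name = c("A", "B"), stringsAsFactors = FALSE),
    crsId = "EPSG:2100", class_ = "RegionSet"
  )
  tab <- zonalTabulate(geoRaster(matrix(1, 1, 2), g), regSplit)
  expect_equal(sum(tab$pixel_count), 2)             # partition, no double count
  expect_equal(tab$pixel_count[tab$region == "A"], 1)  # stable first-containing order
})

test_that("prioritize + summarize tie the region table to the final mask", {
  set.seed(22)
  g <- gridSpec(10, 10, cellSize = 500)
  st <- randomStack(g)
  res <- prioritize(st, regions2())
  expect_s4_class(res, "PriorityResult")
  expect_equal(sum(regionTable(res)$pixel_count),
               sum(rasterValues(finalMask(res)) == 1, na.rm = TRUE))
  expect_equal(totalAreaKm2(res),
               sum(rasterValues(finalMask(res)) == 1, na.rm = TRUE) * 0.25)
  summ <- summarizeResult(res)
  expect_equal(summ$consistency, "OK")
  expect_equal(summ$table$region[nrow(summ$table)], "TOTAL")
  expect_equal(summ$table$area_km2[nrow(summ$table)], totalAreaKm2(res))
  # areas sorted descending in the body
  body <- summ$table$area_km2[-nrow(summ$table)]
  expect_true(all(diff(body) <= 0))
})

test_that("focusArea reports the final-mask area inside a site polygon", {
  g <- gridSpec(10, 10, cellSize = 500)
  fin <- matrix(0, 10, 10); fin[1:2, 1:2] <- 1   # 4 pixels in the NW corner
  r <- geoRaster(fin, g)
  # polygon around the NW corner (top-left quarter)
  f <- focusArea(r, rectRing(0, 2500, 2500, 5000))
  expect_equal(f$pixel_count, 4L)
  expect_equal(f$area_km2, 1)
  f2 <- focusArea(r, rectRing(2500, 0, 5000, 2500))
  expect_equal(f2$pixel_count, 0L)
})
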