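bareScenario <- function(seed = 2L, p = 0.05, ...) {
  # no planted pixels, no decoys: pure background fire process
  syntheticScenario(seed = seed, nAnalysis = 24L, nFine = 400L,
                    burnProbBase = p,
                    hotspots = data.frame(row = numeric(), col = numeric(),
                                          radius_cells = numeric(), prob = numeric()),
                    planted = matrix(integer(), 0, 2), decoys = list(), ...)
}

test_that("degenerate burn probabilities give all-zero / all-burn series", {
  s0 <- bareScenario(p = 0)
  comps <- makeFireSeries(s0)
  expect_true(all(vapply(comps, function(r) all(rasterValues(r) == 0), logical(1))))
  s1 <- bareScenario(p = 1)
  freq <- burnFrequency(makeFireSeries(s1))
  nyears <- s1@years[2] - s1@years[1] + 1L
  expect_true(all(rasterValues(freq) == nyears))
})

test_that("empirical burn frequency matches the binomial expectation", {
  s <- bareScenario(seed = 3L, p = 0.05)
  freq <- rasterValues(burnFrequency(makeFireSeries(s)))
  nyears <- s@years[2] - s@years[1] + 1L
  npix <- length(freq)
  expected <- nyears * 0.05
  # binomial oracle for the mean of per-pixel counts (smoothing preserves
  # the mean burn probability); 3 standard errors at n = 576 pixels
  se <- sqrt(nyears * 0.05 * 0.95 / npix)
  expect_lt(abs(mean(freq) - expected), 3 * se)
})

test_that("the generator is bit-reproducible for a fixed seed", {
  s <- smallScenario(seed = 77L)
  a <- makeFireSeries(s)
  b <- makeFireSeries(smallScenario(seed = 77L))
  expect_identical(lapply(a, rasterValues), lapply(b, rasterValues))
  expect_identical(rasterValues(makeDEM(s)),
                   rasterValues(makeDEM(smallScenario(seed = 77L))))
  # a different seed changes the realization
  d <- makeFireSeries(smallScenario(seed = 78L))
  expect_false(identical(lapply(a, rasterValues), lapply(d, rasterValues)))
})

test_that("monthly series composite reproduces the annual series", {
  s <- smallScenario(seed = 5L)
  annual <- makeFireSeries(s, "annual")
  monthly <- makeFireSeries(s, "monthly")
  for (k in seq_along(annual)) {
    comp <- annualComposite(monthly[[k]], annual[[k]]@year)
    expect_equal(rasterValues(comp), rasterValues(annual[[k]]))
  }
})

test_that("planar DEM components give analytically known slopes", {
  mkRamp <- function(gradient) {
    s <- bareScenario()
    s@demSpec$baseGradient <- gradient
    s@demSpec$hills <- s@demSpec$hills[0, ]
    makeDEM(s)
  }
  inner <- function(m) m[5:(nrow(m) - 5), 5:(ncol(m) - 5)]
  # gradient tan(15 deg) to 4 decimals: slope sits on the strict threshold
  sl15 <- inner(rasterValues(computeSlope(mkRamp(0.2679))))
  expect_true(all(abs(sl15 - atan(0.2679) * 180 / pi) < 1e-9))
  expect_true(abs(atan(0.2679) * 180 / pi - 15) < 5e-3)
  # flat terrain
  expect_true(all(inner(rasterValues(computeSlope(mkRamp(0)))) == 0))
  # gradient 0.5774 -> 30 degrees (4-decimal gradient: ~2e-3 degree window)
  sl30 <- inner(rasterValues(computeSlope(mkRamp(0.5774))))
  expect_true(all(abs(sl30 - 30) < 5e-3))
})

test_that("a 15-degree ramp is excluded by the strict threshold everywhere", {
  s <- bareScenario()
  s@demSpec$baseGradient <- tan(15 * pi / 180)
  s@demSpec$hills <- s@demSpec$hills[0, ]
  m <- steepMask(computeSlope(makeDEM(s)), s@analysisGrid)
  expect_equal(sum(rasterValues(m), na.rm = TRUE), 0)
})

test_that("region rectangles partition the grid; overlaps are refused", {
  s <- smallScenario()
  vec <- makeVectors(s)
  ctr <- cellCenters(s@analysisGrid)
  xs <- rep(ctr$x, each = s@analysisGrid@nRows)
  ys <- rep(ctr$y, times = s@analysisGrid@nCols)
  hits <- Reduce(`+`, lapply(vec$regions@geometries, function(gm)
    pointsInPolygon(xs, ys, gm) + 0))
  expect_true(all(hits == 1))   # every center in exactly one region
  s@regionsSpec$col0[2] <- 10L  # make Northeast overlap Northwest columns
  expect_error(makeVectors(s), "partition")
})

test_that("an empty protected layer forces an empty final map", {
  s <- smallScenario(seed = 6L)
  # drop every protected cover: keep planted fire+slope forcing intact
  s@decoys <- s@decoys[c("fire_slope", "fire", "slope", "none")]
  s@planted <- matrix(integer(), 0, 2)
  s@protectedSpec <- list(extras = list())
  vec <- makeVectors(s)
  expect_length(vec$protected@geometries, 0)
  prot <- rasterizeMask(vec$protected, s@analysisGrid)
  expect_equal(sum(rasterValues(prot)), 0)
  freq <- burnFrequency(makeFireSeries(s))
  st <- criteriaStack(repetitiveMask(freq),
                      steepMask(computeSlope(makeDEM(s)), s@analysisGrid),
                      prot)
  fin <- selectPriority(criteriaCount(st), "final")
  expect_equal(sum(rasterValues(fin), na.rm = TRUE), 0)
})

test_that("planted pixels are exactly the all-three-criteria set", {
  s <- smallScenario(seed = 9L)
  freq <- burnFrequency(makeFireSeries(s))
  steep <- steepMask(computeSlope(makeDEM(s)), s@analysisGrid)
  vec <- makeVectors(s)
  prot <- rasterizeMask(vec$protected, s@analysisGrid)
  st <- criteriaStack(repetitiveMask(freq), steep, prot)
  fin <- which(rasterValues(selectPriority(criteriaCount(st), "final")) == 1,
               arr.ind = TRUE)
  truth <- scenarioTruth(s)
  expect_equal(fin[order(fin[, 1]), , drop = FALSE],
               truth$planted[order(truth$planted[, 1]), , drop = FALSE],
               ignore_attr = TRUE)
  # per-pixel criteria check at every special pixel (oracle by construction)
  pre <- rasterValues(selectPriority(criteriaCount(st), "preselect"))
  for (nm in c("fire_slope", "fire_protected", "slope_protected")) {
    px <- truth$decoys[[nm]]
    expect_equal(pre[px[1, 1], px[1, 2]], 1)
  }
  cnt <- rasterValues(criteriaCount(st))
  for (nm in c("fire", "slope", "protected")) {
    px <- truth$decoys[[nm]]
    expect_equal(cnt[px[1, 1], px[1, 2]], 1)
  }
  px <- truth$decoys$none
  expect_equal(cnt[px[1, 1], px[1, 2]], 0)
})

test_that("written scenarios carry truth and a runnable configuration", {
  dir <- withr::local_tempdir()
  s <- smallScenario(seed = 13L)
  writeScenario(s, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(nrow(tr$planted), nrow(s@planted))
  cfg <- readPipelineConfig(file.path(dir, "config.yaml"))
  expect_s4_class(cfg, "PipelineConfig")
  expect_equal(cfg@yearRange, s@years)
  expect_length(list.files(file.path(dir, "burn"), pattern = "\\.asc$"),
                s@years[2] - s@years[1] + 1L)
})
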