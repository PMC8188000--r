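test_that("percentage polygons match hand-computed hulls", {
  sq <- cbind(c(0, 0, 100, 100), c(0, 100, 0, 100))
  core <- percentagePolygon(sq, 100)
  expect_equal(coreArea(core), 1)          # 100 m square = 1 ha
  expect_equal(corePerimeter(core), 400)
  # 8 clustered points + 2 distant outliers at level 80: hull of cluster
  cl <- cbind(c(0, 0, 0, 50, 50, 100, 100, 100), c(0, 50, 100, 0, 100, 0, 50, 100))
  pts <- rbind(cl, c(5000, 5000), c(-5000, 400))
  core80 <- percentagePolygon(pts, 80)
  expect_equal(coreArea(core80), 1)
  expect_equal(corePerimeter(core80), 400)
  # degenerate geometries: zero area, defined perimeter
  expect_equal(coreArea(percentagePolygon(cbind(3, 4), 50)), 0)
  coll <- percentagePolygon(cbind(c(0, 100, 200), c(0, 0, 0)), 100)
  expect_equal(coreArea(coll), 0)
  expect_equal(corePerimeter(coll), 400)   # out-and-back along the segment
  expect_error(percentagePolygon(cbind(numeric(0), numeric(0)), 50),
               "empty")
  expect_error(percentagePolygon(sq, 0), "level")
})

test_that("core profiles are nested: area and perimeter non-decreasing", {
  set.seed(31)
  for (rep in 1:5) {
    pts <- cbind(rnorm(40, sd = 300), rnorm(40, sd = 300))
    cores <- lapply(seq(30, 80, 5), function(l) percentagePolygon(pts, l))
    areas <- vapply(cores, coreArea, numeric(1))
    perims <- vapply(cores, corePerimeter, numeric(1))
    expect_length(cores, 11L)
    expect_true(all(diff(areas) >= -1e-12))
    expect_true(all(diff(perims) >= -1e-12))
  }
  # a 1-pixel territory has zero-area cores at any level
  b <- new("Buzzard", id = 1L, roost = 1L, rgr = integer(0),
           mead = integer(0), x = 12.5, y = 12.5)
  prof <- coreProfile(b, levels = c(50, 100))
  expect_equal(vapply(prof, coreArea, numeric(1)), c(0, 0))
  expect_length(coreProfile(b), 11L)
})

test_that("pairwise overlaps report ordered intersection percentages", {
  mkCore <- function(id, pts) percentagePolygon(pts, 100, id = id)
  sqA <- cbind(c(0, 0, 100, 100), c(0, 100, 0, 100))
  # identical squares: both directions 100%
  ov <- pairwiseOverlaps(list(mkCore(1, sqA), mkCore(2, sqA)))
  expect_equal(nrow(ov), 2L)
  expect_equal(ov$overlapPct, c(100, 100))
  # disjoint squares: no records
  sqB <- sqA + 1000
  expect_equal(nrow(pairwiseOverlaps(list(mkCore(1, sqA), mkCore(2, sqB)))),
               0L)
  # right-half overlap: 50% of A, 100% of B
  half <- cbind(c(50, 50, 100, 100), c(0, 100, 0, 100))
  ov2 <- pairwiseOverlaps(list(mkCore(1, sqA), mkCore(2, half)))
  expect_equal(ov2$overlapPct[ov2$birdA == 1], 50)
  expect_equal(ov2$overlapPct[ov2$birdA == 2], 100)
  # intersection area symmetric: pct ratio equals inverse area ratio
  expect_equal(ov2$overlapPct[1] * coreArea(mkCore(1, sqA)),
               ov2$overlapPct[2] * coreArea(mkCore(2, half)))
  # symmetric mode: one record, intersection over union
  ovs <- pairwiseOverlaps(list(mkCore(1, sqA), mkCore(2, half)),
                          symmetric = TRUE)
  expect_equal(nrow(ovs), 1L)
  expect_equal(ovs$overlapPct, 100 * 0.5 / 1.0)
  # zero-area cores are skipped with a message
  expect_message(
    ovz <- pairwiseOverlaps(list(mkCore(1, sqA), mkCore(2, cbind(0, 0)))),
    "zero-area")
  expect_equal(nrow(ovz), 0L)
  expect_error(pairwiseOverlaps(list(mkCore(1, sqA),
                                     percentagePolygon(sqA, 50))),
               "same level")
})

test_that("abundance counts only core roosts; strip birds still block", {
  # one kit with roost inside a narrow core, another outside it
  m <- kitLandscape(2, seed = 17)
  res <- runSimulation(m, seed = 3)
  expect_identical(nBirds(res), 2L)
  roosts <- vapply(birds(res), function(b) b@roost[1], integer(1))
  g <- resourceGrid(m)
  nr <- nrow(g)
  ps <- pixelSize(m)
  # core rectangle containing only the first roost
  x1 <- (((roosts[1] - 1) %/% nr)) * ps
  mask1 <- makeStudyMask(m, c(x1, x1 + ps, 0, nrow(g) * ps), stripWidth = 0)
  expect_identical(abundance(res, mask1), 1L)
  full <- makeStudyMask(m, stripWidth = 0)
  expect_identical(abundance(res, full), 2L)
  # strip bird's territory still blocks pixels: owner grid unaffected
  expect_identical(sort(unique(as.vector(res@owner))), c(0L, 1L, 2L))
  empty <- new("SimulationResult", birds = list(),
               owner = matrix(0L, nrow(g), ncol(g)), map = m,
               seed = 1L, failedAttempts = 0L, draws = list())
  expect_identical(abundance(empty, full), 0L)
})

test_that("occupancy raster reproduces defended sets with flagged roosts", {
  m <- smallRandomMap(9, n = 25)
  res <- runSimulation(m, smallParams(), seed = 12)
  occ <- occupancyRaster(res)
  totalDefended <- sum(vapply(birds(res), function(b)
    length(territoryPixels(b)), integer(1)))
  expect_identical(sum(occ != 0L), totalDefended)
  for (b in birds(res)) {
    expect_identical(sort(which(occ == b@id | occ == -b@id)),
                     sort(territoryPixels(b)))
    expect_identical(which(occ == -b@id), b@roost)
  }
  noBirds <- runSimulation(resourceMap(matrix("water", 5, 5)), seed = 1)
  expect_true(all(occupancyRaster(noBirds) == 0L))
})
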