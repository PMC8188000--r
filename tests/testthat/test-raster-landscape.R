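test_that("land-cover translation maps categories and defaults to 'other'", {
  lc <- matrix(c(1L, 3L, 2L, 1L), 2, 2)  # [[1,2],[3,1]] row-wise
  mp <- data.frame(mapCat = 1:2, resource = c("woodland", "meadow"))
  out <- resourceGrid(translateLandcover(lc, mp))
  codes <- resourceCodes()
  expect_identical(out, matrix(codes[c("woodland", "other", "meadow",
                                       "woodland")], 2, 2))
  # identity case: all mapped to one class
  allw <- translateLandcover(matrix(1L, 10, 10),
                             data.frame(mapCat = 1, resource = "woodland"))
  expect_identical(sum(resourceGrid(allw) == codes[["woodland"]]), 100L)
  # NODATA becomes water
  lc[2, 2] <- NA
  expect_identical(resourceGrid(translateLandcover(lc, mp))[2, 2],
                   codes[["water"]])
  expect_error(translateLandcover(matrix(integer(0), 0, 0), mp),
               "non-empty")
})

test_that("translation conserves pixel counts per class (brute force)", {
  set.seed(11)
  for (rep in 1:5) {
    lc <- matrix(sample(0:9, 200, replace = TRUE), 10, 20)
    mp <- data.frame(mapCat = c(1, 2, 3, 4),
                     resource = c("woodland", "rough", "meadow", "water"))
    out <- resourceGrid(translateLandcover(lc, mp))
    codes <- resourceCodes()
    for (k in seq_len(nrow(mp)))
      expect_identical(sum(out == codes[[mp$resource[k]]]),
                       sum(lc == mp$mapCat[k]))
    expect_identical(sum(out == codes[["other"]]),
                     sum(!lc %in% mp$mapCat))
  }
})

test_that("patch labelling honours connectivity and partitions the class", {
  m <- mapFromStrings(c("m..",
                        ".m.",
                        "..."))
  expect_length(labelPatches(m, "meadow", connectivity = 4), 2L)
  expect_length(labelPatches(m, "meadow", connectivity = 8), 1L)
  # plus-shaped patch: one patch of 5 pixels = 0.3125 ha at 25 m
  plus <- mapFromStrings(c(".m.",
                           "mmm",
                           ".m."))
  p <- labelPatches(plus, "meadow", connectivity = 4)
  expect_length(p, 1L)
  expect_equal(p[[1]]$areaHa, 5 * 0.0625)
  # absent resource
  expect_identical(labelPatches(plus, "rough"), list())
})

test_that("patch labelling matches a transitive-closure oracle", {
  for (seed in c(2, 7, 19)) {
    m <- smallRandomMap(seed, n = 15)
    for (conn in c(4, 8)) {
      got <- labelPatches(m, "meadow", connectivity = conn)
      want <- bruteForcePatches(m, "meadow", connectivity = conn)
      expect_identical(unname(lapply(got, `[[`, "pixels"))[
        order(vapply(got, function(p) p$pixels[1], integer(1)))],
        unname(want)[order(vapply(want, `[`, integer(1), 1))])
      # partition: union equals the class, pairwise disjoint
      all <- unlist(lapply(got, `[[`, "pixels"))
      expect_identical(sort(all),
                       which(resourceGrid(m) == resourceCodes()[["meadow"]]))
      expect_false(anyDuplicated(all) > 0)
      # areas sum exactly to class pixel count x pixel area
      expect_equal(sum(vapply(got, `[[`, numeric(1), "areaHa")),
                   length(all) * pixelAreaHa(m))
    }
  }
})

test_that("study mask marks pixel centres inside the core extent", {
  m <- resourceMap(matrix("other", 260, 900), pixelSize = 25)
  mask <- makeStudyMask(m, c(0, 22000, 0, 6000), stripWidth = 500)
  expect_identical(sum(mask@core), 880L * 240L)
  expect_equal(mask@stripWidth, 500)
  # full world core
  full <- makeStudyMask(m, stripWidth = 0)
  expect_true(all(full@core))
  expect_error(makeStudyMask(m, c(0, 23000, 0, 6000)), "exceeds")
})

test_that("ASCII grid round trip is exact and NODATA reads as water", {
  m <- mapFromStrings(c("wmr..",
                        "m~m.w",
                        "rrmm.",
                        ".w..m",
                        "mmmmm"), origin = c(1000, 2000))
  f <- withr::local_tempfile(fileext = ".asc")
  writeResourceMap(m, f)
  back <- readResourceMap(f)
  expect_identical(resourceGrid(back), resourceGrid(m))
  expect_equal(pixelSize(back), pixelSize(m))
  expect_equal(mapOrigin(back), mapOrigin(m))
  # NODATA cells become water
  lines <- readLines(f)
  body <- strsplit(lines[7], " ")[[1]]
  body[1] <- "-9999"
  writeLines(c(lines[1:6], paste(body, collapse = " "), lines[8:11]), f)
  expect_identical(resourceGrid(readResourceMap(f))[1, 1],
                   resourceCodes()[["water"]])
  # unknown codes rejected
  body[1] <- "17"
  writeLines(c(lines[1:6], paste(body, collapse = " "), lines[8:11]), f)
  expect_error(readResourceMap(f), "unknown resource code")
})

test_that("kit landscapes place verifiable, well-separated kits", {
  m <- kitLandscape(3, seed = 41)
  codes <- resourceCodes()
  g <- resourceGrid(m)
  wood <- which(g == codes[["woodland"]])
  expect_length(wood, 3L)
  expect_length(labelPatches(m, "rough"), 3L)
  expect_length(labelPatches(m, "meadow"), 3L)
  # every kit's patches lie within the stated radii of its woodland pixel
  for (p in labelPatches(m, "rough")) {
    d <- vapply(wood, function(w) max(pixelDistM(m, p$pixels, w)),
                numeric(1))
    expect_true(any(d <= 500))
  }
  for (p in labelPatches(m, "meadow")) {
    d <- vapply(wood, function(w) max(pixelDistM(m, p$pixels, w)),
                numeric(1))
    expect_true(any(d <= 1200))
  }
  # kit separation
  expect_true(all(dist(cbind((wood - 1) %% nrow(g), (wood - 1) %/% nrow(g)))
                  * pixelSize(m) > 2 * 1200))
  # determinism and the zero-kit degenerate case
  expect_identical(resourceGrid(kitLandscape(3, seed = 41)), g)
  expect_true(all(resourceGrid(kitLandscape(0)) == codes[["other"]]))
  expect_error(kitLandscape(4, worldCols = 50, worldRows = 50),
               "cannot place")
})

test_that("stochastic landscapes hit cover targets and are reproducible", {
  m <- syntheticLandscape(80, 80, seed = 13)
  g <- resourceGrid(m)
  codes <- resourceCodes()
  fr <- function(code) mean(g == codes[[code]])
  expect_equal(fr("meadow"), 0.30, tolerance = 0.02)
  expect_equal(fr("rough"), 0.08, tolerance = 0.02)
  expect_equal(fr("woodland"), 0.02, tolerance = 0.01)
  expect_identical(resourceGrid(syntheticLandscape(80, 80, seed = 13)), g)
  expect_false(identical(resourceGrid(syntheticLandscape(80, 80, seed = 14)),
                         g))
})
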