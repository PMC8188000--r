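test_that("claimPatch floods exactly the free connected component", {
  # isolated free pixel
  m <- mapFromStrings(c("r....",
                        ".....",
                        "..r..",
                        ".rrr.",
                        "..r.."))
  st <- newWorldState(m)
  one <- which(resourceGrid(m) == resourceCodes()[["rough"]])[1]
  expect_identical(claimPatch(st, 1L, "rough", 1L), 1L)
  # plus-shaped patch from its centre
  centre <- 3L + 2L * 5L  # (row 3, col 3)
  got <- claimPatch(st, centre, "rough", 2L)
  expect_length(got, 5L)
  expect_true(all(st@env$owner[got] == 2L))
  expect_false(any(st@env$free[got]))
  # wrong-resource and non-free seeds violate the contract
  expect_error(claimPatch(st, 2L, "rough", 3L), "not of resource")
  expect_error(claimPatch(st, centre, "rough", 3L), "not free")
})

test_that("a pixel defended by another bird splits the component", {
  m <- mapFromStrings(c("mmmmm"))
  st <- newWorldState(m)
  st@env$free[3L] <- FALSE  # middle pixel already defended
  st@env$owner[3L] <- 99L
  left <- claimPatch(st, 1L, "meadow", 1L)
  expect_identical(left, c(1L, 2L))
  right <- claimPatch(st, 5L, "meadow", 2L)
  expect_identical(right, c(4L, 5L))
})

test_that("acquireResource claims whole patches until the requirement", {
  # one 10-pixel rough patch within 500 m: requirement 0.56 ha = 9 px,
  # whole-patch rule claims all 10
  m <- mapFromStrings(c("w.rrrrr...",
                        "..rrrrr..."))
  st <- newWorldState(m)
  set.seed(1)
  out <- acquireResource(st, 1L, 1L, "rough", 0.56, 500)
  expect_true(out$success)
  expect_length(out$pixels, 10L)
  # only 8 free pixels reachable: failure after exhausting seeds
  m8 <- mapFromStrings(c("w.rrrr....",
                         "..rrrr...."))
  st8 <- newWorldState(m8)
  set.seed(1)
  out8 <- acquireResource(st8, 1L, 1L, "rough", 0.56, 500)
  expect_false(out8$success)
  expect_length(out8$pixels, 8L)
  # zero requirement succeeds immediately, defending nothing
  st0 <- newWorldState(m)
  out0 <- acquireResource(st0, 1L, 1L, "rough", 0, 500)
  expect_true(out0$success)
  expect_length(out0$pixels, 0L)
  expect_length(out0$seeds, 0L)
})

test_that("seeds outside the search distance are never drawn", {
  # rough patch >500 m from the roost: distance-constrained seed search
  # cannot start there even though plenty of rough exists
  g <- matrix("other", 5, 40)
  g[1, 1] <- "woodland"
  g[1:5, 30:33] <- "rough"  # >= 29 cols away = 725 m
  m <- resourceMap(g, pixelSize = 25)
  st <- newWorldState(m)
  set.seed(2)
  out <- acquireResource(st, 1L, 1L, "rough", 0.56, 500)
  expect_false(out$success)
  expect_length(out$seeds, 0L)
})

test_that("settleOne succeeds on a viable kit and fails cleanly otherwise", {
  m <- kitLandscape(1, seed = 8)
  st <- newWorldState(m)
  set.seed(1)
  out <- settleOne(st, simulationParams(), id = 1L)
  expect_s4_class(out$bird, "Buzzard")
  expect_true(out$attempt$settled)
  b <- out$bird
  px <- pixelAreaHa(m)
  expect_gte(length(b@rgr) * px, 0.56)
  expect_gte(length(b@mead) * px, 13.5)
  expect_identical(resourceGrid(m)[b@roost], resourceCodes()[["woodland"]])
  expect_length(b@x, length(territoryPixels(b)))

  # woodland + rough but no meadow: failure releases forage, marks roost
  noMead <- mapFromStrings(c("w.rrrrrrrr",
                             "..rrrrrrrr"))
  st2 <- newWorldState(noMead)
  set.seed(1)
  out2 <- settleOne(st2, smallParams(), id = 1L)
  expect_null(out2$bird)
  e <- st2@env
  expect_true(all(e$free[which(resourceGrid(noMead) ==
                                 resourceCodes()[["rough"]])]))
  expect_true(all(e$owner == 0L))
  expect_true(e$tried[out2$attempt$roost])
  # roost now tried: no candidates left
  expect_error(settleOne(st2, smallParams(), id = 2L), "no free, untried")
})

test_that("runs stop at woodland exhaustion with exact packing on kits", {
  m <- kitLandscape(3, seed = 5)
  for (s in c(1, 99)) {
    res <- runSimulation(m, seed = s)
    expect_identical(nBirds(res), 3L)
    expect_identical(res@failedAttempts, 0L)
  }
  # all-water map: nothing happens
  water <- resourceMap(matrix("water", 10, 10))
  res0 <- runSimulation(water, seed = 1)
  expect_identical(nBirds(res0), 0L)
  expect_length(res0@draws, 0L)
})

test_that("fixed seed gives bitwise-identical results", {
  m <- smallRandomMap(4)
  r1 <- runSimulation(m, smallParams(), seed = 7)
  r2 <- runSimulation(m, smallParams(), seed = 7)
  expect_identical(r1@owner, r2@owner)
  expect_identical(r1@draws, r2@draws)
  expect_equal(r1@birds, r2@birds)
  r3 <- runSimulation(m, smallParams(), seed = 8)
  expect_false(identical(r1@draws, r3@draws))
})

test_that("every run satisfies the settlement invariants", {
  for (s in 1:5) {
    m <- smallRandomMap(s, n = 25)
    p <- smallParams()
    res <- runSimulation(m, p, seed = 100 + s)
    px <- pixelAreaHa(m)
    g <- resourceGrid(m)
    codes <- resourceCodes()
    seen <- integer(0)
    for (b in birds(res)) {
      terr <- territoryPixels(b)
      # exclusivity across birds
      expect_length(intersect(terr, seen), 0L)
      seen <- c(seen, terr)
      # sufficiency and roost habitat
      expect_gte(length(b@rgr) * px, p@rgrAreaHa)
      expect_gte(length(b@mead) * px, p@meadAreaHa)
      expect_identical(unique(g[b@roost]), codes[["woodland"]])
      # resource identity of defended pixels
      expect_true(all(g[b@rgr] == codes[["rough"]]))
      expect_true(all(g[b@mead] == codes[["meadow"]]))
      # owner grid agrees with the bird's pixel set
      expect_identical(sort(which(res@owner == b@id)), sort(terr))
    }
    # seed-distance soundness from the recorded draws
    for (att in res@draws) {
      if (length(att$rgrSeeds))
        expect_true(all(pixelDistM(m, att$rgrSeeds, att$roost) <=
                          p@rgrDistM))
      if (length(att$meadSeeds))
        expect_true(all(pixelDistM(m, att$meadSeeds, att$roost) <=
                          p@meadDistM))
    }
    # termination bookkeeping: attempts = settled + failed, and every
    # woodland pixel ends owned, tried or unreachable-free
    expect_identical(length(res@draws),
                     nBirds(res) + res@failedAttempts)
  }
})

test_that("the engine replays exactly under the brute-force oracle", {
  for (s in 1:10) {
    m <- smallRandomMap(s, n = 20)
    p <- smallParams()
    res <- runSimulation(m, p, seed = 40 + s)
    rep <- oracleReplay(m, p, res@draws)
    expect_identical(length(rep$birds), nBirds(res))
    for (i in seq_along(rep$birds)) {
      b <- birds(res)[[i]]
      expect_identical(rep$birds[[i]]$roost, b@roost[1])
      expect_identical(sort(rep$birds[[i]]$rgr), sort(b@rgr))
      expect_identical(sort(rep$birds[[i]]$mead), sort(b@mead))
    }
    expect_identical(rep$owner, res@owner)
  }
})

test_that("replicate summaries are exact on a deterministic construction", {
  m <- kitLandscape(3, seed = 5)
  rep <- runReplicates(m, nRuns = 10, baseSeed = 1)
  expect_equal(rep$mean, 3)
  expect_equal(rep$ci, c(3, 3))
  expect_equal(rep$range, c(3, 3))
  one <- runReplicates(m, nRuns = 1, baseSeed = 5)
  expect_equal(one$mean, one$abundance[1])
})
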