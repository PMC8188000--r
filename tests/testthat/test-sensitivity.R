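test_that("Morris effects are exact on a linear model", {
  lin <- function(p) c(y = 2 * p[["a"]] + p[["b"]])
  m <- morrisScreening(lin, lower = c(a = 0, b = 0), upper = c(a = 1, b = 1),
                       levels = 4, trajectories = 8, seed = 2)
  s <- m$summary
  expect_equal(s$mu[s$parameter == "a"], 2)
  expect_equal(s$mu[s$parameter == "b"], 1)
  expect_equal(s$muStar[s$parameter == "a"], 2)
  expect_equal(s$sigma, c(0, 0), tolerance = 1e-12)
  expect_equal(unique(s$n), 8L)
  # range scaling: effects are per full range traversal
  lin2 <- function(p) c(y = p[["a"]])
  m2 <- morrisScreening(lin2, lower = c(a = 100), upper = c(a = 300),
                        trajectories = 3, seed = 1)
  expect_equal(m2$summary$mu, 200)
})

test_that("Morris on a constant model gives zero effects everywhere", {
  cst <- function(p) c(u = 5, v = -1)
  m <- morrisScreening(cst, lower = c(a = 0, b = -2), upper = c(a = 1, b = 2),
                       trajectories = 5, seed = 3)
  expect_true(all(m$summary$mu == 0))
  expect_true(all(m$summary$muStar == 0))
  expect_equal(nrow(m$summary), 4L)  # 2 parameters x 2 outputs
})

test_that("Morris aggregates equal brute-force recomputation from raw effects", {
  set.seed(4)
  bumpy <- function(p) c(y = p[["a"]]^2 - 3 * p[["b"]] + p[["a"]] * p[["b"]])
  m <- morrisScreening(bumpy, lower = c(a = 0, b = 0),
                       upper = c(a = 2, b = 2), trajectories = 12, seed = 9)
  for (pn in c("a", "b")) {
    ee <- m$effects$ee[m$effects$parameter == pn & !is.na(m$effects$ee)]
    row <- m$summary[m$summary$parameter == pn, ]
    expect_equal(row$mu, mean(ee))
    expect_equal(row$muStar, mean(abs(ee)))
    expect_equal(row$sigma, sd(ee))
  }
})

test_that("a failing evaluator is recorded as missing, not fatal", {
  flaky <- local({
    calls <- 0L
    function(p) {
      calls <<- calls + 1L
      if (calls == 2L) stop("boom")
      c(y = p[["a"]])
    }
  })
  expect_warning(
    m <- morrisScreening(flaky, lower = c(a = 0), upper = c(a = 1),
                         trajectories = 3, seed = 5),
    "evaluator failed")
  expect_true(anyNA(m$effects$ee))
  expect_true(nrow(m$summary) >= 1L)
})

test_that("the ABM evaluator reports the six screened outputs", {
  m <- smallRandomMap(6, n = 30)
  ev <- abmEvaluator(m, baseParams = smallParams(), seed = 4)
  out <- ev(c(meadAreaHa = 0.75))
  expect_named(out, c("abundance", "overlap80", "area40", "area80",
                      "perim40", "perim80"))
  expect_true(out[["abundance"]] >= 0)
  # identical parameter vectors give identical outputs (common seed)
  expect_identical(out, ev(c(meadAreaHa = 0.75)))
  # a harsher meadow requirement cannot raise abundance on the same seed
  harsh <- ev(c(meadAreaHa = 3))
  expect_lte(harsh[["abundance"]], out[["abundance"]])
})

test_that("full factorial evaluates every cell deterministically", {
  m <- smallRandomMap(6, n = 30)
  p <- smallParams()
  ff <- fullFactorial(m, baseParams = p,
                      meadAreaGrid = c(0.5, 0.75, 1),
                      meadDistGrid = c(300, 350),
                      runsPerCell = 1, baseSeed = 11)
  expect_equal(nrow(ff$table), 6L)
  expect_length(ff$marginals$meadAreaHa, 3L)
  # per-cell seeding: rerun reproduces the table exactly
  ff2 <- fullFactorial(m, baseParams = p,
                       meadAreaGrid = c(0.5, 0.75, 1),
                       meadDistGrid = c(300, 350),
                       runsPerCell = 1, baseSeed = 11)
  expect_identical(ff$table, ff2$table)
  # the published axes give 81 cells (checked on the default grids)
  cells <- expand.grid(seq(9.5, 17.5, by = 1), seq(800, 1600, by = 100))
  expect_equal(nrow(cells), 81L)
})
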