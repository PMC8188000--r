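# Brute-force replay simulator. Re-executes a settlement run from the
# recorded random draws (roost pixel, then forage seed pixels in claim
# order) using deliberately naive algorithms: one-pixel-at-a-time
# transitive-closure connected components and full-grid distance scans.
# Asserts that every recorded draw was legal at the moment it was
# consumed, and returns the final per-bird pixel sets and owner grid for
# exact comparison with the engine. Assumes whole-patch claims and a
# one-pixel roost (the defaults).
oracleReplay <- function(map, params, draws) {
  g <- resourceGrid(map)
  nr <- nrow(g); nc <- ncol(g)
  ps <- pixelSize(map)
  pxHa <- (ps / 100)^2
  codes <- resourceCodes()
  conn <- params@connectivity
  free <- matrix(as.vector(g) %in% codes[c("woodland", "rough", "meadow")],
                 nr, nc)
  tried <- matrix(FALSE, nr, nc)
  owner <- matrix(0L, nr, nc)
  rowOf <- function(i) (i - 1L) %% nr + 1L
  colOf <- function(i) (i - 1L) %/% nr + 1L

  adjacent <- function(i, j) {
    dr <- abs(rowOf(i) - rowOf(j)); dc <- abs(colOf(i) - colOf(j))
    if (conn == 4L) dr + dc == 1L else max(dr, dc) == 1L && (dr + dc) > 0L
  }
  component <- function(seed, code) {
    comp <- seed
    repeat {
      added <- FALSE
      for (px in which(g == code & free)) {
        if (px %in% comp) next
        for (q in comp) {
          if (adjacent(px, q)) {
            comp <- c(comp, px); added <- TRUE; break
          }
        }
      }
      if (!added) break
    }
    sort(comp)
  }
  eligSeeds <- function(roost, code, dist) {
    cand <- which(g == code & free)
    if (!length(cand)) return(integer(0))
    dx <- (colOf(cand) - colOf(roost)) * ps
    dy <- (rowOf(cand) - rowOf(roost)) * ps
    cand[sqrt(dx^2 + dy^2) <= dist]
  }

  birdsO <- list()
  attempts <- logical(0)
  for (att in draws) {
    id <- length(birdsO) + 1L
    roost <- att$roost
    stopifnot(g[roost] == codes[["woodland"]], free[roost], !tried[roost])
    free[roost] <- FALSE
    owner[roost] <- id
    phase <- function(seeds, code, req, dist) {
      acquired <- 0
      px <- integer(0)
      for (s in seeds) {
        stopifnot(acquired < req - 1e-9)        # engine had not stopped yet
        stopifnot(s %in% eligSeeds(roost, code, dist))
        comp <- component(s, code)
        free[comp] <<- FALSE
        owner[comp] <<- id
        px <- c(px, comp)
        acquired <- acquired + length(comp) * pxHa
      }
      success <- acquired >= req - 1e-9
      if (!success)                              # exhaustion, not truncation
        stopifnot(length(eligSeeds(roost, code, dist)) == 0L)
      list(success = success, px = px)
    }
    rgr <- phase(att$rgrSeeds, codes[["rough"]], params@rgrAreaHa,
                 params@rgrDistM)
    mead <- list(success = FALSE, px = integer(0))
    if (rgr$success)
      mead <- phase(att$meadSeeds, codes[["meadow"]], params@meadAreaHa,
                    params@meadDistM)
    settled <- rgr$success && mead$success
    stopifnot(identical(settled, att$settled))
    if (settled) {
      birdsO[[id]] <- list(roost = roost, rgr = rgr$px, mead = mead$px)
    } else {
      release <- c(rgr$px, mead$px)
      free[release] <- TRUE
      owner[release] <- 0L
      free[roost] <- TRUE
      owner[roost] <- 0L
      tried[roost] <- TRUE
    }
    attempts <- c(attempts, settled)
  }
  # termination reached: no free, untried woodland can remain
  stopifnot(!any(g == codes[["woodland"]] & free & !tried))
  list(birds = birdsO, owner = owner, attempts = attempts)
}

# Scaled-down parameters for small-map oracle and property tests: same
# structure as the defaults but requirements a 30 x 30 world can hold.
smallParams <- function(...) {
  simulationParams(rgrAreaHa = 0.25, rgrDistM = 200,
                   meadAreaHa = 0.75, meadDistM = 350, ...)
}

smallRandomMap <- function(seed, n = 30) {
  syntheticLandscape(n, n, seed = seed,
                     woodlandFrac = 0.05, roughFrac = 0.12,
                     meadowFrac = 0.25,
                     woodlandPatchHa = c(0.0625, 0.2),
                     roughPatchHa = c(0.0625, 0.3),
                     meadowMeanLogHa = log(0.3), meadowSdLogHa = 0.5)
}
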