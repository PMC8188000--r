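#' @include AllClasses.R resourceMap.R
NULL

#' Construct simulation parameters
#'
#' Defaults are the RADA estimates and calibrated search distances for
#' common buzzards in lowland UK: a one-pixel (0.06 ha) woodland roost,
#' 0.56 ha of rough-ground found from seeds within 500 m of the roost, and
#' 13.5 ha of meadow found from seeds within 1200 m.
#'
#' @param roostAreaHa,rgrAreaHa,rgrDistM,meadAreaHa,meadDistM,connectivity,wholePatch
#'   see [SimulationParams-class].
#' @return A [SimulationParams] object.
#' @examples
#' simulationParams(meadAreaHa = 10)
#' @export
simulationParams <- function(roostAreaHa = 0.06, rgrAreaHa = 0.56,
                             rgrDistM = 500, meadAreaHa = 13.5,
                             meadDistM = 1200, connectivity = 8,
                             wholePatch = TRUE) {
  new("SimulationParams", roostAreaHa = roostAreaHa, rgrAreaHa = rgrAreaHa,
      rgrDistM = rgrDistM, meadAreaHa = meadAreaHa, meadDistM = meadDistM,
      connectivity = as.integer(connectivity), wholePatch = wholePatch)
}

#' Create the mutable world state for a settlement run
#'
#' Initialises the per-pixel records the engine mutates: resource code,
#' availability (resource pixels start free; "other" and "water" are never
#' claimable), tried-roost flags and owner IDs.
#'
#' @param map a [ResourceMap].
#' @param connectivity pixel adjacency for flood-fill claims, 4 or 8.
#' @return A [WorldState].
#' @examples
#' st <- newWorldState(kitLandscape(1, seed = 1))
#' st
#' @export
newWorldState <- function(map, connectivity = 8) {
  e <- new.env(parent = emptyenv())
  e$res <- map@grid
  e$nr <- nrow(map@grid)
  e$nc <- ncol(map@grid)
  e$pixelSize <- map@pixelSize
  e$origin <- map@origin
  e$free <- map@grid %in% .RES_CODES[c("woodland", "rough", "meadow")] &
    array(TRUE, dim(map@grid))
  dim(e$free) <- dim(map@grid)
  e$tried <- matrix(FALSE, e$nr, e$nc)
  e$owner <- matrix(0L, e$nr, e$nc)
  e$offsets <- .neighbourOffsets(as.integer(connectivity))
  e$woodCand <- which(map@grid == .RES_CODES[["woodland"]])
  new("WorldState", env = e)
}

.drawOne <- function(v) if (length(v) == 1L) v else v[sample.int(length(v), 1L)]

#' Claim the free patch containing a seed pixel
#'
#' Flood-fills the connected component of *free* same-resource pixels
#' containing \code{seedPixel} (pixels already defended by other birds are
#' excluded, which may split a landscape patch) and marks every returned
#' pixel as defended by \code{birdId}.
#'
#' @param state a [WorldState] (mutated in place).
#' @param seedPixel linear pixel index; must be free and of \code{resource}.
#' @param resource resource name.
#' @param birdId owner ID to record.
#' @param maxPixels claim at most this many pixels (used when truncated,
#'   non-whole-patch claims are configured).
#' @return Integer vector of claimed pixel indices (sorted).
#' @examples
#' st <- newWorldState(kitLandscape(1, seed = 1))
#' rgrSeed <- which(resourceGrid(kitLandscape(1, seed = 1)) == 2L)[1]
#' length(claimPatch(st, rgrSeed, "rough", 1L))
#' @export
claimPatch <- function(state, seedPixel, resource, birdId,
                       maxPixels = Inf) {
  e <- state@env
  code <- .resCode(resource)
  if (e$res[seedPixel] != code)
    stop("claimPatch: seed pixel is not of resource '", resource, "'")
  if (!e$free[seedPixel])
    stop("claimPatch: seed pixel is not free")
  ## breadth-first flood over free same-resource pixels; claimed pixels are
  ## withdrawn from `free` immediately, which doubles as the visited mark
  seen <- seedPixel
  e$free[seedPixel] <- FALSE
  frontier <- seedPixel
  while (length(frontier) && length(seen) < maxPixels) {
    nb <- unique(.neighboursOf(frontier, e$nr, e$nc, e$offsets))
    nb <- nb[e$free[nb] & e$res[nb] == code]
    if (!length(nb)) break
    if (length(seen) + length(nb) > maxPixels)
      nb <- nb[seq_len(maxPixels - length(seen))]
    e$free[nb] <- FALSE
    seen <- c(seen, nb)
    frontier <- nb
  }
  comp <- sort(seen)
  e$owner[comp] <- as.integer(birdId)
  comp
}

## Free pixels of `code` whose centres lie within distM of the roost centre.
.eligibleSeeds <- function(e, roost, code, distM) {
  rPx <- distM / e$pixelSize
  row0 <- (roost - 1L) %% e$nr + 1L
  col0 <- (roost - 1L) %/% e$nr + 1L
  rad <- floor(rPx)
  rows <- max(1L, row0 - rad):min(e$nr, row0 + rad)
  cols <- max(1L, col0 - rad):min(e$nc, col0 + rad)
  idx <- as.vector(outer((cols - 1L) * e$nr, rows, `+`))
  idx <- idx[e$res[idx] == code & e$free[idx]]
  if (!length(idx)) return(integer(0))
  dr <- (idx - 1L) %% e$nr + 1L - row0
  dc <- (idx - 1L) %/% e$nr + 1L - col0
  idx[dr * dr + dc * dc <= rPx * rPx]
}

#' Acquire one resource for a settling bird
#'
#' Implements the iterative forage search: a seed pixel is drawn uniformly
#' at random among free pixels of the resource whose centres lie within
#' \code{searchDistM} of the roost centre, and the whole free patch
#' reachable from it is claimed (defence may extend beyond the search
#' distance; only the seed is distance-constrained). The search stops as
#' soon as the defended area of the resource reaches \code{areaReqHa}
#' after a complete patch claim -- whole patches are claimed, so the
#' requirement can be overshot -- and fails when it is unmet and no
#' eligible seed pixel remains.
#'
#' @param state a [WorldState] (mutated in place).
#' @param birdId owner ID.
#' @param roost linear index of the bird's roost pixel.
#' @param resource resource name ("rough" or "meadow").
#' @param areaReqHa area requirement (ha); 0 succeeds immediately.
#' @param searchDistM seed search distance from the roost (m).
#' @param wholePatch claim whole patches (TRUE) or stop mid-patch once the
#'   requirement is met (FALSE).
#' @return list with \code{success} (logical), \code{pixels} (claimed
#'   indices) and \code{seeds} (the seed pixels drawn, in order).
#' @export
acquireResource <- function(state, birdId, roost, resource, areaReqHa,
                            searchDistM, wholePatch = TRUE) {
  e <- state@env
  pxHa <- (e$pixelSize / 100)^2
  pixels <- integer(0)
  seeds <- integer(0)
  if (areaReqHa <= 0)
    return(list(success = TRUE, pixels = pixels, seeds = seeds))
  code <- .resCode(resource)
  elig <- .eligibleSeeds(e, roost, code, searchDistM)
  acquired <- 0
  repeat {
    elig <- elig[e$free[elig]]
    if (!length(elig))
      return(list(success = FALSE, pixels = pixels, seeds = seeds))
    seed <- .drawOne(elig)
    seeds <- c(seeds, seed)
    maxPx <- if (wholePatch) Inf else
      ceiling((areaReqHa - acquired) / pxHa - 1e-9)
    claimed <- claimPatch(state, seed, resource, birdId, maxPixels = maxPx)
    pixels <- c(pixels, claimed)
    acquired <- acquired + length(claimed) * pxHa
    if (acquired >= areaReqHa - 1e-9)
      return(list(success = TRUE, pixels = pixels, seeds = seeds))
  }
}

#' Attempt to settle one virtual buzzard
#'
#' Draws a roost uniformly among free, untried woodland pixels, then runs
#' the rough-ground search followed by the meadow search. On failure every
#' pixel the bird defended is released, except the drawn roost pixel,
#' which is permanently marked as tried (unsettleable) so the run is
#' guaranteed to terminate.
#'
#' @param state a [WorldState] (mutated in place).
#' @param params a [SimulationParams].
#' @param id bird ID to assign on success.
#' @return list with \code{bird} (a [Buzzard], or NULL on failure) and
#'   \code{attempt}, the record of random draws consumed: \code{roost},
#'   \code{rgrSeeds}, \code{meadSeeds}, \code{settled}.
#' @export
settleOne <- function(state, params, id = 1L) {
  e <- state@env
  e$woodCand <- e$woodCand[e$free[e$woodCand] & !e$tried[e$woodCand]]
  if (!length(e$woodCand))
    stop("settleOne: no free, untried woodland pixel remains")
  pxHa <- (e$pixelSize / 100)^2
  roost <- .drawOne(e$woodCand)
  nRoostPx <- max(1L, ceiling(params@roostAreaHa / pxHa - 1e-9))
  roostPx <- claimPatch(state, roost, "woodland", id, maxPixels = nRoostPx)
  rgr <- acquireResource(state, id, roost, "rough", params@rgrAreaHa,
                         params@rgrDistM, params@wholePatch)
  mead <- list(success = FALSE, pixels = integer(0), seeds = integer(0))
  if (rgr$success)
    mead <- acquireResource(state, id, roost, "meadow", params@meadAreaHa,
                            params@meadDistM, params@wholePatch)
  attempt <- list(roost = roost, rgrSeeds = rgr$seeds,
                  meadSeeds = mead$seeds,
                  settled = rgr$success && mead$success)
  if (!attempt$settled) {
    release <- c(setdiff(roostPx, roost), rgr$pixels, mead$pixels)
    e$free[release] <- TRUE
    e$owner[release] <- 0L
    e$free[roost] <- TRUE
    e$owner[roost] <- 0L
    e$tried[roost] <- TRUE
    return(list(bird = NULL, attempt = attempt))
  }
  allPx <- c(roostPx, rgr$pixels, mead$pixels)
  xy <- cbind(x = e$origin[1] +
                (((allPx - 1L) %/% e$nr + 1L) - 0.5) * e$pixelSize,
              y = e$origin[2] +
                (e$nr - ((allPx - 1L) %% e$nr + 1L) + 0.5) * e$pixelSize)
  bird <- new("Buzzard", id = as.integer(id), roost = roostPx,
              rgr = rgr$pixels, mead = mead$pixels,
              x = unname(xy[, "x"]), y = unname(xy[, "y"]))
  list(bird = bird, attempt = attempt)
}

#' Run one settlement simulation to saturation
#'
#' Virtual buzzards settle sequentially ([settleOne()]) until no free,
#' untried woodland pixel remains anywhere in the world (study core and
#' boundary strip alike), at which point maximum distribution and
#' abundance have emerged. With a fixed \code{seed} the run is fully
#' deterministic; the random draws consumed (roost, then forage seeds in
#' claim order) are recorded per attempt for step-by-step replay.
#'
#' @param map a [ResourceMap].
#' @param params a [SimulationParams].
#' @param seed integer RNG seed, or NULL to continue the current RNG
#'   stream (run then not reproducible).
#' @param mask optional [StudyMask]; settlement itself ignores it (the
#'   whole world is simulated) but its dimensions are checked.
#' @return A [SimulationResult].
#' @examples
#' res <- runSimulation(kitLandscape(3, seed = 5), seed = 1)
#' nBirds(res)
#' @export
runSimulation <- function(map, params = simulationParams(), seed = NULL,
                          mask = NULL) {
  if (!is.null(mask) && !identical(dim(mask@core), dim(map@grid)))
    stop("mask dimensions do not match the map")
  if (!is.null(seed)) set.seed(seed)
  state <- newWorldState(map, connectivity = params@connectivity)
  e <- state@env
  birds <- list()
  draws <- list()
  failed <- 0L
  repeat {
    e$woodCand <- e$woodCand[e$free[e$woodCand] & !e$tried[e$woodCand]]
    if (!length(e$woodCand)) break
    out <- settleOne(state, params, id = length(birds) + 1L)
    draws[[length(draws) + 1L]] <- out$attempt
    if (is.null(out$bird)) failed <- failed + 1L
    else birds[[length(birds) + 1L]] <- out$bird
  }
  new("SimulationResult", birds = birds, owner = e$owner, map = map,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      failedAttempts = failed, draws = draws)
}

#' Run replicate simulations and summarize abundance
#'
#' Runs \code{nRuns} independent simulations with seeds derived
#' reproducibly from \code{baseSeed} (\code{baseSeed + 0:(nRuns-1)}) and
#' summarizes abundance within the study core: mean, 95\% confidence
#' interval of the mean (t-based), and range.
#'
#' @param map a [ResourceMap].
#' @param mask a [StudyMask] (defaults to the whole map as core).
#' @param params a [SimulationParams].
#' @param nRuns number of replicate runs.
#' @param baseSeed integer base seed.
#' @param keepResults keep the individual [SimulationResult]s (memory!).
#' @return list with \code{abundance} (per-run vector), \code{mean},
#'   \code{ci} (95\% CI of the mean), \code{range}, \code{seeds} and,
#'   when \code{keepResults}, \code{results}.
#' @examples
#' rep <- runReplicates(kitLandscape(3, seed = 5), nRuns = 3, baseSeed = 1)
#' rep$mean
#' @export
runReplicates <- function(map, mask = NULL, params = simulationParams(),
                          nRuns = 100, baseSeed = 1,
                          keepResults = FALSE) {
  stopifnot(nRuns >= 1)
  if (is.null(mask)) mask <- makeStudyMask(map, stripWidth = 0)
  seeds <- as.integer(baseSeed) + seq_len(nRuns) - 1L
  abund <- integer(nRuns)
  results <- if (keepResults) vector("list", nRuns) else NULL
  for (i in seq_len(nRuns)) {
    res <- runSimulation(map, params, seed = seeds[i], mask = mask)
    abund[i] <- abundance(res, mask)
    if (keepResults) results[[i]] <- res
  }
  m <- mean(abund)
  ci <- if (nRuns > 1 && stats::sd(abund) > 0) {
    half <- stats::qt(0.975, nRuns - 1) * stats::sd(abund) / sqrt(nRuns)
    c(m - half, m + half)
  } else c(m, m)
  out <- list(abundance = abund, mean = m, ci = ci,
              range = range(abund), seeds = seeds)
  if (keepResults) out$results <- results
  out
}
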