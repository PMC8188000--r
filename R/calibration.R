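#' @include AllClasses.R engine.R rangeMetrics.R
NULL

#' Mean core-area profile of one or more runs
#'
#' Pools all settled birds (optionally per run first) and returns the mean
#' percentage-polygon core area at each level -- the 11-value profile the
#' calibration objective compares against a wild-bird reference.
#'
#' @param results a [SimulationResult] or list of them.
#' @param levels core levels (default the 11 levels 30-80\% by 5).
#' @param perRun average within each run first, then across runs, instead
#'   of pooling birds from all runs with equal weight.
#' @return Named numeric vector of mean core areas (ha), one per level;
#'   all-NA if no bird settled.
#' @export
meanCoreProfile <- function(results, levels = seq(30, 80, by = 5),
                            perRun = FALSE) {
  if (is(results, "SimulationResult")) results <- list(results)
  tabs <- lapply(results, rangeMetricsTable, levels = levels)
  prof <- if (perRun) {
    mats <- lapply(tabs, function(tb) {
      if (!nrow(tb)) return(NULL)
      tapply(tb$areaHa, tb$level, mean)
    })
    mats <- Filter(Negate(is.null), mats)
    if (!length(mats)) rep(NA_real_, length(levels))
    else colMeans(do.call(rbind, mats))
  } else {
    tb <- do.call(rbind, tabs)
    if (is.null(tb) || !nrow(tb)) rep(NA_real_, length(levels))
    else as.vector(tapply(tb$areaHa, tb$level, mean))
  }
  stats::setNames(as.numeric(prof), levels)
}

#' Deterministic run seeds for a calibration combo
#'
#' Seeds are a function of the candidate distances themselves (not of the
#' grid position), so the grid search is invariant to evaluation order and
#' any profile generated at a parameter pair with these seeds is matched
#' exactly when the grid search evaluates that pair.
#'
#' @param rgrDistM,meadDistM candidate distances (m).
#' @param runsPerCombo number of replicate runs.
#' @param baseSeed integer base seed.
#' @return Integer vector of run seeds.
#' @export
calibrationRunSeeds <- function(rgrDistM, meadDistM, runsPerCombo = 6,
                                baseSeed = 1) {
  as.integer(round(baseSeed + 100 * rgrDistM + meadDistM +
                     seq_len(runsPerCombo)))
}

#' Calibrate forage search distances against a reference core profile
#'
#' Pattern-oriented grid search over the two forage search distances. For
#' each (rough-ground distance, meadow distance) pair, \code{runsPerCombo}
#' replicate simulations are run with combo-specific deterministic seeds,
#' the mean core-area profile over all settled birds is computed, and the
#' objective is the sum over the 11 core levels of the absolute difference
#' from the reference profile. The returned best pair minimizes the
#' objective (ties broken towards lexicographically smaller distances).
#'
#' @param map a [ResourceMap].
#' @param reference numeric vector of reference mean core areas (ha), one
#'   per level in \code{levels}.
#' @param baseParams a [SimulationParams]; its area requirements are kept
#'   fixed (they come from RADA, not calibration).
#' @param rgrDistGrid,meadDistGrid candidate distances (m); defaults are
#'   the published calibration intervals 300-500 and 1150-1350 in 50 m
#'   steps.
#' @param runsPerCombo replicate runs per pair (6 suffices for reasonably
#'   stable results).
#' @param levels core levels of the reference profile.
#' @param baseSeed integer; run seeds are derived from the candidate
#'   values as \code{baseSeed + 100 * rgrDist + meadDist + run} (see
#'   [calibrationRunSeeds()]), so the search is order-independent and a
#'   reference profile generated at some pair under the same scheme is
#'   reproduced exactly by that combo (objective 0) -- the
#'   self-consistency construction used for parameter-recovery checks.
#' @param perRun passed to [meanCoreProfile()].
#' @return list with \code{best} (named vector rgrDistM/meadDistM),
#'   \code{objective} (its L1 objective), and \code{table} (one row per
#'   combo: distances, objective, birds pooled).
#' @export
calibrateSearchDistances <- function(map, reference,
                                     baseParams = simulationParams(),
                                     rgrDistGrid = seq(300, 500, by = 50),
                                     meadDistGrid = seq(1150, 1350, by = 50),
                                     runsPerCombo = 6,
                                     levels = seq(30, 80, by = 5),
                                     baseSeed = 1, perRun = FALSE) {
  stopifnot(length(reference) == length(levels), runsPerCombo >= 1,
            length(rgrDistGrid) >= 1, length(meadDistGrid) >= 1)
  combos <- expand.grid(rgrDistM = rgrDistGrid, meadDistM = meadDistGrid)
  objective <- numeric(nrow(combos))
  nBirdsPooled <- integer(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    p <- baseParams
    p@rgrDistM <- combos$rgrDistM[k]
    p@meadDistM <- combos$meadDistM[k]
    seeds <- calibrationRunSeeds(combos$rgrDistM[k], combos$meadDistM[k],
                                 runsPerCombo, baseSeed)
    runs <- lapply(seeds, function(s) runSimulation(map, p, seed = s))
    nBirdsPooled[k] <- sum(vapply(runs, nBirds, integer(1)))
    prof <- meanCoreProfile(runs, levels = levels, perRun = perRun)
    objective[k] <- if (anyNA(prof)) Inf
                    else sum(abs(prof - reference))
  }
  tab <- cbind(combos, objective = objective, nBirds = nBirdsPooled)
  if (all(!is.finite(objective)))
    warning("no combo settled any bird; objectives are all infinite")
  ord <- order(objective, combos$rgrDistM, combos$meadDistM)
  best <- tab[ord[1L], ]
  list(best = c(rgrDistM = best$rgrDistM, meadDistM = best$meadDistM),
       objective = best$objective, table = tab)
}
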