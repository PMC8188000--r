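#' @include AllClasses.R engine.R rangeMetrics.R
NULL

#' Morris elementary-effects screening (randomized OAT)
#'
#' Screens parameter influence without assumptions about the model. Each
#' trajectory starts from a random point on a regular grid of
#' \code{levels} values per parameter and perturbs the parameters one at a
#' time in random order by the standard Morris step
#' \eqn{\Delta = p/(2(p-1))} on the unit-scaled range (step direction
#' random where both directions stay in range). The elementary effect is
#' the output change divided by the signed unit-scale step, i.e. the
#' effect of traversing the full parameter range. Per parameter and output
#' the mean (\code{mu}), mean absolute value (\code{muStar}) and standard
#' deviation (\code{sigma}) of effects over trajectories are returned.
#'
#' @param evaluator function taking a named numeric parameter vector and
#'   returning a named numeric vector of outputs. Evaluation failures are
#'   recorded as missing effects with a warning.
#' @param lower,upper named numeric vectors: parameter ranges.
#' @param levels number of grid levels per parameter (>= 2).
#' @param trajectories number of randomized trajectories.
#' @param seed optional RNG seed.
#' @return list with \code{summary} (data.frame: parameter, output, mu,
#'   muStar, sigma, n) and \code{effects} (raw long table of elementary
#'   effects per trajectory).
#' @examples
#' lin <- function(p) c(y = 2 * p[["a"]] + p[["b"]])
#' m <- morrisScreening(lin, c(a = 0, b = 0), c(a = 1, b = 1),
#'                      trajectories = 4, seed = 1)
#' m$summary
#' @export
morrisScreening <- function(evaluator, lower, upper, levels = 4,
                            trajectories = 10, seed = NULL) {
  stopifnot(length(lower) == length(upper), levels >= 2, trajectories >= 1,
            all(upper > lower))
  if (is.null(names(lower))) stop("parameter ranges must be named")
  if (!is.null(seed)) set.seed(seed)
  pars <- names(lower)
  k <- length(pars)
  gridVals <- seq(0, 1, length.out = levels)
  delta <- levels / (2 * (levels - 1))
  toNatural <- function(u) lower + u * (upper - lower)
  evalSafe <- function(u) {
    tryCatch(evaluator(toNatural(u)),
             error = function(e) {
               warning("evaluator failed: ", conditionMessage(e))
               NULL
             })
  }
  effects <- list()
  for (tr in seq_len(trajectories)) {
    u <- stats::setNames(sample(gridVals, k, replace = TRUE), pars)
    yPrev <- evalSafe(u)
    for (p in sample(pars)) {
      canUp <- u[[p]] + delta <= 1 + 1e-12
      canDown <- u[[p]] - delta >= -1e-12
      dir <- if (canUp && canDown) sample(c(delta, -delta), 1L)
             else if (canUp) delta else -delta
      u[[p]] <- min(1, max(0, u[[p]] + dir))
      yNew <- evalSafe(u)
      ee <- if (is.null(yPrev) || is.null(yNew)) NULL
            else (yNew - yPrev) / dir
      if (!is.null(ee))
        effects[[length(effects) + 1L]] <-
          data.frame(trajectory = tr, parameter = p,
                     output = names(ee), ee = as.numeric(ee))
      else
        effects[[length(effects) + 1L]] <-
          data.frame(trajectory = tr, parameter = p,
                     output = NA_character_, ee = NA_real_)
      yPrev <- yNew
    }
  }
  eff <- do.call(rbind, effects)
  rownames(eff) <- NULL
  ok <- !is.na(eff$ee)
  agg <- if (any(ok)) {
    sp <- split(eff$ee[ok], list(eff$parameter[ok], eff$output[ok]),
                drop = TRUE)
    keys <- do.call(rbind, strsplit(names(sp), "\\.(?=[^.]+$)", perl = TRUE))
    data.frame(parameter = keys[, 1L], output = keys[, 2L],
               mu = vapply(sp, mean, numeric(1)),
               muStar = vapply(sp, function(x) mean(abs(x)), numeric(1)),
               sigma = vapply(sp, function(x)
                 if (length(x) > 1L) stats::sd(x) else 0, numeric(1)),
               n = lengths(sp), row.names = NULL)
  } else data.frame(parameter = character(0), output = character(0),
                    mu = numeric(0), muStar = numeric(0),
                    sigma = numeric(0), n = integer(0))
  list(summary = agg, effects = eff)
}

#' Morris ranges for the buzzard settlement parameters
#'
#' The published screening varies the four behavioural parameters around
#' their reference values by fixed relative amounts: rough-ground search
#' distance by 70\%, and rough-ground area, meadow area and meadow search
#' distance by 67\%.
#'
#' @param params a [SimulationParams] holding the reference values.
#' @return list with named vectors \code{lower} and \code{upper} for
#'   parameters \code{rgrAreaHa}, \code{rgrDistM}, \code{meadAreaHa},
#'   \code{meadDistM}.
#' @export
buzzardMorrisRanges <- function(params = simulationParams()) {
  base <- c(rgrAreaHa = params@rgrAreaHa, rgrDistM = params@rgrDistM,
            meadAreaHa = params@meadAreaHa, meadDistM = params@meadDistM)
  rel <- c(rgrAreaHa = 0.67, rgrDistM = 0.70, meadAreaHa = 0.67,
           meadDistM = 0.67)
  list(lower = base * (1 - rel), upper = base * (1 + rel))
}

#' Build a model evaluator for sensitivity analysis
#'
#' Wraps the settlement model as a function from the four behavioural
#' parameters to the six screened outputs: abundance, mean 80\% core
#' pairwise overlap percentage, mean 40\% and 80\% core areas and
#' perimeters. All evaluations use the same seed (common random numbers),
#' so output differences reflect parameter changes only.
#'
#' @param map a [ResourceMap].
#' @param mask a [StudyMask] (defaults to whole-map core).
#' @param baseParams a [SimulationParams]; parameters not supplied by the
#'   evaluator's argument keep these values.
#' @param seed seed used for every evaluation.
#' @return function(namedParams) -> named numeric(6); parameters
#'   recognised are \code{rgrAreaHa}, \code{rgrDistM}, \code{meadAreaHa},
#'   \code{meadDistM}.
#' @export
abmEvaluator <- function(map, mask = NULL,
                         baseParams = simulationParams(), seed = 1) {
  if (is.null(mask)) mask <- makeStudyMask(map, stripWidth = 0)
  function(x) {
    p <- baseParams
    if ("rgrAreaHa" %in% names(x)) p@rgrAreaHa <- x[["rgrAreaHa"]]
    if ("rgrDistM" %in% names(x)) p@rgrDistM <- x[["rgrDistM"]]
    if ("meadAreaHa" %in% names(x)) p@meadAreaHa <- x[["meadAreaHa"]]
    if ("meadDistM" %in% names(x)) p@meadDistM <- x[["meadDistM"]]
    res <- runSimulation(map, p, seed = seed, mask = mask)
    tb <- rangeMetricsTable(res, levels = c(40, 80))
    cores80 <- lapply(res@birds, function(b)
      percentagePolygon(cbind(b@x, b@y), 80, id = b@id))
    ov <- if (length(cores80) >= 2L)
      suppressMessages(pairwiseOverlaps(cores80)) else NULL
    c(abundance = abundance(res, mask),
      overlap80 = if (!is.null(ov) && nrow(ov)) mean(ov$overlapPct) else 0,
      area40 = if (nrow(tb)) mean(tb$areaHa[tb$level == 40]) else 0,
      area80 = if (nrow(tb)) mean(tb$areaHa[tb$level == 80]) else 0,
      perim40 = if (nrow(tb)) mean(tb$perimeterM[tb$level == 40]) else 0,
      perim80 = if (nrow(tb)) mean(tb$perimeterM[tb$level == 80]) else 0)
  }
}

#' Full factorial sensitivity over meadow area and search distance
#'
#' Global sensitivity design over the two parameters that dominate
#' abundance: meadow area requirement (9.5-17.5 ha in 1 ha steps) and
#' meadow forage search distance (800-1600 m in 100 m steps), 81 cells.
#' Each cell runs \code{runsPerCell} replicates with deterministic
#' cell-specific seeds, so the table is invariant to evaluation order.
#'
#' @param map a [ResourceMap].
#' @param mask a [StudyMask] (defaults to whole-map core).
#' @param baseParams a [SimulationParams].
#' @param meadAreaGrid,meadDistGrid factor levels.
#' @param runsPerCell replicates per cell.
#' @param baseSeed integer; cell seeds are
#'   \code{baseSeed + 1000 * cellIndex + run}.
#' @return list with \code{table} (meadAreaHa, meadDistM, meanAbundance)
#'   and \code{marginals} (mean abundance by level of each factor).
#' @export
fullFactorial <- function(map, mask = NULL,
                          baseParams = simulationParams(),
                          meadAreaGrid = seq(9.5, 17.5, by = 1),
                          meadDistGrid = seq(800, 1600, by = 100),
                          runsPerCell = 1, baseSeed = 1) {
  if (is.null(mask)) mask <- makeStudyMask(map, stripWidth = 0)
  cells <- expand.grid(meadAreaHa = meadAreaGrid, meadDistM = meadDistGrid)
  meanAb <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    p <- baseParams
    p@meadAreaHa <- cells$meadAreaHa[k]
    p@meadDistM <- cells$meadDistM[k]
    seeds <- baseSeed + 1000L * k + seq_len(runsPerCell)
    meanAb[k] <- mean(vapply(seeds, function(s)
      abundance(runSimulation(map, p, seed = s, mask = mask), mask),
      numeric(1)))
  }
  tab <- cbind(cells, meanAbundance = meanAb)
  list(table = tab,
       marginals = list(
         meadAreaHa = tapply(tab$meanAbundance, tab$meadAreaHa, mean),
         meadDistM = tapply(tab$meanAbundance, tab$meadDistM, mean)))
}
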