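#' @include AllClasses.R resourceMap.R
NULL

#' Meadow plots eligible for conversion to woodland
#'
#' Returns the meadow patches whose area meets the economically viable
#' plot size for afforestation (threshold inclusive, default 20 ha).
#'
#' @param map a [ResourceMap].
#' @param minPlotAreaHa minimum plot area in hectares.
#' @param connectivity patch adjacency, 4 or 8.
#' @return A list of patches as returned by [labelPatches()].
#' @examples
#' m <- syntheticLandscape(120, 120, seed = 2)
#' length(eligiblePlots(m, 20))
#' @export
eligiblePlots <- function(map, minPlotAreaHa = 20, connectivity = 8) {
  plots <- labelPatches(map, "meadow", connectivity = connectivity)
  Filter(function(p) p$areaHa >= minPlotAreaHa, plots)
}

#' Convert economically viable meadow plots into woodland
#'
#' Implements the landscape-change scenarios: whole meadow plots of at
#' least \code{minPlotAreaHa} are drawn uniformly at random without
#' replacement and converted to woodland until the cumulative converted
#' area first reaches \code{fraction} of the total eligible area. Plots are
#' indivisible economic units, so the target can be overshot by at most the
#' area of the largest eligible plot. All other pixels are untouched;
#' sub-threshold meadow is never converted.
#'
#' @param map a [ResourceMap].
#' @param fraction target proportion of eligible meadow area to convert
#'   (0-1); the scenarios of interest are 0.3, 0.6 and 0.9.
#' @param minPlotAreaHa economically viable plot threshold (ha), inclusive.
#' @param connectivity patch adjacency, 4 or 8.
#' @param seed optional RNG seed; fixed seed fixes the chosen plots.
#' @return The converted [ResourceMap], with attributes
#'   \code{"convertedHa"} (area converted), \code{"eligibleHa"} (total
#'   eligible area) and \code{"plotsConverted"} (number of plots).
#' @examples
#' m <- syntheticLandscape(120, 120, seed = 2)
#' s1 <- convertMeadow(m, 0.3, seed = 9)
#' attr(s1, "convertedHa") / attr(s1, "eligibleHa")
#' @export
convertMeadow <- function(map, fraction, minPlotAreaHa = 20,
                          connectivity = 8, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (minPlotAreaHa <= 0) stop("minPlotAreaHa must be positive")
  if (!is.null(seed)) set.seed(seed)
  plots <- eligiblePlots(map, minPlotAreaHa, connectivity)
  eligibleHa <- sum(vapply(plots, `[[`, numeric(1), "areaHa"))
  out <- map
  converted <- 0
  nConv <- 0L
  if (fraction > 0 && length(plots) == 0L) {
    warning("no eligible meadow plots; map returned unchanged")
  } else if (fraction > 0) {
    target <- fraction * eligibleHa
    order <- sample.int(length(plots))
    g <- out@grid
    for (i in order) {
      if (converted >= target) break
      g[plots[[i]]$pixels] <- .RES_CODES[["woodland"]]
      converted <- converted + plots[[i]]$areaHa
      nConv <- nConv + 1L
    }
    out@grid <- g
  }
  attr(out, "convertedHa") <- converted
  attr(out, "eligibleHa") <- eligibleHa
  attr(out, "plotsConverted") <- nConv
  out
}
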