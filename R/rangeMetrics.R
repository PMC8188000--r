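#' @include AllClasses.R geometry.R
NULL

#' Percentage convex-polygon home-range core
#'
#' The classic polygon home-range estimator: retain the
#' \code{ceiling(level/100 * n)} locations nearest the arithmetic-mean
#' centre of *all* locations (one ranking; the centre is not recomputed
#' between peels) and return the convex hull of the retained points.
#' Degenerate retained sets (a single point, or collinear points) yield a
#' zero-area geometry whose perimeter is twice the spanned segment length.
#'
#' @param points numeric matrix (n x 2) of planar locations in metres.
#' @param level percentage of locations to retain, in (0, 100].
#' @param id bird ID to record in the result.
#' @return A [RangeCore].
#' @examples
#' sq <- cbind(c(0, 0, 100, 100), c(0, 100, 0, 100))
#' coreArea(percentagePolygon(sq, 100))   # 1 ha
#' @export
percentagePolygon <- function(points, level, id = 0L) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (level <= 0 || level > 100) stop("level must be in (0, 100]")
  centre <- colMeans(points)
  d2 <- (points[, 1] - centre[1])^2 + (points[, 2] - centre[2])^2
  keep <- order(d2)[seq_len(ceiling(level / 100 * nrow(points)))]
  hull <- .convexHull(points[keep, , drop = FALSE])
  new("RangeCore", id = as.integer(id), level = as.numeric(level),
      polygon = unname(hull), areaHa = .polyAreaM2(hull) / 1e4,
      perimeterM = .polyPerimM(hull))
}

#' Core profile of a settled bird
#'
#' Computes percentage-polygon cores over a bird's territory pixel centres
#' (roost + rough-ground + meadow) at the standard utilization levels 30\%
#' to 80\% in 5\% steps (11 cores; levels above 85\% are associated with
#' non-foraging excursions and are excluded from defaults).
#'
#' @param bird a [Buzzard].
#' @param levels numeric vector of core levels.
#' @return list of [RangeCore], one per level.
#' @examples
#' res <- runSimulation(kitLandscape(1, seed = 2), seed = 1)
#' prof <- coreProfile(birds(res)[[1]])
#' vapply(prof, coreArea, numeric(1))
#' @export
coreProfile <- function(bird, levels = seq(30, 80, by = 5)) {
  pts <- cbind(bird@x, bird@y)
  lapply(levels, function(l) percentagePolygon(pts, l, id = bird@id))
}

#' Pairwise overlaps between home-range cores
#'
#' For every ordered pair of cores at the same level whose polygons
#' intersect with positive area, reports the intersection as a percentage
#' of the first core's area (a proxy for territorial spacing). Ordered
#' pairs (A,B) and (B,A) share the intersection area but differ in
#' denominator. Zero-area (degenerate) cores are skipped. With
#' \code{symmetric = TRUE} one record per unordered pair is returned with
#' intersection/union percentages instead.
#'
#' @param cores list of [RangeCore] objects at one level.
#' @param symmetric report intersection-over-union per unordered pair.
#' @return data.frame with columns \code{birdA}, \code{birdB},
#'   \code{level}, \code{overlapPct}; zero rows if no pair intersects.
#' @export
pairwiseOverlaps <- function(cores, symmetric = FALSE) {
  lev <- vapply(cores, coreLevel, numeric(1))
  if (length(unique(lev)) > 1L) stop("all cores must be at the same level")
  ok <- vapply(cores, function(co) coreArea(co) > 0, logical(1))
  if (any(!ok))
    message(sum(!ok), " zero-area core(s) skipped in overlap computation")
  cores <- cores[ok]
  recs <- list()
  n <- length(cores)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- cores[[i]]; b <- cores[[j]]
    inter <- .polyAreaM2(.clipConvex(a@polygon, b@polygon)) / 1e4
    if (inter <= 0) next
    if (symmetric) {
      uni <- coreArea(a) + coreArea(b) - inter
      recs[[length(recs) + 1L]] <-
        data.frame(birdA = a@id, birdB = b@id, level = a@level,
                   overlapPct = 100 * inter / uni)
    } else {
      recs[[length(recs) + 1L]] <-
        data.frame(birdA = c(a@id, b@id), birdB = c(b@id, a@id),
                   level = a@level,
                   overlapPct = 100 * inter / c(coreArea(a), coreArea(b)))
    }
  }
  if (!length(recs))
    return(data.frame(birdA = integer(0), birdB = integer(0),
                      level = numeric(0), overlapPct = numeric(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Abundance within the study core
#'
#' Counts settled birds whose (drawn) roost pixel lies inside the study
#' core. Birds roosting in the boundary strip still block pixels but are
#' excluded, on the assumption that their incursions into the core balance
#' the excursions of core birds.
#'
#' @param result a [SimulationResult].
#' @param mask a [StudyMask] on the same grid.
#' @return Integer count.
#' @export
abundance <- function(result, mask) {
  if (!identical(dim(mask@core), dim(result@owner)))
    stop("mask and result are not on the same grid")
  sum(vapply(result@birds, function(b) mask@core[b@roost[1L]], logical(1)))
}

#' Occupancy raster of a simulation result
#'
#' Returns an integer grid labelling every defended pixel with its owner's
#' ID; roost pixels are flagged distinctly as the negative of the owner ID.
#' Unowned pixels are 0.
#'
#' @param result a [SimulationResult].
#' @return Integer matrix with the map's dimensions.
#' @export
occupancyRaster <- function(result) {
  occ <- result@owner
  for (b in result@birds) occ[b@roost] <- -b@id
  occ
}

#' Pooled home-range metrics table
#'
#' Core area and perimeter for every settled bird at the requested levels,
#' as a long table suitable for calibration and comparison with wild-bird
#' summaries.
#'
#' @param result a [SimulationResult].
#' @param levels core levels (default 30-80\% by 5).
#' @return data.frame with columns \code{bird}, \code{level},
#'   \code{areaHa}, \code{perimeterM}.
#' @export
rangeMetricsTable <- function(result, levels = seq(30, 80, by = 5)) {
  rows <- lapply(result@birds, function(b) {
    prof <- coreProfile(b, levels)
    data.frame(bird = b@id, level = levels,
               areaHa = vapply(prof, coreArea, numeric(1)),
               perimeterM = vapply(prof, corePerimeter, numeric(1)))
  })
  if (!length(rows))
    return(data.frame(bird = integer(0), level = numeric(0),
                      areaHa = numeric(0), perimeterM = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
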