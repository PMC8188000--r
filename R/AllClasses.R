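#' @import methods
NULL

## Integer codes used in the resource grid. Kept stable because rasters are
## written to disk with these values.
.RES_CODES <- c(other = 0L, woodland = 1L, rough = 2L, meadow = 3L, water = 4L)

#' Resource codes used in buzzard resource maps
#'
#' The categorical raster underlying the model holds one of five resource
#' classes per pixel: \code{woodland} (roosting/nesting), \code{rough}
#' (rough-ground: sparse grass, open and dense shrub hunting habitat),
#' \code{meadow} (seasonally-long-grass hunting habitat), \code{water}
#' (sea, lakes and NODATA; never claimable) and \code{other} (all remaining
#' cover, crossed but not defended).
#'
#' @return Named integer vector mapping resource names to grid codes.
#' @examples
#' resourceCodes()
#' @export
resourceCodes <- function() .RES_CODES

.resCode <- function(resource) {
  resource <- match.arg(resource, names(.RES_CODES))
  .RES_CODES[[resource]]
}

#' ResourceMap: a categorical buzzard resource raster
#'
#' An S4 container for a square-pixel categorical raster of buzzard key
#' resources, with georeferencing. The grid is an integer matrix using the
#' codes of [resourceCodes()]; row 1 is the northern edge, column 1 the
#' western edge, matching on-disk ESRI ASCII grid row order. Geographic
#' positions refer to pixel centres; the origin is the lower-left (south-
#' west) corner of the grid in map units (metres).
#'
#' @slot grid integer matrix of resource codes.
#' @slot pixelSize numeric(1), pixel edge length in metres (square pixels).
#' @slot origin numeric(2), easting/northing of the lower-left corner (m).
#'
#' @seealso [resourceMap()], [translateLandcover()], [syntheticLandscape()]
#' @name ResourceMap-class
#' @aliases ResourceMap
#' @exportClass ResourceMap
setClass("ResourceMap",
  representation(grid = "matrix", pixelSize = "numeric", origin = "numeric"),
  prototype(grid = matrix(integer(0), 0, 0), pixelSize = 25,
            origin = c(0, 0)))

setValidity("ResourceMap", function(object) {
  g <- object@grid
  if (!is.integer(g)) return("grid must be an integer matrix")
  if (nrow(g) == 0L || ncol(g) == 0L) return("grid must be non-empty")
  if (anyNA(g)) return("grid must not contain NA (use the 'water' code)")
  if (!all(g %in% .RES_CODES)) return("grid contains unknown resource codes")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@origin) != 2L || anyNA(object@origin))
    return("origin must be numeric(2)")
  TRUE
})

#' StudyMask: study-area core plus boundary strip
#'
#' Marks which pixels of a [ResourceMap] belong to the study-area core.
#' Birds roosting in the surrounding boundary strip are simulated (they can
#' defend pixels inside the core) but are excluded from abundance and
#' distribution summaries, balancing incursions across the core edge.
#'
#' @slot core logical matrix, same dimensions as the map grid.
#' @slot stripWidth numeric(1), width in metres of the boundary strip.
#'
#' @seealso [makeStudyMask()], [abundance()]
#' @name StudyMask-class
#' @aliases StudyMask
#' @exportClass StudyMask
setClass("StudyMask",
  representation(core = "matrix", stripWidth = "numeric"),
  prototype(core = matrix(logical(0), 0, 0), stripWidth = 0))

setValidity("StudyMask", function(object) {
  if (!is.logical(object@core)) return("core must be a logical matrix")
  if (anyNA(object@core)) return("core must not contain NA")
  if (length(object@stripWidth) != 1L || object@stripWidth < 0)
    return("stripWidth must be a single non-negative number")
  TRUE
})

#' SimulationParams: RADA area requirements and forage search distances
#'
#' Holds the five behavioural parameters of the settlement model. Area
#' requirements come from Resource-Area-Dependence Analysis of radio-tracked
#' wild buzzards; search distances constrain where forage *seed* pixels may
#' be chosen (defence of a claimed patch may extend beyond them).
#'
#' @slot roostAreaHa woodland roost area requirement (ha); the default
#'   0.06 ha is one 25 m pixel.
#' @slot rgrAreaHa rough-ground area requirement (ha), default 0.56.
#' @slot rgrDistM rough-ground forage search distance from roost (m),
#'   default 500.
#' @slot meadAreaHa meadow area requirement (ha), default 13.5.
#' @slot meadDistM meadow forage search distance from roost (m),
#'   default 1200.
#' @slot connectivity pixel adjacency for patches and flood fill, 4 or 8
#'   (default 8: diagonal field corners form continuous cover at 25 m grain).
#' @slot wholePatch logical; if TRUE (default) a claimed patch is always
#'   incorporated in full, so requirements may be overshot; if FALSE the
#'   claim stops once the requirement is met mid-patch.
#'
#' @seealso [simulationParams()], [runSimulation()]
#' @name SimulationParams-class
#' @aliases SimulationParams
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(roostAreaHa = "numeric", rgrAreaHa = "numeric",
                 rgrDistM = "numeric", meadAreaHa = "numeric",
                 meadDistM = "numeric", connectivity = "integer",
                 wholePatch = "logical"),
  prototype(roostAreaHa = 0.06, rgrAreaHa = 0.56, rgrDistM = 500,
            meadAreaHa = 13.5, meadDistM = 1200, connectivity = 8L,
            wholePatch = TRUE))

setValidity("SimulationParams", function(object) {
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@roostAreaHa) || object@roostAreaHa <= 0)
    return("roostAreaHa must be a single positive number")
  if (!num1(object@rgrAreaHa) || object@rgrAreaHa < 0)
    return("rgrAreaHa must be a single non-negative number")
  if (!num1(object@meadAreaHa) || object@meadAreaHa < 0)
    return("meadAreaHa must be a single non-negative number")
  if (!num1(object@rgrDistM) || object@rgrDistM <= 0)
    return("rgrDistM must be a single positive number")
  if (!num1(object@meadDistM) || object@meadDistM <= 0)
    return("meadDistM must be a single positive number")
  if (!object@connectivity %in% c(4L, 8L))
    return("connectivity must be 4 or 8")
  if (length(object@wholePatch) != 1L || is.na(object@wholePatch))
    return("wholePatch must be TRUE or FALSE")
  TRUE
})

#' Buzzard: one settled virtual bird
#'
#' A settled agent holds one defended woodland roost pixel (possibly more
#' when the roost area requirement exceeds one pixel), the defended
#' rough-ground and meadow pixel sets, and the easting/northing lists of all
#' territory pixels. Pixels are stored as 1-based linear indices into the
#' map grid (column-major).
#'
#' @slot id integer bird ID (settlement order).
#' @slot roost integer vector of defended woodland pixel indices.
#' @slot rgr integer vector of defended rough-ground pixel indices.
#' @slot mead integer vector of defended meadow pixel indices.
#' @slot x,y numeric vectors: eastings/northings (m) of every territory
#'   pixel centre, ordered roost, rough-ground, meadow.
#'
#' @name Buzzard-class
#' @aliases Buzzard
#' @exportClass Buzzard
setClass("Buzzard",
  representation(id = "integer", roost = "integer", rgr = "integer",
                 mead = "integer", x = "numeric", y = "numeric"))

setValidity("Buzzard", function(object) {
  n <- length(object@roost) + length(object@rgr) + length(object@mead)
  if (length(object@x) != n || length(object@y) != n)
    return("x/y must list coordinates of every territory pixel")
  if (length(object@roost) < 1L) return("a settled bird must hold a roost")
  TRUE
})

#' SimulationResult: outcome of one settlement run
#'
#' @slot birds list of settled [Buzzard] objects.
#' @slot owner integer matrix: owning bird ID per pixel (0 = unowned).
#' @slot map the [ResourceMap] the run used.
#' @slot seed integer(1) RNG seed of the run (NA when unseeded).
#' @slot failedAttempts integer(1): settlement attempts that ended in
#'   emigration (their roost pixel is left marked as tried).
#' @slot draws list: per-attempt record of the random draws consumed
#'   (roost pixel, then forage seed pixels in claim order), enabling exact
#'   step-by-step replay.
#'
#' @seealso [runSimulation()], [abundance()], [occupancyRaster()]
#' @name SimulationResult-class
#' @aliases SimulationResult
#' @exportClass SimulationResult
setClass("SimulationResult",
  representation(birds = "list", owner = "matrix", map = "ResourceMap",
                 seed = "integer", failedAttempts = "integer",
                 draws = "list"))

setValidity("SimulationResult", function(object) {
  if (!is.integer(object@owner)) return("owner must be an integer matrix")
  if (!identical(dim(object@owner), dim(object@map@grid)))
    return("owner grid must match the map grid")
  ids <- vapply(object@birds, function(b) b@id, integer(1))
  if (anyDuplicated(ids)) return("bird IDs must be unique")
  TRUE
})

#' RangeCore: a percentage convex-polygon home-range core
#'
#' The x% core retains the x% of a bird's territory locations nearest the
#' arithmetic-mean centre of all locations (single ranking, centre not
#' recomputed between peels) and takes their convex hull. Degenerate point
#' sets (one point, or collinear points) yield a zero-area geometry with a
#' defined perimeter.
#'
#' @slot id integer bird ID.
#' @slot level percentage of locations retained (0-100].
#' @slot polygon numeric matrix (n x 2) of hull vertex coordinates (m),
#'   counter-clockwise, not closed.
#' @slot areaHa polygon area in hectares.
#' @slot perimeterM polygon perimeter in metres.
#'
#' @seealso [percentagePolygon()], [coreProfile()], [pairwiseOverlaps()]
#' @name RangeCore-class
#' @aliases RangeCore
#' @exportClass RangeCore
setClass("RangeCore",
  representation(id = "integer", level = "numeric", polygon = "matrix",
                 areaHa = "numeric", perimeterM = "numeric"))

setValidity("RangeCore", function(object) {
  if (length(object@level) != 1L || object@level <= 0 || object@level > 100)
    return("level must be in (0, 100]")
  if (ncol(object@polygon) != 2L) return("polygon must be an n x 2 matrix")
  if (object@areaHa < 0 || object@perimeterM < 0)
    return("area and perimeter must be non-negative")
  TRUE
})

#' WorldState: mutable per-run settlement state
#'
#' Reference-semantics holder of the mutable grids the settlement engine
#' works on: per-pixel resource code, availability (free vs defended),
#' tried-roost flags and owner IDs. Created by [newWorldState()]; mutated in
#' place by [claimPatch()], [acquireResource()] and [settleOne()].
#'
#' @slot env environment holding matrices \code{res}, \code{free},
#'   \code{tried}, \code{owner} and the map geometry.
#'
#' @name WorldState-class
#' @aliases WorldState
#' @exportClass WorldState
setClass("WorldState", representation(env = "environment"))
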