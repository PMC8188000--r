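#' @include AllClasses.R
NULL

#' Accessors for buteoABM classes
#'
#' Small accessor generics used throughout the package in place of direct
#' slot access.
#'
#' @param x an object of the documented class.
#' @return `resourceGrid`: the integer code matrix; `pixelSize`: pixel edge
#'   (m); `pixelAreaHa`: pixel area in hectares, `(pixelSize/100)^2`;
#'   `mapOrigin`: numeric(2) lower-left corner; `mapExtent`: named
#'   numeric(2) E-W/N-S extent in metres; `birds`: list of [Buzzard];
#'   `ownerGrid`: integer owner matrix; `nBirds`: number of settled birds;
#'   `runSeed`: seed of the run; `territoryPixels`: integer linear pixel
#'   indices of a bird's territory; `coreArea`/`corePerimeter`/`coreLevel`/
#'   `corePolygon`: components of a [RangeCore].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("resourceGrid", function(x) standardGeneric("resourceGrid"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("pixelAreaHa", function(x) standardGeneric("pixelAreaHa"))
#' @rdname accessors
#' @export
setGeneric("mapOrigin", function(x) standardGeneric("mapOrigin"))
#' @rdname accessors
#' @export
setGeneric("mapExtent", function(x) standardGeneric("mapExtent"))
#' @rdname accessors
#' @export
setGeneric("birds", function(x) standardGeneric("birds"))
#' @rdname accessors
#' @export
setGeneric("ownerGrid", function(x) standardGeneric("ownerGrid"))
#' @rdname accessors
#' @export
setGeneric("nBirds", function(x) standardGeneric("nBirds"))
#' @rdname accessors
#' @export
setGeneric("runSeed", function(x) standardGeneric("runSeed"))
#' @rdname accessors
#' @export
setGeneric("territoryPixels", function(x) standardGeneric("territoryPixels"))
#' @rdname accessors
#' @export
setGeneric("coreArea", function(x) standardGeneric("coreArea"))
#' @rdname accessors
#' @export
setGeneric("corePerimeter", function(x) standardGeneric("corePerimeter"))
#' @rdname accessors
#' @export
setGeneric("coreLevel", function(x) standardGeneric("coreLevel"))
#' @rdname accessors
#' @export
setGeneric("corePolygon", function(x) standardGeneric("corePolygon"))

#' @rdname accessors
setMethod("resourceGrid", "ResourceMap", function(x) x@grid)
#' @rdname accessors
setMethod("pixelSize", "ResourceMap", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelAreaHa", "ResourceMap", function(x) (x@pixelSize / 100)^2)
#' @rdname accessors
setMethod("mapOrigin", "ResourceMap", function(x) x@origin)
#' @rdname accessors
setMethod("mapExtent", "ResourceMap", function(x)
  c(eastings = ncol(x@grid) * x@pixelSize,
    northings = nrow(x@grid) * x@pixelSize))

#' @rdname accessors
setMethod("birds", "SimulationResult", function(x) x@birds)
#' @rdname accessors
setMethod("ownerGrid", "SimulationResult", function(x) x@owner)
#' @rdname accessors
setMethod("nBirds", "SimulationResult", function(x) length(x@birds))
#' @rdname accessors
setMethod("runSeed", "SimulationResult", function(x) x@seed)

#' @rdname accessors
setMethod("territoryPixels", "Buzzard", function(x)
  c(x@roost, x@rgr, x@mead))

#' @rdname accessors
setMethod("coreArea", "RangeCore", function(x) x@areaHa)
#' @rdname accessors
setMethod("corePerimeter", "RangeCore", function(x) x@perimeterM)
#' @rdname accessors
setMethod("coreLevel", "RangeCore", function(x) x@level)
#' @rdname accessors
setMethod("corePolygon", "RangeCore", function(x) x@polygon)

#' Show methods for buteoABM classes
#'
#' Compact printed summaries of the package's S4 objects.
#'
#' @param object the object to display.
#' @return The object, invisibly.
#' @name show-methods
#' @aliases show,ResourceMap-method show,SimulationParams-method
#'   show,Buzzard-method show,SimulationResult-method
#'   show,RangeCore-method show,StudyMask-method show,WorldState-method
#' @exportMethod show
NULL

setMethod("show", "ResourceMap", function(object) {
  ext <- mapExtent(object)
  cat(sprintf("ResourceMap: %d x %d pixels at %g m (%.1f x %.1f km)\n",
              nrow(object@grid), ncol(object@grid), object@pixelSize,
              ext[["eastings"]] / 1000, ext[["northings"]] / 1000))
  tab <- tabulate(object@grid + 1L, nbins = length(.RES_CODES))
  names(tab) <- names(.RES_CODES)
  ha <- tab * pixelAreaHa(object)
  for (nm in names(tab))
    cat(sprintf("  %-9s %8d px %10.2f ha\n", nm, tab[[nm]], ha[[nm]]))
  invisible(object)
})

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams (RADA area requirements + forage search distances)\n")
  cat(sprintf("  roost %g ha | rough-ground %g ha within %g m | meadow %g ha within %g m\n",
              object@roostAreaHa, object@rgrAreaHa, object@rgrDistM,
              object@meadAreaHa, object@meadDistM))
  cat(sprintf("  connectivity %d, %s claims\n", object@connectivity,
              if (object@wholePatch) "whole-patch" else "truncated"))
  invisible(object)
})

setMethod("show", "Buzzard", function(object) {
  cat(sprintf("Buzzard #%d: %d roost + %d rough-ground + %d meadow pixels\n",
              object@id, length(object@roost), length(object@rgr),
              length(object@mead)))
  invisible(object)
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d settled birds, %d failed attempts (seed %s)\n",
              length(object@birds), object@failedAttempts,
              ifelse(is.na(object@seed), "none", object@seed)))
  invisible(object)
})

setMethod("show", "RangeCore", function(object) {
  cat(sprintf("RangeCore: bird #%d, %g%% polygon, %.3f ha, %.0f m perimeter\n",
              object@id, object@level, object@areaHa, object@perimeterM))
  invisible(object)
})

setMethod("show", "StudyMask", function(object) {
  cat(sprintf("StudyMask: %d core pixels of %d (strip %g m)\n",
              sum(object@core), length(object@core), object@stripWidth))
  invisible(object)
})

setMethod("show", "WorldState", function(object) {
  e <- object@env
  cat(sprintf("WorldState: %d x %d pixels, %d free, %d owned\n",
              nrow(e$res), ncol(e$res), sum(e$free), sum(e$owner > 0L)))
  invisible(object)
})
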