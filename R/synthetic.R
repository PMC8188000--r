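#' @include AllClasses.R resourceMap.R
NULL

## Grow one connected blob of up to n pixels over cells of `grid` equal to
## `allowed`, by randomized frontier sampling (4-neighbour growth gives
## compact, field-like shapes). Optionally constrains every blob pixel to
## lie within `radiusPx` (pixel units, centre-to-centre) of `centreRC`.
## Returns linear indices (possibly fewer than n if the blob gets trapped).
.growBlob <- function(grid, start, n, allowed, centreRC = NULL,
                      radiusPx = Inf) {
  nr <- nrow(grid); nc <- ncol(grid)
  offsets <- .neighbourOffsets(4L)
  okCell <- function(idx) {
    keep <- grid[idx] == allowed
    if (!is.null(centreRC) && is.finite(radiusPx)) {
      row <- (idx - 1L) %% nr + 1L
      col <- (idx - 1L) %/% nr + 1L
      keep <- keep &
        (row - centreRC[1L])^2 + (col - centreRC[2L])^2 <= radiusPx^2
    }
    keep
  }
  if (!okCell(start)) return(integer(0))
  inBlob <- logical(nr * nc)
  inCand <- logical(nr * nc)
  blob <- integer(n)
  blob[1L] <- start
  inBlob[start] <- TRUE
  size <- 1L
  cand <- .neighboursOf(start, nr, nc, offsets)
  cand <- unique(cand[okCell(cand)])
  inCand[cand] <- TRUE
  while (size < n && length(cand)) {
    pick <- if (length(cand) == 1L) 1L else sample.int(length(cand), 1L)
    cell <- cand[pick]
    cand <- cand[-pick]
    inCand[cell] <- FALSE
    size <- size + 1L
    blob[size] <- cell
    inBlob[cell] <- TRUE
    nb <- .neighboursOf(cell, nr, nc, offsets)
    nb <- nb[!inBlob[nb] & !inCand[nb]]
    nb <- unique(nb[okCell(nb)])
    if (length(nb)) {
      inCand[nb] <- TRUE
      cand <- c(cand, nb)
    }
  }
  blob[seq_len(size)]
}

#' Generate a synthetic landscape of explicit territory kits
#'
#' Builds a test landscape containing \code{nKits} self-contained,
#' well-separated "territory kits". Each kit is one woodland pixel (the
#' prospective roost), one connected rough-ground patch of
#' \code{rgrPixels} pixels placed entirely within \code{rgrRadiusM} of the
#' woodland pixel, and one connected meadow patch of \code{meadPixels}
#' pixels within \code{meadRadiusM}. Kit centres are at least \code{gapM}
#' apart, so under default search distances each kit supports exactly one
#' settled bird and kits cannot interact. Everything else is
#' \code{"other"}.
#'
#' @param nKits number of kits (0 yields an all-"other" map).
#' @param rgrPixels,meadPixels pixels per rough-ground / meadow patch; the
#'   defaults (10 and 220 at 25 m pixels) exceed the 0.56 ha and 13.5 ha
#'   RADA requirements.
#' @param rgrRadiusM,meadRadiusM maximum centre-to-centre distance (m) of
#'   patch pixels from the kit's woodland pixel.
#' @param gapM minimum distance (m) between kit centres; the default
#'   2 x 1200 m + 200 m prevents any cross-kit search.
#' @param pixelSize pixel edge (m).
#' @param worldCols,worldRows optional world size in pixels; by default the
#'   world is sized to hold the kit grid. Explicit sizes too small to hold
#'   the kits raise a placement error.
#' @param seed optional RNG seed; fixed seed gives an identical map.
#' @return A [ResourceMap].
#' @examples
#' m <- kitLandscape(3, seed = 1)
#' length(labelPatches(m, "meadow"))
#' @export
kitLandscape <- function(nKits, rgrPixels = 10L, meadPixels = 220L,
                         rgrRadiusM = 500, meadRadiusM = 1200,
                         gapM = 2 * 1200 + 200, pixelSize = 25,
                         worldCols = NULL, worldRows = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  marginPx <- ceiling(meadRadiusM / pixelSize) + 2L
  gapPx <- ceiling(gapM / pixelSize)
  if (nKits > 0L) {
    gcols <- ceiling(sqrt(nKits))
    grows <- ceiling(nKits / gcols)
  } else {
    gcols <- grows <- 1L
  }
  needCols <- 2L * marginPx + (gcols - 1L) * gapPx + 1L
  needRows <- 2L * marginPx + (grows - 1L) * gapPx + 1L
  if (is.null(worldCols)) worldCols <- needCols
  if (is.null(worldRows)) worldRows <- needRows
  if (nKits > 0L && (worldCols < needCols || worldRows < needRows))
    stop("cannot place ", nKits, " kits in a ", worldRows, " x ", worldCols,
         " world: need at least ", needRows, " x ", needCols)
  grid <- matrix(.RES_CODES[["other"]], worldRows, worldCols)
  if (nKits == 0L)
    return(resourceMap(grid, pixelSize = pixelSize))
  rgrRadPx <- rgrRadiusM / pixelSize
  meadRadPx <- meadRadiusM / pixelSize
  k <- 0L
  for (gr in seq_len(grows)) {
    for (gc in seq_len(gcols)) {
      if (k >= nKits) break
      k <- k + 1L
      row <- marginPx + (gr - 1L) * gapPx + 1L
      col <- marginPx + (gc - 1L) * gapPx + 1L
      centre <- (col - 1L) * worldRows + row
      grid[centre] <- .RES_CODES[["woodland"]]
      ## rough-ground patch: grow from a 4-neighbour of the roost
      start <- (col - 1L) * worldRows + row - 1L
      rgr <- .growBlob(grid, start, rgrPixels, .RES_CODES[["other"]],
                       centreRC = c(row, col), radiusPx = rgrRadPx)
      if (length(rgr) < rgrPixels)
        stop("kit ", k, ": rough-ground patch did not fit")
      grid[rgr] <- .RES_CODES[["rough"]]
      ## meadow patch: start a few pixels away so it clears the rough patch
      start <- NULL
      for (d in 3:12) {
        cand <- (col + d - 1L) * worldRows + row
        if (grid[cand] == .RES_CODES[["other"]]) { start <- cand; break }
      }
      if (is.null(start)) stop("kit ", k, ": no free start cell for meadow")
      mead <- .growBlob(grid, start, meadPixels, .RES_CODES[["other"]],
                        centreRC = c(row, col), radiusPx = meadRadPx)
      if (length(mead) < meadPixels)
        stop("kit ", k, ": meadow patch did not fit")
      grid[mead] <- .RES_CODES[["meadow"]]
    }
  }
  resourceMap(grid, pixelSize = pixelSize)
}

#' Generate a stochastic synthetic lowland landscape
#'
#' Emulates the structure of a lowland UK land-cover raster at 25 m grain:
#' scattered woodland copses (roost sites), many small rough-ground
#' patches, and meadow fields with a right-skewed (lognormal) size
#' distribution spanning sub-viable fragments to fields above the 20 ha
#' economically viable threshold, all embedded in non-resource cover.
#' Patches are grown as compact random blobs until each class reaches its
#' target cover fraction; late blobs may merge with earlier ones, giving a
#' realistic mix of field sizes.
#'
#' @param worldCols,worldRows world size in pixels.
#' @param pixelSize pixel edge (m).
#' @param woodlandFrac,roughFrac,meadowFrac,waterFrac target cover
#'   fractions; the remainder stays \code{"other"}.
#' @param woodlandPatchHa,roughPatchHa,waterPatchHa uniform patch-size
#'   ranges (ha) for the respective classes.
#' @param meadowMeanLogHa,meadowSdLogHa lognormal parameters of meadow
#'   field size (ha); defaults give a median field of ~3 ha with roughly
#'   5\% of fields exceeding 20 ha.
#' @param seed optional RNG seed (fixed seed reproduces the map exactly).
#' @return A [ResourceMap].
#' @examples
#' m <- syntheticLandscape(60, 60, seed = 7)
#' table(resourceGrid(m))
#' @export
syntheticLandscape <- function(worldCols = 200, worldRows = 200,
                               pixelSize = 25,
                               woodlandFrac = 0.02, roughFrac = 0.08,
                               meadowFrac = 0.30, waterFrac = 0,
                               woodlandPatchHa = c(0.25, 1.5),
                               roughPatchHa = c(0.2, 2),
                               meadowMeanLogHa = log(3),
                               meadowSdLogHa = 1.2,
                               waterPatchHa = c(5, 50),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(woodlandFrac + roughFrac + meadowFrac + waterFrac <= 1)
  grid <- matrix(.RES_CODES[["other"]], worldRows, worldCols)
  pxHa <- (pixelSize / 100)^2
  total <- worldRows * worldCols
  placeClass <- function(grid, code, targetPx, sizeDraw) {
    placed <- 0L
    misses <- 0L
    while (placed < targetPx && misses < 200L) {
      n <- max(1L, min(as.integer(round(sizeDraw() / pxHa)),
                       targetPx - placed))
      free <- which(grid == .RES_CODES[["other"]])
      if (!length(free)) break
      start <- free[sample.int(length(free), 1L)]
      blob <- .growBlob(grid, start, n, .RES_CODES[["other"]])
      if (length(blob) < max(1L, n %/% 4L)) { misses <- misses + 1L; next }
      grid[blob] <- code
      placed <- placed + length(blob)
    }
    grid
  }
  unif <- function(rg) function() stats::runif(1, rg[1], rg[2])
  ## meadow first (largest blobs need room), then rough, woodland, water
  grid <- placeClass(grid, .RES_CODES[["meadow"]],
                     as.integer(round(meadowFrac * total)),
                     function() stats::rlnorm(1, meadowMeanLogHa,
                                              meadowSdLogHa))
  grid <- placeClass(grid, .RES_CODES[["rough"]],
                     as.integer(round(roughFrac * total)),
                     unif(roughPatchHa))
  grid <- placeClass(grid, .RES_CODES[["woodland"]],
                     as.integer(round(woodlandFrac * total)),
                     unif(woodlandPatchHa))
  if (waterFrac > 0)
    grid <- placeClass(grid, .RES_CODES[["water"]],
                       as.integer(round(waterFrac * total)),
                       unif(waterPatchHa))
  resourceMap(grid, pixelSize = pixelSize)
}

#' Fine-grained resource mosaic for distance-sensitive analyses
#'
#' A [syntheticLandscape()] preset in which rough-ground occurs as
#' near-single-pixel scatter and meadow as many small (roughly 0.5-1.5 ha)
#' fields. Because every bird must then assemble its requirements from
#' many patches drawn across its search discs, territory spread -- and
#' hence the core-area profile -- responds strongly to the forage search
#' distances, which makes this the landscape of choice for calibration
#' self-consistency and sensitivity-direction checks.
#'
#' @param seed RNG seed for the landscape.
#' @param worldCols,worldRows world size in pixels (25 m).
#' @return A [ResourceMap].
#' @examples
#' m <- fineMosaicLandscape(seed = 3, worldCols = 60, worldRows = 60)
#' @export
fineMosaicLandscape <- function(seed, worldCols = 150, worldRows = 150) {
  syntheticLandscape(worldCols, worldRows, seed = seed,
                     meadowFrac = 0.25, meadowMeanLogHa = log(0.8),
                     meadowSdLogHa = 0.4,
                     roughFrac = 0.05, roughPatchHa = c(0.06, 0.15),
                     woodlandFrac = 0.015)
}
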