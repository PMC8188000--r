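#' @include AllClasses.R
NULL

#' Construct a ResourceMap
#'
#' @param grid integer matrix of resource codes (see [resourceCodes()]), or
#'   a character matrix of resource names; row 1 is the northern edge.
#' @param pixelSize pixel edge length in metres (square pixels).
#' @param origin numeric(2): easting/northing of the lower-left (south-west)
#'   grid corner, in metres.
#' @return A [ResourceMap].
#' @examples
#' m <- resourceMap(matrix("meadow", 4, 4), pixelSize = 25)
#' mapExtent(m)
#' @export
resourceMap <- function(grid, pixelSize = 25, origin = c(0, 0)) {
  if (is.character(grid)) {
    codes <- .RES_CODES[grid]
    if (anyNA(codes)) stop("unknown resource name in grid")
    grid <- matrix(unname(codes), nrow(grid), ncol(grid))
  }
  storage.mode(grid) <- "integer"
  new("ResourceMap", grid = grid, pixelSize = pixelSize,
      origin = as.numeric(origin))
}

## --- pixel index helpers -------------------------------------------------
## Pixels are addressed as 1-based linear indices into the grid matrix
## (column-major). Geographic positions are pixel centres; row 1 = north.

.pixelXY <- function(map, idx) {
  nr <- nrow(map@grid)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  ps <- map@pixelSize
  cbind(x = map@origin[1] + (col - 0.5) * ps,
        y = map@origin[2] + (nr - row + 0.5) * ps)
}

.neighbourOffsets <- function(connectivity) {
  if (connectivity == 4L)
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
}

## Neighbours of a set of linear indices; returns (possibly duplicated)
## in-bounds linear indices.
.neighboursOf <- function(idx, nr, nc, offsets) {
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  nrow_off <- nrow(offsets)
  r <- rep(row, each = nrow_off) + rep.int(offsets[, 1L], length(idx))
  c <- rep(col, each = nrow_off) + rep.int(offsets[, 2L], length(idx))
  ok <- r >= 1L & r <= nr & c >= 1L & c <= nc
  (c[ok] - 1L) * nr + r[ok]
}

#' Translate a land-cover raster into a buzzard resource map
#'
#' Applies a category-to-resource mapping table to an integer land-cover
#' grid (for example a Land Cover Map of Great Britain tile). Category IDs
#' absent from the table resolve to \code{"other"}; \code{NA} cells (NODATA)
#' become \code{"water"}.
#'
#' @param landcover integer matrix of land-cover category IDs.
#' @param mapping data.frame with columns \code{mapCat} (integer category
#'   ID) and \code{resource} (resource name, see [resourceCodes()]).
#' @param pixelSize,origin georeferencing, as in [resourceMap()].
#' @return A [ResourceMap] with the same dimensions as \code{landcover}.
#' @examples
#' lc <- matrix(c(1L, 2L, 3L, 1L), 2, 2)
#' mp <- data.frame(mapCat = 1:2, resource = c("woodland", "meadow"))
#' resourceGrid(translateLandcover(lc, mp))
#' @export
translateLandcover <- function(landcover, mapping, pixelSize = 25,
                               origin = c(0, 0)) {
  if (!is.matrix(landcover) || length(landcover) == 0L)
    stop("landcover must be a non-empty matrix")
  if (!all(c("mapCat", "resource") %in% names(mapping)))
    stop("mapping must have columns 'mapCat' and 'resource'")
  res <- as.character(mapping$resource)
  bad <- setdiff(res, names(.RES_CODES))
  if (length(bad))
    stop("unknown resource name(s) in mapping: ", paste(bad, collapse = ", "))
  codes <- .RES_CODES[res]
  out <- matrix(.RES_CODES[["other"]], nrow(landcover), ncol(landcover))
  m <- match(landcover, mapping$mapCat)
  hit <- !is.na(m)
  out[hit] <- codes[m[hit]]
  out[is.na(landcover)] <- .RES_CODES[["water"]]
  resourceMap(out, pixelSize = pixelSize, origin = origin)
}

#' Label contiguous patches of one resource
#'
#' Partitions all pixels of a given resource into connected patches under
#' 4- or 8-neighbour adjacency (default 8, so diagonally touching field
#' corners form one patch at 25 m grain).
#'
#' @param map a [ResourceMap].
#' @param resource resource name (see [resourceCodes()]).
#' @param connectivity 4 or 8.
#' @return A list of patches, each a list with elements \code{resource},
#'   \code{pixels} (integer linear indices), and \code{areaHa}. Patches are
#'   ordered by their first (smallest) pixel index. An absent resource
#'   yields an empty list.
#' @examples
#' m <- resourceMap(matrix(c("meadow", "other", "other", "meadow"), 2, 2))
#' length(labelPatches(m, "meadow", connectivity = 4))
#' length(labelPatches(m, "meadow", connectivity = 8))
#' @export
labelPatches <- function(map, resource, connectivity = 8) {
  code <- .resCode(resource)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  g <- map@grid
  nr <- nrow(g); nc <- ncol(g)
  target <- which(g == code)
  if (length(target) == 0L) return(list())
  offsets <- .neighbourOffsets(connectivity)
  inClass <- g == code
  unvisited <- inClass
  pxArea <- pixelAreaHa(map)
  patches <- vector("list", 0L)
  for (start in target) {
    if (!unvisited[start]) next
    comp <- .floodComponent(start, inClass, unvisited, nr, nc, offsets)
    unvisited[comp] <- FALSE
    patches[[length(patches) + 1L]] <-
      list(resource = resource, pixels = comp,
           areaHa = length(comp) * pxArea)
  }
  patches
}

## Breadth-first connected component of `inClass & unvisited` pixels
## containing `start`. Frontier expansion is vectorised; marks nothing.
.floodComponent <- function(start, inClass, unvisited, nr, nc, offsets,
                            maxPixels = Inf) {
  seen <- c(start)
  unvisited[start] <- FALSE
  frontier <- start
  while (length(frontier) && length(seen) < maxPixels) {
    nb <- unique(.neighboursOf(frontier, nr, nc, offsets))
    nb <- nb[inClass[nb] & unvisited[nb]]
    if (!length(nb)) break
    if (length(seen) + length(nb) > maxPixels)
      nb <- nb[seq_len(maxPixels - length(seen))]
    unvisited[nb] <- FALSE
    seen <- c(seen, nb)
    frontier <- nb
  }
  sort(seen)
}

#' Build a study-area mask with a boundary strip
#'
#' Marks the pixels whose centres fall inside a rectangular core extent.
#' The surrounding boundary strip (the rest of the simulated world, up to
#' \code{stripWidth} from the core) is simulated but excluded from
#' abundance: strip birds may defend pixels inside the core, balancing
#' excursions of core birds.
#'
#' @param map a [ResourceMap].
#' @param coreExtent numeric(4): \code{c(xmin, xmax, ymin, ymax)} in map
#'   units (metres). Defaults to the full map.
#' @param stripWidth strip width in metres. The default, twice the meadow
#'   forage search distance (2400 m), guarantees no bird roosting beyond
#'   the modelled world could have reached into the core.
#' @return A [StudyMask].
#' @examples
#' m <- resourceMap(matrix("other", 240, 880))
#' mask <- makeStudyMask(m, c(0, 22000, 0, 6000), stripWidth = 0)
#' sum(mask@core) == 880 * 240
#' @export
makeStudyMask <- function(map, coreExtent = NULL, stripWidth = 2400) {
  ext <- mapExtent(map)
  x0 <- map@origin[1]; y0 <- map@origin[2]
  if (is.null(coreExtent))
    coreExtent <- c(x0, x0 + ext[["eastings"]], y0, y0 + ext[["northings"]])
  if (length(coreExtent) != 4L) stop("coreExtent must be c(xmin,xmax,ymin,ymax)")
  if (coreExtent[1] < x0 - 1e-9 || coreExtent[3] < y0 - 1e-9 ||
      coreExtent[2] > x0 + ext[["eastings"]] + 1e-9 ||
      coreExtent[4] > y0 + ext[["northings"]] + 1e-9)
    stop("coreExtent exceeds the map extent")
  nr <- nrow(map@grid); nc <- ncol(map@grid)
  ps <- map@pixelSize
  cx <- x0 + (seq_len(nc) - 0.5) * ps
  cy <- y0 + (nr - seq_len(nr) + 0.5) * ps
  core <- outer(cy >= coreExtent[3] & cy <= coreExtent[4],
                cx >= coreExtent[1] & cx <= coreExtent[2], `&`)
  new("StudyMask", core = core, stripWidth = as.numeric(stripWidth))
}
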