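#' @include AllClasses.R resourceMap.R
NULL

## Parse an ESRI ASCII grid into its header and raw integer matrix
## (row 1 = northernmost). Shared by the resource-map reader and the
## land-cover translation stage.
.readAsciiRaw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  g <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value))
    g[g == as.integer(hdr$nodata_value)] <- NA_integer_
  list(grid = g, cellsize = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner))
}

.writeAsciiRaw <- function(grid, path, cellsize, origin = c(0, 0),
                           nodata = -9999L) {
  g <- grid
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(g)),
           sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2]),
           sprintf("cellsize %.10g", cellsize),
           sprintf("NODATA_value %d", nodata))
  writeLines(c(hdr, apply(g, 1L, paste, collapse = " ")), path)
  invisible(path)
}

#' Read and write resource maps as ESRI ASCII grids
#'
#' Resource maps are stored as single-band ESRI ASCII grids
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by one row of integer codes per grid row, northernmost first). NODATA
#' cells are read as \code{"water"}; unknown codes raise a validation
#' error. A write-then-read round trip reproduces the grid, pixel size and
#' origin exactly.
#'
#' @param path file path (conventionally \code{.asc}).
#' @param map a [ResourceMap] (for writing).
#' @return `readResourceMap`: a [ResourceMap]. `writeResourceMap`:
#'   `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' m <- resourceMap(matrix(c("meadow", "woodland", "other", "water"), 2, 2))
#' writeResourceMap(m, f)
#' identical(resourceGrid(readResourceMap(f)), resourceGrid(m))
#' @export
readResourceMap <- function(path) {
  raw <- .readAsciiRaw(path)
  g <- raw$grid
  g[is.na(g)] <- .RES_CODES[["water"]]
  unknown <- setdiff(unique(as.vector(g)), unname(.RES_CODES))
  if (length(unknown))
    stop("grid contains unknown resource code(s): ",
         paste(unknown, collapse = ", "))
  resourceMap(g, pixelSize = raw$cellsize, origin = raw$origin)
}

#' @rdname readResourceMap
#' @export
writeResourceMap <- function(map, path) {
  stopifnot(is(map, "ResourceMap"))
  .writeAsciiRaw(map@grid, path, cellsize = map@pixelSize,
                 origin = map@origin)
  invisible(path)
}

#' Read a category-to-resource mapping table
#'
#' Two-column delimited table (comma or whitespace) with columns
#' \code{mapCat} (integer land-cover category ID) and \code{resource}
#' (resource name), as consumed by [translateLandcover()].
#'
#' @param path file path.
#' @return data.frame with columns \code{mapCat}, \code{resource}.
#' @export
readCategoryMapping <- function(path) {
  tb <- utils::read.csv(path, strip.white = TRUE)
  if (!all(c("mapCat", "resource") %in% names(tb)))
    stop("mapping table must have columns 'mapCat' and 'resource'")
  tb$mapCat <- as.integer(tb$mapCat)
  tb$resource <- as.character(tb$resource)
  tb
}
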