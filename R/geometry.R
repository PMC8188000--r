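## Planar geometry for convex home-range polygons. Vertices are n x 2
## matrices in metres, counter-clockwise, not closed.

## Signed shoelace area (positive for counter-clockwise rings), m^2.
.polyAreaM2 <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Ring perimeter, m. A 2-vertex "polygon" (collinear degenerate) is the
## out-and-back segment, perimeter twice its length.
.polyPerimM <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 2L) return(0)
  j <- c(seq_len(n)[-1L], 1L)
  sum(sqrt((poly[j, 1L] - poly[, 1L])^2 + (poly[j, 2L] - poly[, 2L])^2))
}

## Convex hull as counter-clockwise vertex matrix (chull returns clockwise).
.convexHull <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(pts)
  h <- grDevices::chull(pts)
  pts[rev(h), , drop = FALSE]
}

## Sutherland-Hodgman clip of convex polygon `subject` by convex polygon
## `clip`, both counter-clockwise. Returns the intersection polygon (may
## have 0 rows). Exact for convex-convex input up to floating point.
.clipConvex <- function(subject, clip, eps = 1e-9) {
  out <- subject
  nClip <- nrow(clip)
  if (is.null(nClip) || nClip < 3L || is.null(nrow(subject)) ||
      nrow(subject) < 3L)
    return(subject[0L, , drop = FALSE])
  for (i in seq_len(nClip)) {
    a <- clip[i, ]
    b <- clip[if (i == nClip) 1L else i + 1L, ]
    if (is.null(nrow(out)) || nrow(out) == 0L) break
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) -
            (b[2] - a[2]) * (out[, 1] - a[1])
    keepPrev <- side >= -eps
    n <- nrow(out)
    newPts <- list()
    for (k in seq_len(n)) {
      kPrev <- if (k == 1L) n else k - 1L
      if (keepPrev[kPrev] != keepPrev[k]) {
        p <- out[kPrev, ]; q <- out[k, ]
        denom <- side[kPrev] - side[k]
        t <- if (abs(denom) < 1e-30) 0 else side[kPrev] / denom
        newPts[[length(newPts) + 1L]] <- p + t * (q - p)
      }
      if (keepPrev[k]) newPts[[length(newPts) + 1L]] <- out[k, ]
    }
    out <- if (length(newPts)) do.call(rbind, newPts)
           else out[0L, , drop = FALSE]
  }
  out
}
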