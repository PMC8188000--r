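# Build a small ResourceMap from drawing strings: one string per grid row
# (row 1 = north), characters w = woodland, r = rough, m = meadow,
# ~ = water, . = other.
mapFromStrings <- function(rows, pixelSize = 25, origin = c(0, 0)) {
  key <- c(w = "woodland", r = "rough", m = "meadow", "~" = "water",
           "." = "other")
  chars <- do.call(rbind, strsplit(rows, ""))
  resourceMap(matrix(key[chars], nrow(chars), ncol(chars)),
              pixelSize = pixelSize, origin = origin)
}

# Transitive-closure patch labelling oracle (quadratic, small maps only).
bruteForcePatches <- function(map, resource, connectivity = 8) {
  g <- resourceGrid(map)
  nr <- nrow(g)
  px <- which(g == resourceCodes()[[resource]])
  if (!length(px)) return(list())
  rowOf <- (px - 1L) %% nr + 1L
  colOf <- (px - 1L) %/% nr + 1L
  n <- length(px)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dr <- abs(rowOf[i] - rowOf[j]); dc <- abs(colOf[i] - colOf[j])
      adj <- if (connectivity == 4) dr + dc == 1L
             else max(dr, dc) == 1L && dr + dc > 0L
      if (adj && lab[i] != lab[j]) {
        lab[pmax(lab[i], lab[j]) == lab] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(split(px, lab), sort)
}

# Distances (m) from each of a set of pixels to a reference pixel,
# computed from scratch (centre to centre).
pixelDistM <- function(map, idx, ref) {
  nr <- nrow(resourceGrid(map))
  ps <- pixelSize(map)
  dr <- ((idx - 1L) %% nr) - ((ref - 1L) %% nr)
  dc <- ((idx - 1L) %/% nr) - ((ref - 1L) %/% nr)
  sqrt(dr^2 + dc^2) * ps
}

# Exact two-tailed Mann-Whitney p by full enumeration of all C(m+n, m)
# assignments of the pooled ranks to sample A (no ties assumed).
enumerateExactP <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  us <- apply(sets, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  mu <- m * n / 2
  mean(abs(us - mu) >= abs(U1 - mu) - 1e-9)
}
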