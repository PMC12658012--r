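# Independent pure-R oracles used to cross-check the package
# implementations (which route through compiled code). These deliberately
# use naive loops / brute force so the two paths share no code.

# Brute-force surface extraction: foreground voxels with at least one
# 6-neighbour background (outside the grid counts as background).
oracleSurfacePoints <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(arr)
  pts <- NULL
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (arr[i, j, k] != 1) next
    isSurf <- FALSE
    for (q in 1:6) {
      ii <- i + nb[q, 1]; jj <- j + nb[q, 2]; kk <- k + nb[q, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          arr[ii, jj, kk] == 0) { isSurf <- TRUE; break }
    }
    if (isSurf) pts <- rbind(pts, (c(i, j, k) - 1) * spacing + origin)
  }
  pts
}

# Brute-force all-pairs directed nearest-neighbour distances.
oracleDirectedDists <- function(A, B) {
  apply(A, 1, function(a) {
    sqrt(min(colSums((t(B) - a)^2)))
  })
}

# Brute-force symmetric ASD / HD95 from two binary arrays.
oracleSurfaceMetrics <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- oracleSurfacePoints(a, spacing)
  pb <- oracleSurfacePoints(b, spacing)
  dd <- c(oracleDirectedDists(pa, pb), oracleDirectedDists(pb, pa))
  list(asd = mean(dd),
       hd95 = unname(quantile(dd, 0.95, type = 7)),
       hdmax = max(dd))
}

# Brute-force 3x3x3 box erosion.
oracleErode <- function(arr) {
  d <- dim(arr)
  out <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    keep <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          arr[ii, jj, kk] == 0) keep <- FALSE
    }
    out[i, j, k] <- as.integer(keep && arr[i, j, k] == 1)
  }
  out
}

# Random blobby binary mask on a small grid (seeded).
randomMask <- function(d = c(8, 8, 8), p = 0.3) {
  array(as.integer(runif(prod(d)) < p), d)
}

# Tiny phantom parameters for fast unit tests.
tinyPhantomParams <- function(noiseSd = 0, ...) {
  phantomParams(gridDim = c(32L, 32L, 64L), spacing = c(4, 4, 6.25),
                noiseSd = noiseSd, ...)
}

# Reduced network/pipeline configuration shared by pipeline tests.
testSpec <- function() unetSpec(depth = 2L, baseChannels = 4L)
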