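# Shared fixtures and independent oracles.

# Brute-force nearest-seed Chebyshev field: the O(h*w*|S|) oracle.
bruteChebyshev <- function(seeds, dim) {
  out <- matrix(NA_integer_, dim[1], dim[2])
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2]))
    out[r, c] <- min(pmax(abs(r - seeds[, 1]), abs(c - seeds[, 2])))
  out
}

chebDist <- function(a, b) max(abs(a - b))

# All three pairings of four points; minimal total set-distance matching.
exhaustiveMatching <- function(points) {
  stopifnot(length(points) == 4)
  d <- function(i, j) {
    D <- pmax(abs(outer(points[[i]][, 1], points[[j]][, 1], "-")),
              abs(outer(points[[i]][, 2], points[[j]][, 2], "-")))
    min(D)
  }
  opts <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
               list(c(1, 4), c(2, 3)))
  costs <- vapply(opts, function(m) d(m[[1]][1], m[[1]][2]) +
                                     d(m[[2]][1], m[[2]][2]), numeric(1))
  opts[[which.min(costs)]]
}

# Pixel raster of a crescent: disc minus a shifted disc.
crescentPixels <- function(center = c(20, 20), r = 12, shift = 8) {
  d1 <- discPixels(center, r)
  d2 <- discPixels(center + c(0, shift), r)
  k1 <- paste(d1[, 1], d1[, 2]); k2 <- paste(d2[, 1], d2[, 2])
  d1[!(k1 %in% k2), , drop = FALSE]
}

# Audit a cut path: interior pixels have exactly two 8-neighbours on the
# path, endpoints exactly one.
auditPath <- function(path) {
  n <- nrow(path)
  if (n == 1) return(TRUE)
  nb <- sapply(seq_len(n), function(i) {
    sum(vapply(seq_len(n), function(j)
      i != j && max(abs(path[i, ] - path[j, ])) <= 1, logical(1)))
  })
  all(nb[c(1, n)] == 1) && (n == 2 || all(nb[2:(n - 1)] == 2))
}

# Mask -> count of 8-connected components (via the package labeller,
# cross-checked elsewhere against a flood fill).
nComponents <- function(mask) {
  sc <- labelComponents(mask)
  nObjects(sc)
}

# Independent flood-fill component count (8-connectivity).
floodComponents <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (mask[r, c] == 1 && !seen[r, c]) {
      n <- n + 1
      queue <- list(c(r, c)); seen[r, c] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
              mask[rr, cc] == 1 && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  n
}

# Stage-2 on a clump mask whose single object is forced OC (unit fixtures
# have one object, which stage 1 by definition calls PS).
splitForced <- function(mask) {
  sc <- labelComponents(mask)
  sc@features$label <- rep("OC", nObjects(sc))
  suppressWarnings(splitCells(sc))
}
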