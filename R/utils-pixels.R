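# Low-level pixel-set utilities shared across the pipeline.
#
# Pixel sets are integer matrices with two columns (row, col), 1-based,
# origin at the top-left of the image, consistent with R matrix indexing.

# 8-neighbourhood offsets, starting at the east neighbour and continuing
# counter-clockwise (the convention used by the thinning operator).
.NB8 <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
)

# 4-neighbourhood offsets (N, S, W, E)
.NB4 <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))

#' @noRd
.asPixelMatrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.integer(p), ncol = 2L)
  storage.mode(p) <- "integer"
  colnames(p) <- c("row", "col")
  p
}

# Shift a matrix by (dr, dc); vacated cells get `fill`.
.shiftMat <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h); cs <- seq_len(w)
  rsrc <- rs - dr; csrc <- cs - dc
  rok <- rsrc >= 1L & rsrc <= h
  cok <- csrc >= 1L & csrc <= w
  out[rs[rok], cs[cok]] <- m[rsrc[rok], csrc[cok]]
  out
}

# Logical matrix of pixels that have at least one TRUE 8-neighbour in `m`.
.dilate8 <- function(m) {
  out <- m
  for (k in seq_len(nrow(.NB8)))
    out <- out | .shiftMat(m, .NB8[k, 1L], .NB8[k, 2L], FALSE)
  out
}

# Inner 8-boundary of a logical matrix: TRUE pixels with at least one
# FALSE (or out-of-image) 8-neighbour.
.innerBoundary8 <- function(m) {
  inside <- m
  for (k in seq_len(nrow(.NB8)))
    inside <- inside & .shiftMat(m, .NB8[k, 1L], .NB8[k, 2L], FALSE)
  m & !inside
}

# Pixel matrix -> logical window matrix plus the window offset.
# Window covers the bounding box padded by `pad`, clipped to `dim`.
.pixelWindow <- function(px, dim, pad = 0L) {
  r0 <- max(1L, min(px[, 1L]) - pad); r1 <- min(dim[1L], max(px[, 1L]) + pad)
  c0 <- max(1L, min(px[, 2L]) - pad); c1 <- min(dim[2L], max(px[, 2L]) + pad)
  m <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  m[cbind(px[, 1L] - r0 + 1L, px[, 2L] - c0 + 1L)] <- TRUE
  list(m = m, r0 = r0, c0 = c0)
}

# Inverse of .pixelWindow: TRUE cells of window matrix -> absolute pixels.
.windowPixels <- function(m, r0, c0) {
  idx <- which(m, arr.ind = TRUE)
  .asPixelMatrix(cbind(idx[, 1L] + r0 - 1L, idx[, 2L] + c0 - 1L))
}

# Chebyshev distance between two pixel sets (min over member pairs).
.setChebyshev <- function(a, b) {
  a <- .asPixelMatrix(a); b <- .asPixelMatrix(b)
  dr <- abs(outer(a[, 1L], b[, 1L], "-"))
  dc <- abs(outer(a[, 2L], b[, 2L], "-"))
  min(pmax(dr, dc))
}

# Per-pixel Chebyshev distance from each row of `a` to the set `b`.
.chebyshevToSet <- function(a, b) {
  a <- .asPixelMatrix(a); b <- .asPixelMatrix(b)
  d <- pmax(abs(outer(a[, 1L], b[, 1L], "-")), abs(outer(a[, 2L], b[, 2L], "-")))
  if (ncol(d) == 1L) as.vector(d) else apply(d, 1L, min)
}

# Local geometry of a foreground mask around a point: the fraction of
# foreground in a disc window and the inward normal (foreground centroid
# minus background centroid, normalized). Radius 5 px: about half a cell
# radius at the 20x scale, enough to smooth rasterization.
.localGeometry <- function(fgMask, center, radius = 5L) {
  h <- nrow(fgMask); w <- ncol(fgMask)
  r0 <- max(1L, floor(center[1L]) - radius); r1 <- min(h, ceiling(center[1L]) + radius)
  c0 <- max(1L, floor(center[2L]) - radius); c1 <- min(w, ceiling(center[2L]) + radius)
  rr <- r0:r1; cc <- c0:c1
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  inDisc <- (R - center[1L])^2 + (C - center[2L])^2 <= radius^2
  fg <- fgMask[rr, cc, drop = FALSE] & inDisc
  bg <- !fgMask[rr, cc, drop = FALSE] & inDisc
  nf <- sum(fg); nb <- sum(bg)
  frac <- nf / max(nf + nb, 1L)
  if (nf == 0L || nb == 0L)
    return(list(fgFraction = frac, normal = c(NA_real_, NA_real_)))
  u <- c(sum(R[fg]) / nf - sum(R[bg]) / nb, sum(C[fg]) / nf - sum(C[bg]) / nb)
  n2 <- sqrt(sum(u^2))
  list(fgFraction = frac,
       normal = if (n2 == 0) c(NA_real_, NA_real_) else u / n2)
}

# Deterministic ordering of a pixel matrix: by row then col.
.lexOrder <- function(px) {
  px[order(px[, 1L], px[, 2L]), , drop = FALSE]
}

# 8-connected component labelling. EBImage::bwlabel() is 4-connected, so
# labels that touch diagonally are merged with a small union-find pass and
# renumbered 1..N in order of first (column-major) appearance.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal label adjacencies
  a1 <- lab[-h, -w]; b1 <- lab[-1L, -1L]
  a2 <- lab[-1L, -w]; b2 <- lab[-h, -1L]
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1L]); rb <- find(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1L))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # renumber to consecutive ids in order of first appearance
  ids <- unique(lab[lab > 0L])
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Breadth-first shortest path between two pixels inside a logical window.
# Returns an ordered pixel matrix (window coordinates) or NULL.
.bfsPath <- function(m, start, end, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  idx <- function(p) (p[2L] - 1L) * h + p[1L]
  if (!m[start[1L], start[2L]] || !m[end[1L], end[2L]]) return(NULL)
  nb <- if (connectivity == 8L) .NB8 else .NB4
  prev <- integer(h * w)          # 0 = unvisited
  si <- idx(start); ei <- idx(end)
  prev[si] <- -1L
  frontier <- si
  found <- si == ei
  while (length(frontier) && !found) {
    nxt <- integer(0)
    for (k in seq_len(nrow(nb))) {
      cand <- frontier + nb[k, 1L] + nb[k, 2L] * h
      r <- ((frontier - 1L) %% h) + 1L + nb[k, 1L]
      c <- ((frontier - 1L) %/% h) + 1L + nb[k, 2L]
      ok <- r >= 1L & r <= h & c >= 1L & c <= w
      cand <- cand[ok]
      ok2 <- m[cand] & prev[cand] == 0L
      cand <- cand[ok2]
      if (length(cand)) {
        prev[cand] <- frontier[ok][ok2]
        nxt <- c(nxt, cand)
      }
    }
    if (ei %in% nxt) { found <- TRUE; break }
    frontier <- unique(nxt)
  }
  if (!found) return(NULL)
  # walk back
  path <- ei
  while (path[1L] != si) path <- c(prev[path[1L]], path)
  cbind(row = ((path - 1L) %% h) + 1L, col = ((path - 1L) %/% h) + 1L)
}

# Remove redundant path pixels: if path[i] and path[i+2] are 8-adjacent,
# path[i+1] is dropped. Guarantees interior pixels have exactly two path
# neighbours under 8-connectivity.
.straightenPath <- function(path) {
  repeat {
    n <- nrow(path)
    if (n <= 2L) return(path)
    drop <- rep(FALSE, n)
    i <- 1L
    while (i + 2L <= n) {
      if (max(abs(path[i, ] - path[i + 2L, ])) <= 1L) {
        drop[i + 1L] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
    if (!any(drop)) return(path)
    path <- path[!drop, , drop = FALSE]
  }
}
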