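# Chessboard-distance seed growing and the field algebra built on it.
#
# Every distance in stage 2 is the chessboard (Chebyshev) metric
# max(|dr|, |dc|): computationally cheap and, for the morphology analysed
# here, equivalent in effect to Euclidean distance. A "field" grown from a
# seed set S assigns every pixel its distance to the nearest seed (seeds
# are 0). The same construction yields:
#   DA, DC  — fields grown from an ST's arc and chord; their sum DM peaks
#             on the arc at the critical (initial splitting) point;
#   D_p     — field grown from a splitting point p; B_{p,v} = D_p + D_v
#             attains its minimum, the set distance between p and v, on
#             exactly the geodesic corridor joining them.

#' Grow a chessboard distance field from a seed set
#'
#' @param seeds pixel matrix of seed positions (distance 0).
#' @param dim field dimensions c(h, w).
#' @return Integer h x w matrix: each pixel's Chebyshev distance to its
#'   nearest seed.
#' @examples
#' chebyshevField(cbind(1, 1), c(3, 3))   # max(row, col) - 1 closed form
#' @export
chebyshevField <- function(seeds, dim) {
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  seeds <- .asPixelMatrix(seeds)
  if (any(seeds[, 1L] < 1L | seeds[, 1L] > dim[1L] |
          seeds[, 2L] < 1L | seeds[, 2L] > dim[2L]))
    stop("seeds must lie inside the field")
  R <- matrix(seq_len(dim[1L]), dim[1L], dim[2L])
  C <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE)
  field <- matrix(Inf, dim[1L], dim[2L])
  for (i in seq_len(nrow(seeds)))
    field <- pmin(field, pmax(abs(R - seeds[i, 1L]), abs(C - seeds[i, 2L])))
  matrix(as.integer(field), dim[1L], dim[2L])
}

#' Critical point of a splitting triangle
#'
#' The initial splitting point: the arc pixel(s) at maximal chessboard
#' distance from the chord. (On the arc the arc-grown field DA is zero, so
#' the maximum of DM = DA + DC over the arc is the maximum of the
#' chord-distance DC.) Ties return every maximal pixel: a splitting point
#' may consist of several pixels.
#'
#' @param arc,chord pixel matrices from \code{\link{decomposeST}}.
#' @return Pixel matrix of the splitting point (>= 1 rows), lexicographically
#'   ordered.
#' @export
criticalPoint <- function(arc, chord) {
  arc <- .asPixelMatrix(arc); chord <- .asPixelMatrix(chord)
  if (nrow(arc) == 0L) stop("arc must be non-empty")
  d <- .chebyshevToSet(arc, chord)
  .lexOrder(arc[d == max(d), , drop = FALSE])
}

# Persistent peaks of the chord-distance profile along an arc.
#
# When the convex hull's tangent edge clears an interior cell of a clump
# (bent chains), adjacent concave regions merge into a single ST whose arc
# carries one distance peak per pinch. Peaks are separated by topological
# persistence: pixels are activated in order of decreasing chord distance
# and merged by 8-adjacency; a component whose summit stands at least
# `minProminence` above the level at which it merges into a higher
# component is a splitting point of its own, otherwise it is absorbed.
# With a single peak (or a plateau) this reduces to the plain argmax set.
.arcPeaks <- function(arc, dvals, minProminence = 2L) {
  n <- nrow(arc)
  ord <- order(-dvals, arc[, 1L], arc[, 2L])
  key <- paste(arc[, 1L], arc[, 2L])
  pos <- seq_len(n); names(pos) <- key
  parent <- integer(n)                 # 0 = inactive
  birth <- numeric(n); summit <- vector("list", n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  peaks <- list()
  for (i in ord) {
    parent[i] <- i; birth[i] <- dvals[i]; summit[[i]] <- i
    # neighbours already active
    nb <- paste(rep(arc[i, 1L], 8L) + .NB8[, 1L],
                rep(arc[i, 2L], 8L) + .NB8[, 2L])
    hits <- pos[nb[nb %in% key]]
    for (q in hits) {
      if (parent[q] == 0L) next
      ra <- find(i); rb <- find(q)
      if (ra == rb) next
      # higher-born root wins; loser dies at this level
      if (birth[ra] < birth[rb] ||
          (birth[ra] == birth[rb] && ra > rb)) { tmp <- ra; ra <- rb; rb <- tmp }
      if (birth[rb] - dvals[i] >= minProminence) {
        peaks[[length(peaks) + 1L]] <- summit[[rb]]
      } else if (birth[rb] == birth[ra] && birth[rb] == dvals[i]) {
        summit[[ra]] <- c(summit[[ra]], summit[[rb]])   # joint plateau
      }
      parent[rb] <- ra
    }
    # same-level plateau summits accumulate
    r <- find(i)
    if (dvals[i] == birth[r] && !(i %in% summit[[r]]))
      summit[[r]] <- c(summit[[r]], i)
  }
  roots <- unique(vapply(which(parent > 0L), find, integer(1L)))
  for (r in roots) peaks[[length(peaks) + 1L]] <- summit[[r]]
  lapply(peaks, function(idx) .lexOrder(arc[idx, , drop = FALSE]))
}

#' Pair up the initial splitting points of a cell
#'
#' Scenario for cells with two or more splitting points: the partner of a
#' point p is the point v minimizing the minimum of B_{p,v} = D_p + D_v,
#' i.e. the set-to-set chessboard distance. Pairs are formed greedily in
#' ascending distance order, each point used at most once; unpaired points
#' (an odd count, or no admissible partner) are left over, to be routed to
#' the cell contour by \code{\link{contourFallback}}. Ties are broken by
#' lexicographic point order so runs are deterministic and independent of
#' input order.
#'
#' A splitting line joins a concave region to its \emph{counterpart}
#' concave region — the one indenting the cell from the opposite side.
#' When \code{directions} is supplied (the unit direction in which each
#' concavity points, chord towards critical point), candidate pairs whose
#' concavities point the same way (positive dot product) are inadmissible:
#' two dents on the same flank of a clump never delimit a cell between
#' them. Because the chessboard metric quantizes distance (its unit balls
#' are squares, so a counterpart pair and a diagonal pair can differ by a
#' pixel either way after rasterization), admissible pairs within 2 px of
#' the current nearest are treated as tied and resolved toward the most
#' mutually facing pair. Without \code{directions} pairing is by distance
#' alone with lexicographic tie-breaks.
#'
#' @param points list of splitting points (pixel matrices).
#' @param directions optional list of direction vectors, one per point
#'   (need not be normalized; NA disables the filter for that point);
#'   \code{NULL} disables the counterpart-orientation logic entirely.
#' @return List with \code{pairs} (list of integer 2-vectors indexing
#'   \code{points}) and \code{leftover} (integer vector, possibly empty).
#' @export
pairPoints <- function(points, directions = NULL) {
  if (length(points) < 2L) stop("pairing needs at least two points")
  points <- lapply(points, function(p) .lexOrder(.asPixelMatrix(p)))
  # canonical order: by first pixel
  firsts <- t(vapply(points, function(p) p[1L, ], integer(2L)))
  ord <- order(firsts[, 1L], firsts[, 2L])
  n <- length(points)
  cents <- lapply(seq_len(n), function(i) colMeans(points[[ord[i]]]))
  dirOf <- function(i) {
    if (is.null(directions)) return(NULL)
    d <- directions[[ord[i]]]
    if (any(is.na(d))) NULL else d
  }
  D <- matrix(Inf, n, n)
  A <- matrix(-Inf, n, n)      # mutual-facing alignment score
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    di <- dirOf(i); dj <- dirOf(j)
    sep <- cents[[j]] - cents[[i]]
    nsep <- sqrt(sum(sep^2))
    score <- 0
    if (!is.null(di) && !is.null(dj)) {
      if (sum(di * dj) > 0) next              # same flank: inadmissible
      if (nsep > 0)
        score <- sum(di * sep) / nsep - sum(dj * sep) / nsep
    }
    D[i, j] <- .setChebyshev(points[[ord[i]]], points[[ord[j]]])
    A[i, j] <- score
  }
  used <- rep(FALSE, n)
  pairs <- list()
  repeat {
    D2 <- D; D2[used, ] <- Inf; D2[, used] <- Inf
    if (all(!is.finite(D2))) break
    tied <- which(D2 <= min(D2) + if (is.null(directions)) 0 else 2,
                  arr.ind = TRUE)
    sc <- A[tied]
    best <- tied[order(-sc, tied[, 1L], tied[, 2L]), , drop = FALSE][1L, ]
    pairs[[length(pairs) + 1L]] <- c(ord[best[1L]], ord[best[2L]])
    used[best] <- TRUE
  }
  list(pairs = pairs, leftover = ord[!used])
}

#' Route a lone splitting point to the cell contour
#'
#' Scenario for cells with a single concave region (or a leftover point
#' after pairing): the partner is a virtual point on the cell contour. The
#' candidate set is the cell's boundary minus every pixel within one
#' chessboard pixel of any arc (the contour shared with concave regions is
#' excluded); the partner is the candidate pixel(s) nearest to p, keeping
#' the 8-connected group of minimizers that contains the lexicographically
#' first one.
#'
#' When the direction of the concavity is known, candidates are further
#' restricted to the contour the concavity points toward (positive
#' projection onto \code{direction}); the imaginary splitting line runs
#' from the concave region into the cell body, never sideways along its
#' own arc. If the restriction empties the candidate set it is dropped.
#'
#' @param cellPixels pixel matrix of the cell.
#' @param point the splitting point (pixel matrix).
#' @param arcs list of arc pixel matrices of this cell's STs.
#' @param dim image dimensions.
#' @param direction optional unit vector: the direction the concavity at
#'   \code{point} indents into the cell.
#' @return Pixel matrix of the virtual partner point, or NULL (with a
#'   warning) if no candidate contour remains — the cell is unsplittable.
#' @export
contourFallback <- function(cellPixels, point, arcs, dim, direction = NULL) {
  cellPixels <- .asPixelMatrix(cellPixels)
  win <- .pixelWindow(cellPixels, dim, pad = 1L)
  bnd <- .innerBoundary8(win$m)
  excl <- matrix(FALSE, nrow(win$m), ncol(win$m))
  for (a in arcs) {
    a <- .asPixelMatrix(a)
    inw <- a[, 1L] >= win$r0 & a[, 1L] <= win$r0 + nrow(win$m) - 1L &
           a[, 2L] >= win$c0 & a[, 2L] <= win$c0 + ncol(win$m) - 1L
    a <- a[inw, , drop = FALSE]
    if (nrow(a))
      excl[cbind(a[, 1L] - win$r0 + 1L, a[, 2L] - win$c0 + 1L)] <- TRUE
  }
  cand <- bnd & !(excl | .dilate8(excl))
  if (!any(cand)) {
    warning("no contour candidates outside concave regions: cell unsplittable")
    return(NULL)
  }
  candPx <- .windowPixels(cand, win$r0, win$c0)
  if (!is.null(direction) && !any(is.na(direction))) {
    pc <- colMeans(.asPixelMatrix(point))
    dr <- candPx[, 1L] - pc[1L]; dc <- candPx[, 2L] - pc[2L]
    proj <- dr * direction[1L] + dc * direction[2L]
    cosang <- proj / pmax(sqrt(dr^2 + dc^2), 1e-9)
    # the splitting line runs into the concavity: prefer candidates nearly
    # dead-ahead of its direction, then a 90-degree cone, then any forward
    # candidate (the chessboard metric alone would happily run diagonally
    # along the cell instead of across the waist)
    keep <- cosang >= 0.9
    if (!any(keep)) keep <- cosang >= cos(pi / 4)
    if (!any(keep)) keep <- proj > 0
    if (any(keep)) candPx <- candPx[keep, , drop = FALSE]
  }
  d <- .chebyshevToSet(candPx, .asPixelMatrix(point))
  minim <- .lexOrder(candPx[d == min(d), , drop = FALSE])
  if (!is.null(direction) && !any(is.na(direction))) {
    # single best exit pixel: the nearest candidate most aligned with the
    # concavity direction (an endpoint at the fringe of a tied plateau can
    # leave foreground wrapping around the cut's end)
    pc <- colMeans(.asPixelMatrix(point))
    dr <- minim[, 1L] - pc[1L]; dc <- minim[, 2L] - pc[2L]
    cosang <- (dr * direction[1L] + dc * direction[2L]) /
              pmax(sqrt(dr^2 + dc^2), 1e-9)
    return(minim[which.max(cosang), , drop = FALSE])
  }
  # keep the 8-connected group containing the first minimizer
  mm <- .pixelWindow(minim, dim, pad = 0L)
  lab <- .label8(mm$m * 1L)
  g <- lab[minim[1L, 1L] - mm$r0 + 1L, minim[1L, 2L] - mm$c0 + 1L]
  idx <- which(lab == g, arr.ind = TRUE)
  .lexOrder(.asPixelMatrix(cbind(idx[, 1L] + mm$r0 - 1L, idx[, 2L] + mm$c0 - 1L)))
}

#' Geodesic corridor between two splitting points
#'
#' The set of pixels on which B_{p,v} = D_p + D_v attains its global
#' minimum: exactly the pixels x with d(p, x) + d(x, v) = d(p, v) under the
#' chessboard metric — every shortest route from p to v passes through this
#' corridor.
#'
#' @param p,v pixel matrices of the two (possibly multi-pixel) points.
#' @param dim image dimensions.
#' @param clipTo optional pixel matrix; if given, the corridor is
#'   intersected with it (interior clipping).
#' @return Pixel matrix of the corridor (includes p and v).
#' @export
shortestPathRegion <- function(p, v, dim, clipTo = NULL) {
  p <- .asPixelMatrix(p); v <- .asPixelMatrix(v)
  dpv <- .setChebyshev(p, v)
  all <- rbind(p, v)
  win <- .pixelWindow(all, dim, pad = dpv)
  h <- nrow(win$m); w <- ncol(win$m)
  R <- matrix(seq_len(h), h, w) + win$r0 - 1L
  C <- matrix(seq_len(w), h, w, byrow = TRUE) + win$c0 - 1L
  dP <- matrix(Inf, h, w); dV <- matrix(Inf, h, w)
  for (i in seq_len(nrow(p)))
    dP <- pmin(dP, pmax(abs(R - p[i, 1L]), abs(C - p[i, 2L])))
  for (i in seq_len(nrow(v)))
    dV <- pmin(dV, pmax(abs(R - v[i, 1L]), abs(C - v[i, 2L])))
  corr <- (dP + dV) == dpv
  px <- .windowPixels(corr, win$r0, win$c0)
  if (!is.null(clipTo)) {
    clipTo <- .asPixelMatrix(clipTo)
    keyp <- paste(px[, 1L], px[, 2L])
    keyc <- paste(clipTo[, 1L], clipTo[, 2L])
    px <- px[keyp %in% keyc, , drop = FALSE]
  }
  px
}
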