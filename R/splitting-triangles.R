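# Splitting triangles: the concave deficit regions of an overlapping cell.
#
# For an OC object with pixel region R and filled convex hull CH(R), the
# deficit CH(R) \ R decomposes into 8-connected components. Components at
# least minSTArea pixels large are the dominant concave regions — the
# splitting triangles (STs); smaller ones are contour-noise slivers and are
# discarded (but accounted for, so |CH| = |R| + sum|ST| + |slivers| exactly).
#
# Each ST's edge (its boundary) splits into the chord — the part tangent to
# the convex hull — and the arc, the remainder, which lies on the cell
# contour and carries the splitting point.

#' Extract the splitting triangles of one cell object
#'
#' @param pixels pixel matrix of the cell (one 8-connected component).
#' @param minSTArea minimum deficit-component area (px) kept as an ST.
#' @return List with elements \code{sts} (list of pixel matrices, one per
#'   kept ST, ordered deterministically), \code{sliverArea} (total area of
#'   discarded components) and \code{hullArea}.
#' @examples
#' clump <- makeTwoDiscClump(r = 10, dFactor = 1.4)
#' length(splittingTriangles(clump$pixels)$sts)   # 2: one per pinch side
#' @export
splittingTriangles <- function(pixels, minSTArea = 4) {
  pixels <- .asPixelMatrix(pixels)
  hull <- .hullPixels(pixels)
  # deficit = hull \ cell, in a window around the hull
  r0 <- min(hull[, 1L]); c0 <- min(hull[, 2L])
  h <- max(hull[, 1L]) - r0 + 1L; w <- max(hull[, 2L]) - c0 + 1L
  def <- matrix(0L, h, w)
  def[cbind(hull[, 1L] - r0 + 1L, hull[, 2L] - c0 + 1L)] <- 1L
  def[cbind(pixels[, 1L] - r0 + 1L, pixels[, 2L] - c0 + 1L)] <- 0L
  if (!any(def == 1L))
    return(list(sts = list(), sliverArea = 0L, hullArea = nrow(hull)))
  lab <- .label8(def)
  n <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= minSTArea)
  sts <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    .lexOrder(.asPixelMatrix(cbind(idx[, 1L] + r0 - 1L, idx[, 2L] + c0 - 1L)))
  })
  # deterministic ST order: by first pixel
  if (length(sts) > 1L) {
    firsts <- t(vapply(sts, function(p) p[1L, ], integer(2L)))
    sts <- sts[order(firsts[, 1L], firsts[, 2L])]
  }
  list(sts = sts, sliverArea = sum(sizes[sizes < minSTArea]),
       hullArea = nrow(hull))
}

#' Decompose a splitting triangle into edge, chord and arc
#'
#' The edge is the boundary of the ST region; the chord is the edge portion
#' tangent to the cell's convex hull (its exact intersection with the
#' hull's inner boundary: both live on the same pixel raster); the arc is
#' the rest of the edge and follows the cell contour.
#'
#' @param st pixel matrix of the ST region.
#' @param cellPixels pixel matrix of the owning cell.
#' @param dim image dimensions c(h, w).
#' @param edgeMethod \code{"boundary"} for the morphological inner boundary,
#'   \code{"gradient"} for a Sobel-magnitude edge; identical on binary
#'   regions.
#' @return List with pixel matrices \code{edge}, \code{chord}, \code{arc},
#'   or \code{NULL} (with a warning) when the decomposition degenerates
#'   (empty arc or chord: a sliver not worth splitting at).
#' @export
decomposeST <- function(st, cellPixels, dim, edgeMethod = "boundary") {
  st <- .asPixelMatrix(st)
  hull <- .hullPixels(.asPixelMatrix(cellPixels))
  win <- .pixelWindow(st, dim, pad = 2L)
  edgeM <- switch(edgeMethod,
    boundary = .innerBoundary8(win$m),
    gradient = .gradientEdge(win$m),
    stop("unknown edgeMethod: ", edgeMethod)
  )
  # hull boundary, restricted to (a padding of) the ST window
  hwin <- .pixelWindow(hull, dim, pad = 0L)
  hb <- .windowPixels(.innerBoundary8(hwin$m), hwin$r0, hwin$c0)
  hbWin <- hb[hb[, 1L] >= win$r0 & hb[, 1L] <= win$r0 + nrow(win$m) - 1L &
              hb[, 2L] >= win$c0 & hb[, 2L] <= win$c0 + ncol(win$m) - 1L, ,
              drop = FALSE]
  hbM <- matrix(FALSE, nrow(win$m), ncol(win$m))
  if (nrow(hbWin))
    hbM[cbind(hbWin[, 1L] - win$r0 + 1L, hbWin[, 2L] - win$c0 + 1L)] <- TRUE
  # tangency is exact: the ST and the filled hull live on the same raster,
  # so the chord is the edge's intersection with the hull's inner boundary
  chordM <- edgeM & hbM
  arcM <- edgeM & !chordM
  if (!any(arcM) || !any(chordM)) {
    warning("degenerate splitting triangle discarded (empty arc or chord)")
    return(NULL)
  }
  list(edge = .windowPixels(edgeM, win$r0, win$c0),
       chord = .windowPixels(chordM, win$r0, win$c0),
       arc = .windowPixels(arcM, win$r0, win$c0))
}

# Sobel gradient magnitude edge of a binary window; thresholded at > 0 it
# reproduces the region contour.
.gradientEdge <- function(m) {
  x <- m * 1
  gx <- .shiftMat(x, 0, -1) - .shiftMat(x, 0, 1) +
        0.5 * (.shiftMat(x, -1, -1) - .shiftMat(x, -1, 1) +
               .shiftMat(x, 1, -1) - .shiftMat(x, 1, 1))
  gy <- .shiftMat(x, -1, 0) - .shiftMat(x, 1, 0) +
        0.5 * (.shiftMat(x, -1, -1) - .shiftMat(x, 1, -1) +
               .shiftMat(x, -1, 1) - .shiftMat(x, 1, 1))
  (sqrt(gx^2 + gy^2) > 0) & m
}

#' Pool arcs and chords into image-wide label matrices
#'
#' Builds the EA/EC representation: two h x w integer matrices in which the
#' arc (EA) and chord (EC) pixels of overlapping cell j carry value j and
#' everything else is 0.
#'
#' @param decomposed list of decomposed STs; each element a list with
#'   \code{cellId}, \code{arc}, \code{chord}.
#' @param dim image dimensions c(h, w).
#' @return List with integer matrices \code{EA} and \code{EC}.
#' @export
buildLabelMatrices <- function(decomposed, dim) {
  EA <- matrix(0L, dim[1L], dim[2L])
  EC <- matrix(0L, dim[1L], dim[2L])
  for (d in decomposed) {
    stopifnot(all(EA[d$arc] %in% c(0L, d$cellId)))
    EA[d$arc] <- as.integer(d$cellId)
    EC[d$chord] <- as.integer(d$cellId)
  }
  list(EA = EA, EC = EC)
}
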