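# Pixel-set geometry: convex hulls, Feret diameters, concavity.
#
# All geometry is pixel-set arithmetic on integer pixel centres. The convex
# hull of an object is rasterized by keeping every pixel of the bounding box
# whose centre lies inside (or on) the convex polygon of the object's pixel
# centres; the inclusion test uses integer cross products and is exact, so
# the object's own pixels are always a subset of the hull raster.

# Hull vertices of a pixel set, in polygon order. Degenerate (collinear)
# sets return the chull() endpoints.
.hullVertices <- function(px) {
  px <- .asPixelMatrix(px)
  if (nrow(px) <= 2L) return(px)
  idx <- grDevices::chull(px[, 2L], px[, 1L])   # (x = col, y = row)
  px[idx, , drop = FALSE]
}

# Rasterize the filled convex hull of a pixel set: every pixel of the
# bounding box whose centre lies inside (or on) the convex polygon of the
# set's pixel centres. Cross products of integer coordinates make the
# inclusion test exact, so the object's pixels are always a subset.
.hullPixels <- function(px) {
  px <- .asPixelMatrix(px)
  v <- .hullVertices(px)
  if (nrow(v) <= 2L) return(unique(px))        # point or collinear segment
  nv <- nrow(v)
  r <- v[, 1L]; c <- v[, 2L]
  # polygon orientation via signed area (shoelace)
  area2 <- sum(r * c[c(2:nv, 1L)] - r[c(2:nv, 1L)] * c)
  orient <- if (area2 >= 0) 1 else -1
  rr <- min(r):max(r); cc <- min(c):max(c)
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  inside <- matrix(TRUE, length(rr), length(cc))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (r[j] - r[i]) * (C - c[i]) - (c[j] - c[i]) * (R - r[i])
    inside <- inside & (orient * cross >= 0)
  }
  .asPixelMatrix(cbind(R[inside], C[inside]))
}

# Maximum Feret diameter of a pixel set, measured between pixel centres on
# the hull, plus one pixel for the pixel footprint.
.maxFeret <- function(px) {
  v <- .hullVertices(px)
  if (nrow(v) == 1L) return(1)
  d2 <- outer(v[, 1L], v[, 1L], "-")^2 + outer(v[, 2L], v[, 2L], "-")^2
  sqrt(max(d2)) + 1
}

# Minimum Feret diameter (width): the smallest extent of the hull measured
# over the directions normal to the hull edges, plus one pixel.
.minFeret <- function(px) {
  v <- .hullVertices(px)
  if (nrow(v) <= 2L) return(1)                  # point or 1-px-wide segment
  nv <- nrow(v)
  widths <- vapply(seq_len(nv), function(i) {
    j <- if (i == nv) 1L else i + 1L
    e <- v[j, ] - v[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    # distance of every vertex from the line through edge i-j
    max(abs((v[, 1L] - v[i, 1L]) * e[2L] - (v[, 2L] - v[i, 2L]) * e[1L]) / len)
  }, numeric(1L))
  min(widths) + 1
}

#' Diameter equality of a cell object
#'
#' Ratio of the minor to the major diameter of a pixel set. The major
#' diameter is the longest straight line inside the object (maximum Feret
#' diameter of its pixel set); the minor diameter is the object width, the
#' minimum Feret diameter. Round single cells score close to 1; elongated
#' clumps score low.
#'
#' @param pixels integer matrix of (row, col) pixel coordinates.
#' @return Ratio in (0, 1]. A single-pixel object returns 1 with a warning.
#' @examples
#' disc <- discPixels(c(30, 30), 20)
#' diameterEquality(disc)   # ~1 for a disc
#' @export
diameterEquality <- function(pixels) {
  pixels <- .asPixelMatrix(pixels)
  if (nrow(pixels) == 1L) {
    warning("single-pixel object: diameter equality defined as 1")
    return(1)
  }
  maj <- .maxFeret(pixels)
  mnr <- .minFeret(pixels)
  min(mnr / maj, 1)
}

#' Concavity of a cell object
#'
#' Normalized convex-hull deficit: \code{(A_CH - A) / A_CH}, where
#' \code{A} is the object area (pixel count) and \code{A_CH} the area of its
#' filled convex hull. Zero for convex objects (up to hull rasterization);
#' grows as concave pinches between overlapped cells deepen.
#'
#' @param pixels integer matrix of (row, col) pixel coordinates.
#' @return Concavity in [0, 1).
#' @examples
#' sq <- as.matrix(expand.grid(row = 1:10, col = 1:10))
#' concavity(sq)   # 0: a square is its own hull
#' @export
concavity <- function(pixels) {
  pixels <- .asPixelMatrix(pixels)
  if (nrow(pixels) == 0L) stop("empty object has no concavity")
  a <- nrow(unique(pixels))
  ach <- nrow(.hullPixels(pixels))
  (ach - a) / ach
}

#' Rasterize a disc
#'
#' Pixels whose centres lie within \code{radius} of \code{center}.
#'
#' @param center numeric (row, col) centre.
#' @param radius radius in pixels.
#' @return Pixel matrix (row, col).
#' @export
discPixels <- function(center, radius) {
  rr <- floor(center[1L] - radius):ceiling(center[1L] + radius)
  cc <- floor(center[2L] - radius):ceiling(center[2L] + radius)
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - center[1L])^2 + (g$col - center[2L])^2 <= radius^2
  .asPixelMatrix(as.matrix(g[keep, ]))
}

# Rasterize an ellipse with semi-axes a >= b and orientation theta (radians).
.ellipsePixels <- function(center, a, b, theta = 0) {
  m <- ceiling(max(a, b))
  rr <- floor(center[1L] - m):ceiling(center[1L] + m)
  cc <- floor(center[2L] - m):ceiling(center[2L] + m)
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - center[1L]; dc <- g$col - center[2L]
  u <- dc * cos(theta) + dr * sin(theta)
  w <- -dc * sin(theta) + dr * cos(theta)
  keep <- (u / a)^2 + (w / b)^2 <= 1
  .asPixelMatrix(as.matrix(g[keep, ]))
}
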