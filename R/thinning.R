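# Two-subiteration thinning of shortest-path corridors.
#
# The corridor between two splitting points is shrunk to a single-pixel
# route with the two-subcycle parallel thinning operator of Guo & Hall
# (1989). Neighbours x1..x8 are taken starting at the east neighbour and
# continuing counter-clockwise. A pixel is deleted when
#   C1: the crossing number C(x) = sum_k [ !x(2k-1) & (x(2k) | x(2k+1)) ]
#       equals 1 (deletion preserves local connectivity),
#   C2: 2 <= min(N1, N2) <= 3 with N1/N2 the paired neighbour counts
#       (endpoints, with a single neighbour, are never deleted: the
#       operator erodes width, not length), and
#   C3: (x2 | x3 | !x8) & x1 == 0   in odd subcycles,
#   C4: (x6 | x7 | !x4) & x5 == 0   in even subcycles.
# The two endpoints of the route are additionally protected so the thinned
# path always runs from one splitting point to the other.

# One logical matrix per neighbour, in the e, ne, n, nw, w, sw, s, se order.
.neighbours8 <- function(m) {
  lapply(seq_len(nrow(.NB8)), function(k)
    .shiftMat(m, .NB8[k, 1L], .NB8[k, 2L], FALSE))
}

# Guo-Hall thinning of a logical window matrix; `protect` is a logical
# matrix of pixels that are never removed.
.guoHallThin <- function(m, protect = NULL) {
  if (is.null(protect)) protect <- matrix(FALSE, nrow(m), ncol(m))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- .neighbours8(m)
      x1 <- nb[[1]]; x2 <- nb[[2]]; x3 <- nb[[3]]; x4 <- nb[[4]]
      x5 <- nb[[5]]; x6 <- nb[[6]]; x7 <- nb[[7]]; x8 <- nb[[8]]
      C <- (!x1 & (x2 | x3)) + (!x3 & (x4 | x5)) +
           (!x5 & (x6 | x7)) + (!x7 & (x8 | x1))
      N1 <- (x1 | x2) + (x3 | x4) + (x5 | x6) + (x7 | x8)
      N2 <- (x2 | x3) + (x4 | x5) + (x6 | x7) + (x8 | x1)
      N <- pmin(N1, N2)
      E <- if (sub == 1L) (x2 | x3 | !x8) & x1 else (x6 | x7 | !x4) & x5
      del <- m & !protect & (C == 1) & (N >= 2) & (N <= 3) & !E
      if (any(del)) { m <- m & !del; changed <- TRUE }
    }
    if (!changed) return(m)
  }
}

#' Thin a corridor to a one-pixel cut path
#'
#' Reduces the geodesic corridor between two splitting points to a single
#' 1-pixel-wide route: Guo-Hall thinning erodes the corridor width while
#' the protected endpoints anchor its length, and the route is then read
#' off as the shortest path through the thinned set (dropping any residual
#' redundant pixels, so interior pixels have exactly two path neighbours).
#'
#' @param corridor pixel matrix from \code{\link{shortestPathRegion}}.
#' @param p,v the paired splitting points (pixel matrices).
#' @param dim image dimensions.
#' @return Ordered pixel matrix of the cut path, from p's representative
#'   pixel to v's.
#' @export
thinToPath <- function(corridor, p, v, dim) {
  corridor <- .asPixelMatrix(corridor)
  p <- .lexOrder(.asPixelMatrix(p)); v <- .lexOrder(.asPixelMatrix(v))
  win <- .pixelWindow(corridor, dim, pad = 1L)
  toWin <- function(px) cbind(px[, 1L] - win$r0 + 1L, px[, 2L] - win$c0 + 1L)
  # representative endpoints: first corridor pixel of each point set
  keyc <- paste(corridor[, 1L], corridor[, 2L])
  repOf <- function(pt) {
    hit <- which(paste(pt[, 1L], pt[, 2L]) %in% keyc)
    if (!length(hit)) stop("splitting point does not touch its corridor")
    pt[hit[1L], ]
  }
  rp <- repOf(p); rv <- repOf(v)
  protect <- matrix(FALSE, nrow(win$m), ncol(win$m))
  protect[rbind(toWin(matrix(rp, 1L)), toWin(matrix(rv, 1L)))] <- TRUE
  thin <- .guoHallThin(win$m, protect)
  path <- .bfsPath(thin, toWin(matrix(rp, 1L))[1L, ], toWin(matrix(rv, 1L))[1L, ])
  if (is.null(path))   # thinning should not disconnect; corridor as backstop
    path <- .bfsPath(win$m, toWin(matrix(rp, 1L))[1L, ], toWin(matrix(rv, 1L))[1L, ])
  if (is.null(path))
    stop("corridor between splitting points is disconnected")
  path <- .straightenPath(path)
  .asPixelMatrix(cbind(path[, 1L] + win$r0 - 1L, path[, 2L] + win$c0 - 1L))
}
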