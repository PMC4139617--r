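# Mask preprocessing and component labelling.

#' Clean a binary mask
#'
#' Applies the preprocessing chain used before any morphological analysis:
#' region (hole) filling, then opening, then closing, each with a disc
#' structuring element. The opening removes small noisy artifacts (with the
#' default radius 2, anything smaller than the structuring element,
#' including isolated pixels); the filling removes interior holes. The
#' closing defaults to the smallest nontrivial element (radius 1): it
#' repairs single-pixel contour defects without filling in the shallow
#' concave pinches between overlapped cells that the splitting stage
#' depends on.
#'
#' @param mask binary matrix (0/1).
#' @param openRadius radius of the disc element for the opening (default 2).
#' @param closeRadius radius of the disc element for the closing
#'   (default 1).
#' @return Cleaned binary mask of the same dimensions.
#' @examples
#' m <- maskFromPixels(discPixels(c(15, 15), 8), c(30, 30))
#' m[15, 15] <- 0L                  # poke a hole
#' sum(cleanMask(m) != maskFromPixels(discPixels(c(15, 15), 8), c(30, 30)))
#' @export
cleanMask <- function(mask, openRadius = 2, closeRadius = 1) {
  .checkBinary(mask)
  kern <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  m <- EBImage::fillHull(mask)
  m <- EBImage::opening(m, kern(openRadius))
  m <- EBImage::closing(m, kern(closeRadius))
  matrix(as.integer(m != 0), nrow(mask), ncol(mask))
}

#' Build a mask from a pixel set
#'
#' @param pixels integer matrix of (row, col) pixels.
#' @param dim image dimensions c(h, w).
#' @return Binary matrix with those pixels set to 1.
#' @export
maskFromPixels <- function(pixels, dim) {
  m <- matrix(0L, dim[1L], dim[2L])
  if (length(pixels)) {
    pixels <- .asPixelMatrix(pixels)
    keep <- pixels[, 1L] >= 1L & pixels[, 1L] <= dim[1L] &
            pixels[, 2L] >= 1L & pixels[, 2L] <= dim[2L]
    m[pixels[keep, , drop = FALSE]] <- 1L
  }
  m
}

#' Label the cell objects of a mask
#'
#' Extracts every 8-connected foreground component as one cell object and
#' computes its morphology: area (pixel count), filled convex-hull area,
#' diameter equality and concavity. Stage-1 labels are \code{NA} until
#' \code{\link{assignLabels}} is applied.
#'
#' @param mask cleaned binary mask.
#' @return A \linkS4class{SegmentedCells} object.
#' @seealso [assignLabels()], [cleanMask()]
#' @export
labelComponents <- function(mask) {
  .checkBinary(mask)
  lab <- .label8(mask)
  n <- max(lab)
  feats <- S4Vectors::DataFrame(
    id = integer(0), area = integer(0), hullArea = integer(0),
    de = numeric(0), cx = numeric(0), label = character(0)
  )
  if (n > 0L) {
    area <- tabulate(lab[lab > 0L], nbins = n)
    hullArea <- integer(n); de <- numeric(n)
    ord <- order(lab[lab > 0L])
    pxAll <- which(lab > 0L, arr.ind = TRUE)[ord, , drop = FALSE]
    ends <- cumsum(area); starts <- c(1L, head(ends, -1L) + 1L)
    for (i in seq_len(n)) {
      px <- .asPixelMatrix(pxAll[starts[i]:ends[i], , drop = FALSE])
      hullArea[i] <- nrow(.hullPixels(px))
      de[i] <- if (nrow(px) == 1L) 1 else diameterEquality(px)
    }
    feats <- S4Vectors::DataFrame(
      id = seq_len(n), area = area, hullArea = hullArea, de = de,
      cx = (hullArea - area) / hullArea, label = rep(NA_character_, n)
    )
  }
  new("SegmentedCells", mask = matrix(as.integer(mask), nrow(mask), ncol(mask)),
      labels = lab, features = feats)
}

#' Pixels of one labelled object
#'
#' @param cells a \linkS4class{SegmentedCells}.
#' @param id object id (1..N).
#' @return Integer (row, col) pixel matrix.
#' @export
objectPixels <- function(cells, id) {
  .asPixelMatrix(which(cells@labels == id, arr.ind = TRUE))
}
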