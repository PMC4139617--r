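# Reading and writing binary masks. File handling is delegated to
# EBImage::readImage/writeImage (PNG, TIFF, JPEG).

#' Read a binary mask from an image file
#'
#' Any nonzero pixel (in any channel) is foreground. Grayscale, RGB and
#' paletted images are accepted; depth is irrelevant.
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @return Integer matrix of 0/1, rows indexing image rows top to bottom.
#' @seealso [writeMask()], [cleanMask()]
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read mask '", path, "': ",
                                           conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1L, 2L), max)
  if (any(dim(dat) < 1L) || length(dat) == 0L)
    stop("image '", path, "' has empty dimensions")
  # EBImage stores images as (x, y): transpose to (row, col)
  m <- t(dat)
  matrix(as.integer(m != 0), nrow(m), ncol(m))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0, so the round trip
#' \code{readMask(writeMask(m))} is bit-exact.
#'
#' @param mask integer matrix of 0/1.
#' @param path output path (extension selects the format; PNG recommended).
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  .checkBinary(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path)
  invisible(path)
}

.checkBinary <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (values 0/1)")
  invisible(TRUE)
}

#' Threshold an H&E image to a nuclear foreground mask
#'
#' A deliberately simple pluggable binarizer for RGB images of
#' hematoxylin-stained tissue: nuclei are dark, so foreground is every
#' pixel whose luminance falls below a threshold (Otsu's threshold on the
#' luminance histogram by default). It is a convenience entry point, not a
#' replacement for a dedicated tissue segmentation.
#'
#' @param img an EBImage \code{Image} or numeric array in [0,1]
#'   (h x w or h x w x 3).
#' @param threshold luminance cutoff in (0,1); \code{NULL} picks Otsu's.
#' @return Binary mask matrix (row, col).
#' @export
binarizeHE <- function(img, threshold = NULL) {
  isImage <- methods::is(img, "Image")
  dat <- if (isImage) EBImage::imageData(img) else img
  if (length(dim(dat)) == 3L)
    dat <- 0.299 * dat[, , 1L] + 0.587 * dat[, , 2L] + 0.114 * dat[, , 3L]
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(dat))
  fg <- dat < threshold
  if (isImage) fg <- t(fg)   # EBImage stores (x, y)
  matrix(as.integer(fg), nrow(fg), ncol(fg))
}
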