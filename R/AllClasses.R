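#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Parameters of the clump-splitting pipeline
#'
#' Holds every tunable of the two-stage algorithm. Defaults are the values
#' the method was designed around: \code{gamma = 0.9} for the diameter
#' equality threshold and structuring-element radius 2 for the opening;
#' the closing defaults to radius 1 so it cannot erase the shallow concave
#' pinches the splitting stage detects.
#'
#' @slot gamma diameter-equality threshold in (0, 1]; objects rounder than
#'   this are relabelled single cells.
#' @slot openRadius radius (px) of the disc structuring element for opening.
#' @slot closeRadius radius (px) of the disc element for closing.
#' @slot minSTArea minimum area (px) for a concave deficit region to count
#'   as a splitting triangle; smaller deficits are contour noise.
#' @slot edgeMethod \code{"boundary"} (morphological inner boundary) or
#'   \code{"gradient"} (Sobel magnitude); identical on binary regions.
#' @slot pairing \code{"greedy"} nearest-first matching of splitting points.
#' @slot clipCorridor if TRUE, shortest-path corridors are intersected with
#'   the cell foreground before thinning.
#' @slot globalFields if TRUE, seed-growing distance fields are built on the
#'   full image grid from the pooled arc/chord label matrices instead of
#'   per splitting triangle.
#' @slot iouThreshold intersection-over-union needed to accept a predicted
#'   cell as matching a ground-truth cell.
#' @export
setClass("SplitParams",
  representation(
    gamma = "numeric",
    openRadius = "numeric",
    closeRadius = "numeric",
    minSTArea = "numeric",
    edgeMethod = "character",
    pairing = "character",
    clipCorridor = "logical",
    globalFields = "logical",
    iouThreshold = "numeric"
  ),
  prototype(
    gamma = 0.9, openRadius = 2, closeRadius = 1, minSTArea = 4,
    edgeMethod = "boundary", pairing = "greedy", clipCorridor = FALSE,
    globalFields = FALSE, iouThreshold = 0.5
  )
)

setValidity("SplitParams", function(object) {
  msg <- NULL
  if (object@gamma <= 0 || object@gamma > 1)
    msg <- c(msg, "gamma must be in (0, 1]")
  if (object@openRadius <= 0 || object@closeRadius <= 0)
    msg <- c(msg, "structuring element radii must be positive")
  if (object@minSTArea <= 0)
    msg <- c(msg, "minSTArea must be positive")
  if (!object@edgeMethod %in% c("boundary", "gradient"))
    msg <- c(msg, "edgeMethod must be 'boundary' or 'gradient'")
  if (object@iouThreshold <= 0 || object@iouThreshold > 1)
    msg <- c(msg, "iouThreshold must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct pipeline parameters
#'
#' @param gamma,openRadius,closeRadius,minSTArea,edgeMethod,pairing,clipCorridor,globalFields,iouThreshold
#'   see the slot documentation of \linkS4class{SplitParams}.
#' @return A \linkS4class{SplitParams} object.
#' @examples
#' SplitParams()
#' SplitParams(gamma = 0.85, minSTArea = 15)
#' @export
SplitParams <- function(gamma = 0.9, openRadius = 2, closeRadius = 1,
                        minSTArea = 4, edgeMethod = "boundary",
                        pairing = "greedy", clipCorridor = FALSE,
                        globalFields = FALSE, iouThreshold = 0.5) {
  new("SplitParams", gamma = gamma, openRadius = openRadius,
      closeRadius = closeRadius, minSTArea = minSTArea,
      edgeMethod = edgeMethod, pairing = pairing,
      clipCorridor = clipCorridor, globalFields = globalFields,
      iouThreshold = iouThreshold)
}

#' Segmented cell objects of one image
#'
#' The labelled view of a binary mask: an 8-connected component label
#' matrix plus per-object morphology (area, convex-hull area, diameter
#' equality, concavity) and, once \code{\link{assignLabels}} has run, the
#' stage-1 class of each object (PS, PO, SC or OC).
#'
#' @slot mask the cleaned binary mask (integer matrix of 0/1).
#' @slot labels integer label matrix; 0 is background, objects are 1..N.
#' @slot features \code{DataFrame} with one row per object: \code{id},
#'   \code{area}, \code{hullArea}, \code{de}, \code{cx}, \code{label}.
#' @export
setClass("SegmentedCells",
  representation(mask = "matrix", labels = "matrix", features = "DataFrame")
)

setValidity("SegmentedCells", function(object) {
  msg <- NULL
  if (!all(object@mask %in% c(0L, 1L)))
    msg <- c(msg, "mask must be binary 0/1")
  if (!identical(dim(object@mask), dim(object@labels)))
    msg <- c(msg, "mask and labels must have identical dimensions")
  n <- if (length(object@labels)) max(object@labels) else 0L
  if (nrow(object@features) != n)
    msg <- c(msg, "features must have one row per label")
  if (is.null(msg)) TRUE else msg
})

#' Result of splitting the overlapping cells of one image
#'
#' @slot mask binary mask after the cut paths have been cleared.
#' @slot paths list of cut paths; each an integer (row, col) matrix ordered
#'   from one splitting point to its partner.
#' @slot cells the \linkS4class{SegmentedCells} the cuts were derived from.
#' @slot perObject \code{DataFrame}: per stage-1 object, its label, number
#'   of cuts and the number of fragments it contributes to the count.
#' @slot count total cell count: single (non-OC) objects plus post-cut
#'   fragments of OC objects.
#' @export
setClass("SplitResult",
  representation(mask = "matrix", paths = "list", cells = "SegmentedCells",
                 perObject = "DataFrame", count = "integer")
)

#' Cell-counting agreement report
#'
#' True/false positives and negatives of a predicted segmentation against
#' ground truth, with precision, recall and F-measure as percentages.
#'
#' @slot tp,fp,fn integer counts.
#' @slot precision,recall,fmeasure percentages in [0, 100].
#' @export
setClass("CountReport",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 precision = "numeric", recall = "numeric",
                 fmeasure = "numeric")
)

setValidity("CountReport", function(object) {
  v <- c(object@precision, object@recall, object@fmeasure)
  if (any(v < 0 | v > 100)) "metrics must be percentages in [0, 100]" else TRUE
})
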