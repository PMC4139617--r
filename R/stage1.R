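# Stage 1: discriminating overlapping clumps from single cells.
#
# Three sequential morphological rules label each object:
#   1. area:      A_i > mean(A)        -> PO (potentially overlapping),
#                 otherwise            -> PS (potentially single);
#   2. roundness: PO objects with diameter equality DE_i > gamma -> SC
#                 (single cell);
#   3. concavity: surviving PO objects with CX_i > mean(CX)      -> OC
#                 (overlapping cell).
# Objects still labelled PO after rule 3 (large, non-round, but not
# unusually concave) are treated as single for counting and left with the
# PO label so they can be audited.
#
# All inequalities are strict, so ties fall on the non-overlapping side:
# under-splitting one clump is preferred to over-segmenting a single cell.

#' Assign stage-1 labels (PS / PO / SC / OC) to segmented objects
#'
#' @param cells a \linkS4class{SegmentedCells} from
#'   \code{\link{labelComponents}}.
#' @param params a \linkS4class{SplitParams}; \code{gamma} is the diameter
#'   equality threshold (default 0.9).
#' @return The \code{SegmentedCells} with the \code{label} feature filled.
#'   Objects labelled \code{OC} are the overlapping set passed to stage 2.
#' @examples
#' sc <- labelComponents(maskFromPixels(discPixels(c(20, 20), 8), c(40, 40)))
#' stage1Labels(assignLabels(sc))   # a lone object is PS by definition
#' @export
assignLabels <- function(cells, params = SplitParams()) {
  f <- cells@features
  if (nrow(f) == 0L) return(cells)
  meanArea <- mean(f$area)
  meanCx <- mean(f$cx)
  lab <- ifelse(f$area > meanArea, "PO", "PS")
  lab[lab == "PO" & f$de > params@gamma] <- "SC"
  lab[lab == "PO" & f$cx > meanCx] <- "OC"
  cells@features$label <- lab
  cells
}

#' Image-level morphology statistics
#'
#' @param cells a \linkS4class{SegmentedCells}.
#' @return List with \code{meanArea} and \code{meanConcavity}, the averages
#'   over all objects in the image used by the stage-1 rules.
#' @export
imageStats <- function(cells) {
  f <- cells@features
  list(meanArea = if (nrow(f)) mean(f$area) else NA_real_,
       meanConcavity = if (nrow(f)) mean(f$cx) else NA_real_)
}

#' Binary mask of the overlapping (OC) objects
#'
#' @param cells labelled \linkS4class{SegmentedCells}.
#' @return Binary matrix whose foreground is the union of the pixels of all
#'   OC-labelled objects.
#' @export
overlappingMask <- function(cells) {
  f <- cells@features
  oc <- f$id[!is.na(f$label) & f$label == "OC"]
  m <- matrix(0L, nrow(cells@mask), ncol(cells@mask))
  if (length(oc)) m[cells@labels %in% oc] <- 1L
  m
}

#' Write the per-image stage-1 feature report
#'
#' @param cells labelled \linkS4class{SegmentedCells}.
#' @param path CSV output path.
#' @return The path, invisibly.
#' @export
writeStage1Report <- function(cells, path) {
  utils::write.csv(as.data.frame(cells@features), path, row.names = FALSE)
  invisible(path)
}
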