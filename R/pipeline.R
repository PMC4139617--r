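# End-to-end pipeline: preprocess -> stage 1 -> stage 2 -> count
# (-> evaluate when ground truth is available).

#' Run the full counting pipeline on one or more masks
#'
#' Each input is cleaned, labelled, stage-1 classified, split and counted.
#' When ground truth is supplied, predicted cells are matched against it
#' and precision/recall/F-measure are reported per image.
#'
#' @param inputs a list whose elements are either file paths (PNG/TIFF/JPEG
#'   masks), binary matrices, or scene lists from \code{\link{makeScene}}
#'   (their ground truth is used automatically); a single path/matrix/scene
#'   is also accepted.
#' @param params a \linkS4class{SplitParams}.
#' @param truth optional list of ground-truth cell lists (one per input;
#'   each a list of pixel matrices) for inputs that do not carry their own.
#' @param split if FALSE, stage 2 is skipped and counts are raw component
#'   counts (ablation mode).
#' @param outputDir if given, a per-image CSV (\code{counts.csv}), stage-1
#'   feature reports and cut overlays are written there.
#' @return A data.frame with one row per image: object counts per stage,
#'   predicted and true counts, TP/FP/FN and the three metrics (NA without
#'   truth). The per-image \linkS4class{SplitResult}s are attached as
#'   attribute \code{"results"}.
#' @examples
#' scn <- makeScene(shape = c(160, 160), nSingle = 3, nClump = 1, seed = 11)
#' runCount(scn)
#' @export
runCount <- function(inputs, params = SplitParams(), truth = NULL,
                     split = TRUE, outputDir = NULL) {
  if (is.character(inputs)) inputs <- as.list(inputs)
  else if (!is.list(inputs) || is.matrix(inputs) || !is.null(inputs$mask))
    inputs <- list(inputs)
  if (!is.null(outputDir) && !dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  rows <- list(); results <- list()
  for (i in seq_along(inputs)) {
    inp <- inputs[[i]]
    name <- sprintf("image%03d", i)
    tru <- if (!is.null(truth)) truth[[i]] else NULL
    if (is.character(inp)) {
      name <- basename(inp)
      mask <- readMask(inp)
    } else if (is.matrix(inp)) {
      mask <- inp
    } else if (is.list(inp) && !is.null(inp$mask)) {
      mask <- inp$mask
      if (is.null(tru) && !is.null(inp$truth)) tru <- inp$truth$cells
    } else stop("unrecognized input ", i)
    cleaned <- cleanMask(mask, params@openRadius, params@closeRadius)
    cells <- assignLabels(labelComponents(cleaned), params)
    f <- cells@features
    if (split) {
      res <- splitCells(cells, params)
    } else {
      res <- new("SplitResult", mask = cleaned, paths = list(), cells = cells,
                 perObject = S4Vectors::DataFrame(
                   id = f$id, label = f$label,
                   nCuts = integer(nrow(f)), fragments = rep(1L, nrow(f)),
                   unsplittable = logical(nrow(f))),
                 count = nrow(f))
    }
    results[[i]] <- res
    nOC <- sum(f$label == "OC", na.rm = TRUE)
    rep0 <- NULL
    if (!is.null(tru))
      rep0 <- evaluateCounts(predictedCells(res), tru, params@iouThreshold)
    rows[[i]] <- data.frame(
      image = name,
      n_objects = nrow(f),
      n_single = nrow(f) - nOC,
      n_clumps = nOC,
      n_cuts = length(res@paths),
      count_pred = res@count,
      count_true = if (!is.null(tru)) length(tru) else NA_integer_,
      TP = if (!is.null(rep0)) rep0@tp else NA_integer_,
      FP = if (!is.null(rep0)) rep0@fp else NA_integer_,
      FN = if (!is.null(rep0)) rep0@fn else NA_integer_,
      precision = if (!is.null(rep0)) rep0@precision else NA_real_,
      recall = if (!is.null(rep0)) rep0@recall else NA_real_,
      fmeasure = if (!is.null(rep0)) rep0@fmeasure else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(outputDir)) {
      writeStage1Report(cells, file.path(outputDir, paste0(name, "_stage1.csv")))
      writeOverlay(res, file.path(outputDir, paste0(name, "_overlay.png")))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(outputDir))
    utils::write.csv(out, file.path(outputDir, "counts.csv"), row.names = FALSE)
  attr(out, "results") <- results
  out
}

#' Paint a split overlay PNG
#'
#' Foreground in gray, cut paths in red, OC objects outlined in yellow.
#'
#' @param result a \linkS4class{SplitResult}.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
writeOverlay <- function(result, path) {
  mask <- result@cells@mask
  h <- nrow(mask); w <- ncol(mask)
  rch <- gch <- bch <- matrix(0, h, w)
  rch[mask == 1L] <- gch[mask == 1L] <- bch[mask == 1L] <- 0.7
  oc <- overlappingMask(result@cells)
  if (any(oc == 1L)) {
    ob <- .innerBoundary8(oc == 1L)
    rch[ob] <- 1; gch[ob] <- 0.9; bch[ob] <- 0.1
  }
  for (p in result@paths) {
    rch[p] <- 1; gch[p] <- 0.1; bch[p] <- 0.1
  }
  arr <- array(0, c(w, h, 3L))
  arr[, , 1L] <- t(rch); arr[, , 2L] <- t(gch); arr[, , 3L] <- t(bch)
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}
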