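#' @rdname SegmentedCells-class
#' @param object,x a \linkS4class{SegmentedCells}, \linkS4class{SplitResult}
#'   or \linkS4class{CountReport}.
#' @export
setGeneric("maskOf", function(x) standardGeneric("maskOf"))

#' @rdname SegmentedCells-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname SegmentedCells-class
#' @export
setGeneric("objectFeatures", function(x) standardGeneric("objectFeatures"))

#' @rdname SegmentedCells-class
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname SegmentedCells-class
#' @export
setGeneric("stage1Labels", function(x) standardGeneric("stage1Labels"))

#' @rdname SplitResult-class
#' @export
setGeneric("cutPaths", function(x) standardGeneric("cutPaths"))

#' @rdname SplitResult-class
#' @export
setGeneric("cellCount", function(x) standardGeneric("cellCount"))

#' @rdname SegmentedCells-class
#' @export
setMethod("maskOf", "SegmentedCells", function(x) x@mask)

#' @rdname SplitResult-class
#' @export
setMethod("maskOf", "SplitResult", function(x) x@mask)

#' @rdname SegmentedCells-class
#' @export
setMethod("labelMatrix", "SegmentedCells", function(x) x@labels)

#' @rdname SegmentedCells-class
#' @export
setMethod("objectFeatures", "SegmentedCells", function(x) x@features)

#' @rdname SegmentedCells-class
#' @export
setMethod("nObjects", "SegmentedCells", function(x) nrow(x@features))

#' @rdname SegmentedCells-class
#' @export
setMethod("stage1Labels", "SegmentedCells", function(x) x@features$label)

#' @rdname SplitResult-class
#' @export
setMethod("cutPaths", "SplitResult", function(x) x@paths)

#' @rdname SplitResult-class
#' @export
setMethod("cellCount", "SplitResult", function(x) x@count)

#' @rdname SegmentedCells-class
#' @export
setMethod("show", "SegmentedCells", function(object) {
  f <- object@features
  cat("SegmentedCells:", nrow(f), "objects on a",
      paste(dim(object@mask), collapse = " x "), "mask\n")
  if (nrow(f) && !all(is.na(f$label)))
    print(table(stage1 = f$label))
  invisible(NULL)
})

#' @rdname SplitResult-class
#' @export
setMethod("show", "SplitResult", function(object) {
  cat("SplitResult:", length(object@paths), "cuts,", object@count,
      "cells counted\n")
  invisible(NULL)
})

#' @rdname CountReport-class
#' @export
setMethod("show", "CountReport", function(object) {
  cat(sprintf("CountReport: TP=%d FP=%d FN=%d | P=%.2f%% R=%.2f%% F=%.2f%%\n",
              object@tp, object@fp, object@fn,
              object@precision, object@recall, object@fmeasure))
  invisible(NULL)
})
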