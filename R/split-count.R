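# Stage 2 driver: split every overlapping cell and count.

#' Split the overlapping cells of a labelled image
#'
#' For each OC-labelled object: extract its splitting triangles, decompose
#' each into arc and chord, locate the critical splitting point of each
#' arc, pair nearest points (routing a lone or leftover point to the cell
#' contour), thin the geodesic corridor of every pair to a one-pixel cut
#' path, and clear the cuts from the mask. Cells whose concave regions all
#' degenerate are left uncut and counted as one (and flagged in the
#' per-object table).
#'
#' @param cells labelled \linkS4class{SegmentedCells}
#'   (\code{\link{assignLabels}} must have run).
#' @param params a \linkS4class{SplitParams}.
#' @return A \linkS4class{SplitResult}.
#' @examples
#' scn <- makeScene(shape = c(128, 128), nSingle = 2, nClump = 1, seed = 7)
#' sc <- assignLabels(labelComponents(cleanMask(scn$mask)))
#' res <- splitCells(sc)
#' cellCount(res)
#' @export
splitCells <- function(cells, params = SplitParams()) {
  f <- cells@features
  dim <- dim(cells@mask)
  ocIds <- f$id[!is.na(f$label) & f$label == "OC"]
  allPaths <- list()
  nCuts <- integer(nrow(f))
  flagged <- logical(nrow(f))
  for (j in ocIds) {
    px <- objectPixels(cells, j)
    stInfo <- splittingTriangles(px, params@minSTArea)
    dec <- list()
    for (st in stInfo$sts) {
      d <- decomposeST(st, px, dim, params@edgeMethod)
      if (!is.null(d)) { d$cellId <- j; dec[[length(dec) + 1L]] <- d }
    }
    if (!length(dec)) { flagged[j] <- TRUE; next }
    arcs <- lapply(dec, `[[`, "arc")
    # one initial splitting point per persistent peak of each arc's
    # chord-distance profile; a single-peak arc gives exactly the
    # criticalPoint() argmax set
    objM <- cells@labels == j
    pts <- list(); dirs <- list(); ownArc <- list()
    for (k in seq_along(dec)) {
      arc <- dec[[k]]$arc; chord <- dec[[k]]$chord
      dv <- .chebyshevToSet(arc, chord)
      for (grp in .arcPeaks(arc, dv)) {
        loc <- .localGeometry(objM, colMeans(grp))
        # a genuine splitting point sits in a concave indentation: the
        # cell wraps around it, so foreground dominates its neighbourhood;
        # peaks on convex bumps of a merged ST's arc are not concavities
        if (loc$fgFraction < 0.5) next
        pts[[length(pts) + 1L]] <- grp
        dirs[[length(dirs) + 1L]] <- loc$normal
        ownArc[[length(ownArc) + 1L]] <- arc
      }
    }
    if (!length(pts)) { flagged[j] <- TRUE; next }
    pairs <- list()
    leftover <- integer(0)
    if (length(pts) >= 2L) {
      pp <- pairPoints(pts, dirs)
      pairs <- lapply(pp$pairs, function(ij) list(p = pts[[ij[1L]]],
                                                  v = pts[[ij[2L]]]))
      leftover <- pp$leftover
    } else {
      leftover <- 1L
    }
    for (lo in leftover) {
      # exclusion covers only the concave region the point itself sits on:
      # the partner may legitimately lie in a counterpart concave region
      vp <- contourFallback(px, pts[[lo]], ownArc[lo], dim, dirs[[lo]])
      if (!is.null(vp))
        pairs[[length(pairs) + 1L]] <- list(p = pts[[lo]], v = vp)
    }
    if (!length(pairs)) { flagged[j] <- TRUE; next }
    for (pr in pairs) {
      corr <- shortestPathRegion(pr$p, pr$v, dim,
                                 clipTo = if (params@clipCorridor) px else NULL)
      path <- thinToPath(corr, pr$p, pr$v, dim)
      allPaths[[length(allPaths) + 1L]] <- path
      nCuts[j] <- nCuts[j] + 1L
    }
  }
  postMask <- applyCuts(cells@mask, allPaths)
  # fragments contributed by each stage-1 object
  fragments <- rep(1L, nrow(f))
  for (j in ocIds) {
    objMask <- matrix(0L, dim[1L], dim[2L])
    objMask[cells@labels == j] <- 1L
    objMask[postMask == 0L] <- 0L
    lab <- .label8(objMask)
    fragments[j] <- max(max(lab), 1L)
  }
  perObject <- S4Vectors::DataFrame(
    id = f$id, label = f$label, nCuts = nCuts, fragments = fragments,
    unsplittable = flagged
  )
  new("SplitResult", mask = postMask, paths = allPaths, cells = cells,
      perObject = perObject, count = sum(fragments))
}

#' Clear cut paths from a mask
#'
#' Sets every path pixel to background. Two details make a cut actually
#' separate what it crosses under 8-connectivity: (i) a one-pixel
#' 8-connected path does not interrupt foreground at diagonal steps, so
#' one 4-adjacent bridge pixel is cleared per diagonal step; (ii) a
#' rasterized endpoint can sit a pixel shy of the cell contour, so each
#' end of the path is prolonged along its own direction until background
#' is reached (a few pixels at most). Pixels outside the foreground are
#' clipped silently. No morphological restoration is performed: splitting
#' serves counting, not shape recovery.
#'
#' @param mask binary mask.
#' @param paths list of cut-path pixel matrices.
#' @return The mask with cuts cleared.
#' @export
applyCuts <- function(mask, paths) {
  .checkBinary(mask)
  out <- mask
  extend <- function(from, step) {
    # forward continuation until background (bounded)
    px <- NULL; pos <- from
    for (i in 1:6) {
      pos <- pos + step
      if (pos[1L] < 1L || pos[1L] > nrow(out) ||
          pos[2L] < 1L || pos[2L] > ncol(out)) break
      if (out[pos[1L], pos[2L]] == 0L) break
      px <- rbind(px, pos)
    }
    px
  }
  for (path in paths) {
    path <- .asPixelMatrix(path)
    full <- path
    if (nrow(path) >= 2L) {
      e1 <- extend(path[1L, ], sign(path[1L, ] - path[2L, ]))
      e2 <- extend(path[nrow(path), ],
                   sign(path[nrow(path), ] - path[nrow(path) - 1L, ]))
      if (!is.null(e1)) full <- rbind(e1[rev(seq_len(nrow(e1))), , drop = FALSE], full)
      if (!is.null(e2)) full <- rbind(full, e2)
    }
    clear <- full
    if (nrow(full) > 1L) {
      for (i in seq_len(nrow(full) - 1L)) {
        a <- full[i, ]; b <- full[i + 1L, ]
        if (a[1L] != b[1L] && a[2L] != b[2L]) {     # diagonal step
          b1 <- c(a[1L], b[2L]); b2 <- c(b[1L], a[2L])
          pick <- if (out[b1[1L], b1[2L]] == 1L) b1
                  else if (out[b2[1L], b2[2L]] == 1L) b2
                  else NULL
          if (!is.null(pick)) clear <- rbind(clear, pick)
        }
      }
    }
    inb <- clear[, 1L] >= 1L & clear[, 1L] <= nrow(out) &
           clear[, 2L] >= 1L & clear[, 2L] <= ncol(out)
    out[clear[inb, , drop = FALSE]] <- 0L
  }
  out
}

#' Count the cells of a split image
#'
#' Total count = number of non-OC stage-1 objects (each one cell) plus the
#' number of 8-connected fragments the OC objects break into after the
#' cuts. An unsplittable OC object contributes one.
#'
#' @param result a \linkS4class{SplitResult}.
#' @return Integer cell count.
#' @export
countCells <- function(result) {
  result@count
}

#' Pixel sets of the predicted cells
#'
#' Non-OC objects as-is plus the post-cut fragments of each OC object, the
#' unit against which ground truth is evaluated.
#'
#' @param result a \linkS4class{SplitResult}.
#' @return List of pixel matrices.
#' @export
predictedCells <- function(result) {
  cells <- result@cells
  f <- cells@features
  dim <- dim(cells@mask)
  out <- list()
  for (j in f$id) {
    if (!is.na(f$label[j]) && f$label[j] == "OC") {
      objMask <- matrix(0L, dim[1L], dim[2L])
      objMask[cells@labels == j] <- 1L
      objMask[result@mask == 0L] <- 0L
      lab <- .label8(objMask)
      n <- max(lab)
      if (n == 0L) next
      for (k in seq_len(n))
        out[[length(out) + 1L]] <- .asPixelMatrix(which(lab == k, arr.ind = TRUE))
    } else {
      out[[length(out) + 1L]] <- objectPixels(cells, j)
    }
  }
  out
}
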