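# Synthetic binary scenes with per-cell ground truth.
#
# The generator emulates what the splitting algorithm sees after cell
# segmentation of an H&E field at 20x: well-separated round single cells
# plus clumps of 2-5 partially overlapping round/elliptical cells, with
# optional single-pixel noise and 1-pixel holes to exercise preprocessing.
# Cell radii within one scene are drawn around a scene-level base radius
# (+/-10% jitter): nuclei of a single field are close to monomorphic, and
# the stage-1 area rule presumes that homogeneity.

#' Generate a synthetic cell scene with ground truth
#'
#' @param shape image dimensions c(h, w); default 512 x 512.
#' @param nSingle number of single cells.
#' @param nClump number of clumps (used when \code{clumpSizes} is a range).
#' @param clumpSizes integer vector of allowed cells-per-clump, sampled per
#'   clump, or a vector of length \code{nClump} giving the exact sizes.
#' @param radiusRange cell radius range (px); a base radius is drawn per
#'   scene and per-cell radii jitter +/-10% around it (clamped to range).
#' @param dFactorRange centre distance between consecutive clump members,
#'   in units of their mean radius; in (1, 2) so cells overlap without one
#'   engulfing the other.
#' @param ellipseRatioRange minor/major axis ratio range for cells
#'   (default round: c(1, 1); never below 0.5).
#' @param noisePixels isolated foreground noise pixels injected after
#'   ground truth capture.
#' @param holePixels single-pixel interior holes injected after ground
#'   truth capture.
#' @param minSep minimum chessboard separation (px) between distinct
#'   cells/clumps.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   scenes.
#' @param maxTries placement attempts per object before giving up.
#' @return List with \code{mask} (binary matrix), \code{truth} (list:
#'   \code{cells} = list of pixel matrices, \code{clump} = integer clump id
#'   per cell with 0 for singles, \code{count}), and \code{cleanMask}, the
#'   mask before noise/hole injection.
#' @examples
#' scn <- makeScene(shape = c(128, 128), nSingle = 3, nClump = 1, seed = 1)
#' scn$truth$count
#' @export
makeScene <- function(shape = c(512L, 512L), nSingle = 12L, nClump = 5L,
                      clumpSizes = 2:3, radiusRange = c(8, 14),
                      dFactorRange = c(1.1, 1.6),
                      ellipseRatioRange = c(1, 1),
                      noisePixels = 20L, holePixels = 20L,
                      minSep = 3L, seed = NULL, maxTries = 300L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(dFactorRange[1L] > 1, dFactorRange[2L] < 2,
            ellipseRatioRange[1L] >= 0.5)
  h <- shape[1L]; w <- shape[2L]
  baseR <- stats::runif(1L, radiusRange[1L], radiusRange[2L])
  drawR <- function() min(max(baseR * stats::runif(1L, 0.9, 1.1),
                              radiusRange[1L]), radiusRange[2L])
  sizes <- if (nClump == 0L) integer(0)
           else if (length(clumpSizes) == 1L) rep(as.integer(clumpSizes), nClump)
           else if (length(clumpSizes) == nClump) as.integer(clumpSizes)
           else sample(as.integer(clumpSizes), nClump, replace = TRUE)
  occupied <- matrix(FALSE, h, w)
  cellsPx <- list(); clumpId <- integer(0)
  placeEntity <- function(memberOffsets, radii, ratios, thetas) {
    # memberOffsets: k x 2 matrix of member centres relative to first
    pad <- max(radii) + minSep + 2
    for (try in seq_len(maxTries)) {
      cen <- c(stats::runif(1L, pad, h - pad), stats::runif(1L, pad, w - pad))
      member <- lapply(seq_along(radii), function(i) {
        ctr <- cen + memberOffsets[i, ]
        if (ratios[i] >= 0.999) discPixels(ctr, radii[i])
        else .ellipsePixels(ctr, radii[i], radii[i] * ratios[i], thetas[i])
      })
      all <- unique(do.call(rbind, member))
      if (any(all[, 1L] < 1L | all[, 1L] > h | all[, 2L] < 1L | all[, 2L] > w))
        next
      # forbid contact with existing objects: check the dilated footprint
      wpad <- .pixelWindow(all, c(h, w), pad = minSep)
      dil <- wpad$m
      for (k in seq_len(minSep)) dil <- .dilate8(dil)
      hit <- occupied[wpad$r0:(wpad$r0 + nrow(dil) - 1L),
                      wpad$c0:(wpad$c0 + ncol(dil) - 1L)] & dil
      if (any(hit)) next
      return(member)
    }
    NULL
  }
  drawRatio <- function() stats::runif(1L, ellipseRatioRange[1L], ellipseRatioRange[2L])
  # clumps first (they need the most room)
  for (q in seq_len(nClump)) {
    k <- sizes[q]
    radii <- vapply(seq_len(k), function(i) drawR(), numeric(1L))
    ratios <- vapply(seq_len(k), function(i) drawRatio(), numeric(1L))
    thetas <- stats::runif(k, 0, pi)
    # chain layout: consecutive members overlap, bends capped so
    # non-consecutive members stay apart
    dirs <- stats::runif(1L, 0, 2 * pi) +
      cumsum(c(0, stats::runif(max(k - 2L, 0L), -pi / 8, pi / 8)))
    offs <- matrix(0, k, 2L)
    for (i in seq_len(k - 1L)) {
      dfac <- stats::runif(1L, dFactorRange[1L], dFactorRange[2L])
      d <- dfac * (radii[i] + radii[i + 1L]) / 2
      offs[i + 1L, ] <- offs[i, ] + d * c(sin(dirs[i]), cos(dirs[i]))
    }
    member <- placeEntity(offs, radii, ratios, thetas)
    if (is.null(member))
      stop("could not place clump ", q, ": try fewer or smaller cells")
    for (px in member) {
      cellsPx[[length(cellsPx) + 1L]] <- px
      clumpId <- c(clumpId, q)
      occupied[px] <- TRUE
    }
  }
  for (s in seq_len(nSingle)) {
    member <- placeEntity(matrix(0, 1L, 2L), drawR(), drawRatio(),
                          stats::runif(1L, 0, pi))
    if (is.null(member))
      stop("could not place single cell ", s, ": try fewer or smaller cells")
    cellsPx[[length(cellsPx) + 1L]] <- member[[1L]]
    clumpId <- c(clumpId, 0L)
    occupied[member[[1L]]] <- TRUE
  }
  clean <- matrix(as.integer(occupied), h, w)
  mask <- clean
  if (length(cellsPx) == 0L)            # a blank field stays blank
    return(list(mask = mask, cleanMask = clean,
                truth = list(cells = cellsPx, clump = clumpId, count = 0L)))
  # noise: isolated foreground pixels at chessboard distance >= 3 from cells
  if (noisePixels > 0L) {
    far <- !occupied
    d1 <- .dilate8(occupied); d2 <- .dilate8(d1)
    far <- far & !d2
    cand <- which(far)
    if (length(cand))
      mask[sample(cand, min(noisePixels, length(cand)))] <- 1L
  }
  # holes: single interior pixels (all 8 neighbours foreground)
  if (holePixels > 0L) {
    inner <- occupied & !.innerBoundary8(occupied)
    inner <- inner & !.innerBoundary8(inner)   # keep away from the contour
    cand <- which(inner)
    if (length(cand))
      mask[sample(cand, min(holePixels, length(cand)))] <- 0L
  }
  list(mask = mask, cleanMask = clean,
       truth = list(cells = cellsPx, clump = clumpId,
                    count = length(cellsPx)))
}

#' Canonical two-disc clump with analytic pinch points
#'
#' Two equal discs of radius \code{r} whose centres are \code{dFactor * r}
#' apart: the canonical overlapping pair. The two circle-circle
#' intersection points (the pinch points, where the critical splitting
#' points must appear) are returned in closed form.
#'
#' @param r disc radius (px).
#' @param dFactor centre distance in units of r; must be in (1, 2).
#' @param pad margin around the clump (px).
#' @param angle orientation of the centre-centre axis (radians).
#' @return List: \code{mask}, \code{pixels} (clump pixel matrix),
#'   \code{centers} (2 x 2), \code{pinch} (2 x 2 matrix of the analytic
#'   intersection points, (row, col), possibly fractional), \code{dim}.
#' @examples
#' cl <- makeTwoDiscClump(10, 1.5)
#' cl$pinch
#' @export
makeTwoDiscClump <- function(r = 10, dFactor = 1.4, pad = 6, angle = 0) {
  if (dFactor <= 1 || dFactor >= 2)
    stop("dFactor must be in (1, 2): cells overlap, neither engulfed")
  d <- dFactor * r
  u <- c(sin(angle), cos(angle))
  half <- (d / 2) * u
  size <- ceiling(2 * r + d) + 2 * pad
  mid <- c(size / 2, size / 2)
  c1 <- mid - half; c2 <- mid + half
  px <- unique(rbind(discPixels(c1, r), discPixels(c2, r)))
  mask <- maskFromPixels(px, c(size, size))
  hgt <- sqrt(r^2 - (d / 2)^2)
  perp <- c(cos(angle), -sin(angle))
  pinch <- rbind(mid + hgt * perp, mid - hgt * perp)
  colnames(pinch) <- c("row", "col")
  list(mask = mask, pixels = .lexOrder(px), centers = rbind(c1, c2),
       pinch = pinch, dim = c(size, size))
}

#' Chain clump of three or more discs
#'
#' Discs laid along a (optionally bent) chain, consecutive members
#' overlapping; the analytic pinch points of each consecutive pair are
#' returned. A three-disc chain is the canonical four-ST scenario.
#'
#' @param k number of discs.
#' @param r disc radius.
#' @param dFactor centre distance factor per pinch (scalar or length k-1).
#' @param bend direction change per step (radians; scalar or length k-2).
#' @param pad margin (px).
#' @return List: \code{mask}, \code{pixels}, \code{centers} (k x 2),
#'   \code{pinch} (list of 2 x 2 matrices, one per consecutive pair),
#'   \code{dim}.
#' @export
makeChainClump <- function(k = 3, r = 10, dFactor = 1.4, bend = 0, pad = 6) {
  stopifnot(k >= 2)
  dFactor <- rep(dFactor, length.out = k - 1L)
  bend <- rep(bend, length.out = max(k - 2L, 0L))
  dirs <- cumsum(c(0, bend))
  cen <- matrix(0, k, 2L)
  for (i in seq_len(k - 1L))
    cen[i + 1L, ] <- cen[i, ] + dFactor[i] * r * c(sin(dirs[i]), cos(dirs[i]))
  shift <- c(pad + r + 1 - min(cen[, 1L]), pad + r + 1 - min(cen[, 2L]))
  cen <- sweep(cen, 2L, shift, "+")
  size <- c(ceiling(max(cen[, 1L]) + r) + pad, ceiling(max(cen[, 2L]) + r) + pad)
  px <- unique(do.call(rbind, lapply(seq_len(k), function(i)
    discPixels(cen[i, ], r))))
  pinch <- lapply(seq_len(k - 1L), function(i) {
    d <- sqrt(sum((cen[i + 1L, ] - cen[i, ])^2))
    u <- (cen[i + 1L, ] - cen[i, ]) / d
    mid <- (cen[i, ] + cen[i + 1L, ]) / 2
    hgt <- sqrt(r^2 - (d / 2)^2)
    perp <- c(u[2L], -u[1L])
    out <- rbind(mid + hgt * perp, mid - hgt * perp)
    colnames(out) <- c("row", "col")
    out
  })
  list(mask = maskFromPixels(px, size), pixels = .lexOrder(px),
       centers = cen, pinch = pinch, dim = size)
}

#' Write a scene fixture to disk
#'
#' Mask as PNG plus a JSON sidecar holding the ground truth with
#' run-length-encoded cell regions.
#'
#' @param scene a scene from \code{\link{makeScene}}.
#' @param maskPath PNG output path.
#' @param truthPath JSON output path.
#' @return Invisibly, the two paths.
#' @export
writeSceneFixture <- function(scene, maskPath, truthPath) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing fixtures requires the jsonlite package")
  writeMask(scene$mask, maskPath)
  h <- nrow(scene$mask)
  rle1 <- lapply(scene$truth$cells, function(px) {
    idx <- sort((px[, 2L] - 1L) * h + px[, 1L])   # column-major linear index
    breaks <- which(diff(idx) != 1L)
    starts <- idx[c(1L, breaks + 1L)]
    ends <- idx[c(breaks, length(idx))]
    list(starts = starts, lengths = ends - starts + 1L)
  })
  jsonlite::write_json(
    list(h = h, w = ncol(scene$mask), clump = scene$truth$clump,
         count = scene$truth$count, cells = rle1),
    truthPath, auto_unbox = TRUE)
  invisible(c(maskPath, truthPath))
}

#' Read a scene fixture written by \code{\link{writeSceneFixture}}
#'
#' @param maskPath,truthPath the two paths.
#' @return A scene list shaped like \code{\link{makeScene}}'s output.
#' @export
readSceneFixture <- function(maskPath, truthPath) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading fixtures requires the jsonlite package")
  mask <- readMask(maskPath)
  tr <- jsonlite::read_json(truthPath, simplifyVector = FALSE)
  h <- tr$h
  cells <- lapply(tr$cells, function(cell) {
    starts <- unlist(cell$starts); lens <- unlist(cell$lengths)
    idx <- unlist(mapply(function(s, l) s + 0:(l - 1L), starts, lens,
                         SIMPLIFY = FALSE))
    .asPixelMatrix(cbind(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L))
  })
  list(mask = mask, cleanMask = NULL,
       truth = list(cells = cells, clump = unlist(tr$clump),
                    count = tr$count))
}
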