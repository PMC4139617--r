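test_that("chebyshevField matches closed forms on 3x3 grids", {
  expect_equal(chebyshevField(cbind(1, 1), c(3, 3)),
               matrix(c(0, 1, 2, 1, 1, 2, 2, 2, 2), 3, 3, byrow = TRUE))
  expect_equal(chebyshevField(rbind(c(1, 1), c(3, 3)), c(3, 3)),
               matrix(c(0, 1, 2, 1, 1, 1, 2, 1, 0), 3, 3, byrow = TRUE))
  expect_error(chebyshevField(matrix(integer(0), 0, 2), c(3, 3)),
               "non-empty")
  expect_error(chebyshevField(cbind(5, 1), c(3, 3)), "inside")
})

test_that("chebyshevField equals the brute-force oracle on random seeds", {
  set.seed(71)
  for (i in 1:30) {
    k <- sample(1:8, 1)
    seeds <- cbind(sample(20, k, replace = TRUE), sample(20, k, replace = TRUE))
    expect_identical(chebyshevField(seeds, c(20, 20)),
                     bruteChebyshev(seeds, c(20, 20)))
  }
})

test_that("fields are 1-Lipschitz under the Chebyshev metric", {
  set.seed(5)
  seeds <- cbind(sample(15, 4), sample(15, 4))
  f <- chebyshevField(seeds, c(15, 15))
  for (i in 1:50) {
    a <- c(sample(15, 1), sample(15, 1)); b <- c(sample(15, 1), sample(15, 1))
    expect_lte(abs(f[a[1], a[2]] - f[b[1], b[2]]), chebDist(a, b))
  }
})

test_that("criticalPoint equals the brute-force argmax over the arc", {
  th <- seq(0, pi, length.out = 200)
  arc <- unique(cbind(round(10 - 8 * sin(th)), round(10 + 8 * cos(th))))
  chord <- cbind(10, 2:18)
  cp <- criticalPoint(arc, chord)
  # oracle: per-arc-pixel brute-force distance to the chord, argmax set
  d <- apply(arc, 1, function(p)
    min(pmax(abs(p[1] - chord[, 1]), abs(p[2] - chord[, 2]))))
  expOut <- arc[d == max(d), , drop = FALSE]
  expect_setequal(paste(cp[, 1], cp[, 2]), paste(expOut[, 1], expOut[, 2]))
  # the peak straddles the arc midpoint (col 10)
  expect_true(10 %in% cp[, 2] || min(abs(cp[, 2] - 10)) <= 1)

  # arc parallel to its chord: every arc pixel ties
  arc2 <- cbind(5, 3:12); chord2 <- cbind(9, 3:12)
  expect_equal(nrow(criticalPoint(arc2, chord2)), 10L)

  # single-pixel arc returns itself
  expect_equal(criticalPoint(cbind(4L, 4L), chord2),
               matrix(c(4L, 4L), 1, 2, dimnames = list(NULL, c("row", "col"))))
})

test_that("two-disc critical points land on the analytic pinch", {
  for (f in c(1.3, 1.5)) {
    cl <- makeTwoDiscClump(10, f)
    sts <- splittingTriangles(cl$pixels)$sts
    for (st in sts) {
      d <- decomposeST(st, cl$pixels, cl$dim)
      cp <- criticalPoint(d$arc, d$chord)
      err <- min(sqrt(rowSums(sweep(cl$pinch, 2, colMeans(cp))^2)))
      expect_lte(err, 2)
    }
  }
})

test_that("criticalPoint is invariant to translation and rotation", {
  cl <- makeTwoDiscClump(9, 1.4)
  d <- decomposeST(splittingTriangles(cl$pixels)$sts[[1]], cl$pixels, cl$dim)
  cp <- criticalPoint(d$arc, d$chord)

  shift <- c(7L, 11L)
  cpT <- criticalPoint(sweep(d$arc, 2, -shift), sweep(d$chord, 2, -shift))
  expect_equal(sweep(cpT, 2, shift), cp, ignore_attr = TRUE)

  # 90-degree rotation: (r, c) -> (c, M - r)
  M <- 100L
  rot <- function(p) cbind(p[, 2], M - p[, 1])
  cpR <- criticalPoint(rot(d$arc), rot(d$chord))
  expect_setequal(paste(cpR[, 1], cpR[, 2]),
                  paste(rot(cp)[, 1], rot(cp)[, 2]))
})

test_that("pairPoints pairs nearest points and leaves the odd one out", {
  pts <- list(cbind(1L, 1L), cbind(1L, 5L), cbind(11L, 11L))
  pp <- pairPoints(pts)
  expect_length(pp$pairs, 1L)
  expect_setequal(pp$pairs[[1]], c(1L, 2L))
  expect_equal(pp$leftover, 3L)

  # two points: the single possible pair
  pp2 <- pairPoints(list(cbind(2L, 2L), cbind(9L, 4L)))
  expect_length(pp2$pairs, 1L)
  expect_length(pp2$leftover, 0L)
  expect_error(pairPoints(list(cbind(1L, 1L))), "at least two")
})

test_that("pairPoints is invariant to input order", {
  set.seed(31)
  pts <- lapply(1:5, function(i) cbind(sample(40, 1), sample(40, 1)))
  ref <- pairPoints(pts)
  refKey <- sort(vapply(ref$pairs, function(ij)
    paste(sort(ij), collapse = "-"), character(1)))
  for (rep in 1:5) {
    perm <- sample(5)
    pp <- pairPoints(pts[perm])
    key <- sort(vapply(pp$pairs, function(ij)
      paste(sort(perm[ij]), collapse = "-"), character(1)))
    expect_identical(key, refKey)
  }
})

test_that("chain splitting points pair across pinches like the matching oracle", {
  # centre distance 1.6 radii: the across-pinch distance is strictly the
  # smallest, so greedy pairing and exhaustive matching must coincide
  ch <- makeChainClump(3, 10, 1.6)
  sts <- splittingTriangles(ch$pixels)$sts
  dec <- lapply(sts, function(s) decomposeST(s, ch$pixels, ch$dim))
  pts <- lapply(dec, function(d) criticalPoint(d$arc, d$chord))
  expect_length(pts, 4L)
  pp <- pairPoints(pts)
  got <- lapply(pp$pairs, sort)
  want <- lapply(exhaustiveMatching(pts), sort)
  expect_setequal(vapply(got, paste, character(1), collapse = "-"),
                  vapply(want, paste, character(1), collapse = "-"))
  # sanity: the matched pairs straddle a pinch, not the long diagonal
  for (ij in pp$pairs) {
    c1 <- colMeans(pts[[ij[1]]]); c2 <- colMeans(pts[[ij[2]]])
    expect_lte(abs(c1[2] - c2[2]), 4)   # same pinch column
  }
})

test_that("contourFallback routes a crescent point across the waist", {
  cres <- crescentPixels(center = c(25, 20), r = 12, shift = 8)
  msk <- maskFromPixels(cres, c(50, 50))
  sts <- splittingTriangles(cres)$sts
  expect_length(sts, 1L)
  d <- decomposeST(sts[[1]], cres, c(50, 50))
  cp <- criticalPoint(d$arc, d$chord)
  partner <- contourFallback(cres, cp, list(d$arc), c(50, 50))
  expect_false(is.null(partner))
  # partner must not touch the concave arc
  dArc <- min(pmax(abs(outer(partner[, 1], d$arc[, 1], "-")),
                   abs(outer(partner[, 2], d$arc[, 2], "-"))))
  expect_gte(dArc, 2)
  # and it sits across the thin waist: close to the point, on the contour
  expect_lte(min(pmax(abs(outer(partner[, 1], cp[, 1], "-")),
                      abs(outer(partner[, 2], cp[, 2], "-")))), 8)
})

test_that("fallback partner excludes pixels beside an injected notch", {
  disc <- discPixels(c(20, 20), 10)
  k <- paste(disc[, 1], disc[, 2])
  notch <- as.matrix(expand.grid(row = 10:14, col = 19:21))
  disc2 <- disc[!(k %in% paste(notch[, 1], notch[, 2])), ]
  sts <- splittingTriangles(disc2)$sts
  expect_gte(length(sts), 1L)
  d <- decomposeST(sts[[1]], disc2, c(40, 40))
  cp <- criticalPoint(d$arc, d$chord)
  partner <- contourFallback(disc2, cp, list(d$arc), c(40, 40))
  dArc <- min(pmax(abs(outer(partner[, 1], d$arc[, 1], "-")),
                   abs(outer(partner[, 2], d$arc[, 2], "-"))))
  expect_gte(dArc, 2)
})

test_that("shortestPathRegion is the Chebyshev geodesic corridor", {
  # collinear points: the straight segment is inside the corridor
  corr <- shortestPathRegion(cbind(1L, 1L), cbind(1L, 5L), c(8, 8))
  k <- paste(corr[, 1], corr[, 2])
  expect_true(all(paste(1, 1:5) %in% k))

  # oracle: all x with d(p,x) + d(x,v) = d(p,v)
  p <- c(1L, 1L); v <- c(4L, 2L)
  corr2 <- shortestPathRegion(cbind(p[1], p[2]), cbind(v[1], v[2]), c(10, 10))
  expected <- NULL
  for (r in 1:10) for (c in 1:10)
    if (chebDist(c(r, c), p) + chebDist(c(r, c), v) == chebDist(p, v))
      expected <- rbind(expected, c(r, c))
  expect_setequal(paste(corr2[, 1], corr2[, 2]),
                  paste(expected[, 1], expected[, 2]))

  # adjacent pixels: corridor is exactly the two of them
  corr3 <- shortestPathRegion(cbind(3L, 3L), cbind(4L, 4L), c(6, 6))
  expect_equal(nrow(corr3), 2L)

  # corridor minimum equals the set distance (triangle equality)
  set.seed(17)
  for (i in 1:10) {
    a <- cbind(sample(30, 2), sample(30, 2))
    b <- cbind(sample(30, 2), sample(30, 2))
    corr <- shortestPathRegion(a, b, c(30, 30))
    dab <- min(pmax(abs(outer(a[, 1], b[, 1], "-")),
                    abs(outer(a[, 2], b[, 2], "-"))))
    # both endpoints are inside their own corridor
    k <- paste(corr[, 1], corr[, 2])
    expect_true(all(paste(a[, 1], a[, 2]) %in% k) ||
                any(paste(a[, 1], a[, 2]) %in% k))
    expect_gte(nrow(corr), dab + 1)
  }
})
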