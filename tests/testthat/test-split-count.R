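test_that("thinToPath reduces corridors to audited one-pixel routes", {
  # an already-thin corridor passes through unchanged (up to ordering)
  thin <- cbind(5L, 3:9)
  path <- thinToPath(thin, cbind(5L, 3L), cbind(5L, 9L), c(12, 12))
  expect_equal(nrow(path), 7L)
  expect_true(auditPath(path))

  # solid 3x5 block, endpoints at the short ends -> spanning 1-px path
  block <- as.matrix(expand.grid(row = 4:6, col = 2:6))
  p <- cbind(5L, 2L); v <- cbind(5L, 6L)
  path2 <- thinToPath(block, p, v, c(10, 10))
  expect_true(auditPath(path2))
  expect_gte(nrow(path2), 5L)
  expect_equal(path2[1, ], c(row = 5L, col = 2L))
  expect_equal(path2[nrow(path2), ], c(row = 5L, col = 6L))

  # width-2 diagonal staircase -> width-1 staircase, endpoints intact
  stair <- NULL
  for (i in 0:5) stair <- rbind(stair, c(3 + i, 3 + i), c(3 + i, 4 + i),
                                c(4 + i, 3 + i))
  stair <- unique(stair)
  path3 <- thinToPath(stair, cbind(3L, 3L), cbind(8L, 9L), c(14, 14))
  expect_true(auditPath(path3))
  expect_equal(path3[1, ], c(row = 3L, col = 3L))
  expect_equal(path3[nrow(path3), ], c(row = 8L, col = 9L))
})

test_that("corridor thinning preserves endpoints for clump pairs", {
  cl <- makeTwoDiscClump(10, 1.5)
  dec <- lapply(splittingTriangles(cl$pixels)$sts,
                function(s) decomposeST(s, cl$pixels, cl$dim))
  pts <- lapply(dec, function(d) criticalPoint(d$arc, d$chord))
  corr <- shortestPathRegion(pts[[1]], pts[[2]], cl$dim)
  path <- thinToPath(corr, pts[[1]], pts[[2]], cl$dim)
  expect_true(auditPath(path))
  d1 <- min(pmax(abs(outer(path[1, 1], pts[[1]][, 1], "-")),
                 abs(outer(path[1, 2], pts[[1]][, 2], "-"))))
  dn <- min(pmax(abs(outer(path[nrow(path), 1], pts[[2]][, 1], "-")),
                 abs(outer(path[nrow(path), 2], pts[[2]][, 2], "-"))))
  expect_lte(d1, 1); expect_lte(dn, 1)
})

test_that("applyCuts clears cuts and nothing else grows", {
  cl <- makeTwoDiscClump(10, 1.5)
  expect_identical(applyCuts(cl$mask, list()), cl$mask)

  res <- splitForced(cl$mask)
  expect_length(cutPaths(res), 1L)
  post <- maskOf(res)
  expect_true(all(post <= cl$mask))            # cuts only remove
  expect_equal(floodComponents(post), 2L)

  # area accounting: removed pixels = foreground difference
  expect_equal(sum(cl$mask) - sum(post),
               sum(cl$mask == 1L & post == 0L))
})

test_that("cuts can only increase the component count", {
  for (seed in c(2, 7)) {
    scn <- makeScene(shape = c(192, 192), nSingle = 4, nClump = 2, seed = seed)
    m <- cleanMask(scn$mask)
    res <- suppressWarnings(splitCells(assignLabels(labelComponents(m))))
    expect_gte(floodComponents(maskOf(res)), floodComponents(m))
  }
})

test_that("counting adds singles and post-cut fragments", {
  # five separated discs, no clumps
  scn <- makeScene(shape = c(256, 256), nSingle = 5, nClump = 0, seed = 13)
  res <- splitCells(assignLabels(labelComponents(cleanMask(scn$mask))))
  expect_equal(countCells(res), 5L)
  expect_equal(cellCount(res), 5L)

  # three singles plus one two-disc clump: split once, count five
  scn2 <- makeScene(shape = c(256, 256), nSingle = 3, nClump = 1,
                    clumpSizes = 2, dFactorRange = c(1.35, 1.5), seed = 23)
  res2 <- suppressWarnings(
    splitCells(assignLabels(labelComponents(cleanMask(scn2$mask)))))
  expect_equal(countCells(res2), 5L)
  expect_length(predictedCells(res2), 5L)
})

test_that("count report reproduces the metric formulas exactly", {
  rep0 <- countReport(9, 1, 1)
  expect_equal(rep0@precision, 90)
  expect_equal(rep0@recall, 90)
  expect_equal(rep0@fmeasure, 90)

  # empty vs empty is perfect by definition
  repE <- evaluateCounts(list(), list())
  expect_equal(repE@fmeasure, 100)

  # F is symmetric in swapping FP and FN
  expect_equal(countReport(7, 2, 5)@fmeasure, countReport(7, 5, 2)@fmeasure)
})

test_that("evaluation matches predictions one-to-one by overlap", {
  px <- discPixels(c(20, 20), 8)
  perfect <- evaluateCounts(list(px), list(px))
  expect_equal(perfect@tp, 1L)
  expect_equal(perfect@fmeasure, 100)

  # n unsplit clumps of two: one TP by overlap, one FN each
  cl <- makeTwoDiscClump(10, 1.5)
  truth <- list(discPixels(cl$centers[1, ], 10), discPixels(cl$centers[2, ], 10))
  rep1 <- evaluateCounts(list(cl$pixels), truth)
  expect_equal(rep1@tp, 1L)
  expect_equal(rep1@fn, 1L)
  expect_equal(rep1@fp, 0L)
})

test_that("splitting a two-disc clump recovers both cells for scoring", {
  cl <- makeTwoDiscClump(10, 1.5)
  res <- splitForced(cl$mask)
  pred <- predictedCells(res)
  truth <- list(discPixels(cl$centers[1, ], 10),
                discPixels(cl$centers[2, ], 10))
  rep2 <- evaluateCounts(pred, truth)
  expect_equal(rep2@tp, 2L)
  expect_equal(rep2@fmeasure, 100)
})
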