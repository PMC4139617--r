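test_that("diameter equality matches pixel-geometry oracles", {
  expect_gte(diameterEquality(discPixels(c(25, 25), 20)), 0.95)

  rect <- as.matrix(expand.grid(row = 1:20, col = 1:40))
  expect_equal(diameterEquality(rect), 0.5, tolerance = 0.2)

  sq <- as.matrix(expand.grid(row = 1:40, col = 1:40))
  expect_equal(diameterEquality(sq), 1 / sqrt(2), tolerance = 0.02)

  expect_warning(de1 <- diameterEquality(cbind(5L, 5L)), "single-pixel")
  expect_equal(de1, 1)
})

test_that("concavity is the normalized hull deficit", {
  sq <- as.matrix(expand.grid(row = 1:10, col = 1:10))
  expect_lte(concavity(sq), 0.02)

  clump <- makeTwoDiscClump(10, 1.5)$pixels
  expect_gt(concavity(clump), 0.02)

  cres <- crescentPixels()
  expect_gt(concavity(cres), concavity(clump))
  expect_error(concavity(matrix(integer(0), 0, 2)), "empty")
})

test_that("concavity and diameter equality are nearly scale invariant", {
  for (r in c(10, 12)) {
    small <- discPixels(c(30, 30), r)
    big <- discPixels(c(60, 60), 2 * r)
    expect_lte(abs(concavity(small) - concavity(big)), 0.05)
    expect_lte(abs(diameterEquality(small) - diameterEquality(big)), 0.05)
  }
  s1 <- makeTwoDiscClump(8, 1.4)$pixels
  s2 <- makeTwoDiscClump(16, 1.4)$pixels
  expect_lte(abs(concavity(s1) - concavity(s2)), 0.05)
})

test_that("sequential labelling rules reproduce the hand-applied oracle", {
  # one object alone: A equals the mean, strict inequality keeps it PS
  lone <- labelComponents(maskFromPixels(discPixels(c(20, 20), 8), c(40, 40)))
  expect_equal(stage1Labels(assignLabels(lone)), "PS")

  # three-object scene: small disc (PS), big round disc (PO -> SC),
  # clump bigger than average and more concave than average (PO -> OC)
  m <- matrix(0L, 120, 180)
  m[maskFromPixels(discPixels(c(25, 25), 8), dim(m)) == 1L] <- 1L
  m[maskFromPixels(discPixels(c(80, 40), 16), dim(m)) == 1L] <- 1L
  cl <- makeTwoDiscClump(12, 1.4)
  px <- cl$pixels; px[, 2L] <- px[, 2L] + 110L
  m[maskFromPixels(px, dim(m)) == 1L] <- 1L
  sc <- assignLabels(labelComponents(m))
  f <- as.data.frame(objectFeatures(sc))
  # oracle: apply the three rules to the measured features
  expLab <- ifelse(f$area > mean(f$area), "PO", "PS")
  expLab[expLab == "PO" & f$de > 0.9] <- "SC"
  expLab[expLab == "PO" & f$cx > mean(f$cx)] <- "OC"
  expect_identical(f$label, expLab)
  expect_setequal(f$label, c("PS", "SC", "OC"))
})

test_that("every object gets exactly one stage-1 label", {
  scn <- makeScene(shape = c(256, 256), nSingle = 6, nClump = 2, seed = 14)
  sc <- assignLabels(labelComponents(cleanMask(scn$mask)))
  labs <- stage1Labels(sc)
  expect_false(any(is.na(labs)))
  expect_true(all(labs %in% c("PS", "PO", "SC", "OC")))
  expect_identical(imageStats(sc)$meanArea, mean(objectFeatures(sc)$area))
})

test_that("overlappingMask keeps exactly the OC pixels", {
  scn <- makeScene(shape = c(256, 256), nSingle = 5, nClump = 2, seed = 4)
  sc <- assignLabels(labelComponents(cleanMask(scn$mask)))
  om <- overlappingMask(sc)
  f <- objectFeatures(sc)
  ocArea <- sum(f$area[f$label == "OC"])
  expect_equal(sum(om), ocArea)

  # no OC objects -> all-zero mask
  lone <- assignLabels(labelComponents(
    maskFromPixels(discPixels(c(20, 20), 8), c(40, 40))))
  expect_equal(sum(overlappingMask(lone)), 0L)
})

test_that("discrimination holds on disc/clump fixture scenes", {
  nC <- 0; nCok <- 0; nS <- 0; nSok <- 0
  for (seed in 1:6) {
    scn <- makeScene(shape = c(320, 320), nSingle = 8, nClump = 3,
                     clumpSizes = 2, seed = seed)
    sc <- assignLabels(labelComponents(cleanMask(scn$mask)))
    labs <- labelMatrix(sc); f <- objectFeatures(sc)
    for (q in seq_along(scn$truth$cells)) {
      cen <- round(colMeans(scn$truth$cells[[q]]))
      obj <- labs[cen[1], cen[2]]
      if (obj == 0) next
      if (scn$truth$clump[q] == 0) {
        nS <- nS + 1; if (f$label[obj] != "OC") nSok <- nSok + 1
      } else {
        nC <- nC + 1; if (f$label[obj] == "OC") nCok <- nCok + 1
      }
    }
  }
  expect_gte(nCok / nC, 0.9)
  expect_gte(nSok / nS, 0.9)
})
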