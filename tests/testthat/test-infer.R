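test_that("the literal fusion rule follows its printed branches", {
  th <- suppressWarnings(fusionThresholds())  # all 0.5
  expect_equal(fuseEq2(matrix(0.4), matrix(0.4), th), matrix(2L))
  th2 <- fusionThresholds(0.3, 0.7, 0.5, 0.5)
  expect_equal(fuseEq2(matrix(0.5), matrix(0.2), th2), matrix(1L))
  # any pixel with high contour probability is background
  No <- matrix(stats::runif(25), 5, 5)
  Nc <- matrix(0.9, 5, 5)
  expect_true(all(fuseEq2(No, Nc, th2) == 0L))
  expect_error(fuseEq2(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("fuseEq2 equals per-pixel brute force, including the degeneracy", {
  th <- fusionThresholds(0.3, 0.7, 0.5, 0.6)
  for (seed in 1:6) {
    set.seed(seed)
    No <- matrix(stats::runif(16 * 16), 16, 16)
    Nc <- matrix(stats::runif(16 * 16), 16, 16)
    expect_identical(fuseEq2(No, Nc, th), fuseOracle(No, Nc, th))
  }
  # with the printed defaults (all 0.5) the epidermis branch is empty
  expect_warning(fusionThresholds(), "empty")
  thDef <- suppressWarnings(fusionThresholds())
  set.seed(7)
  No <- matrix(stats::runif(400), 20, 20)
  Nc <- matrix(stats::runif(400), 20, 20)
  expect_false(any(fuseEq2(No, Nc, thDef) == 1L))
})

test_that("practical fusion reduces to argmax away from contours", {
  cm <- randomClassMask(16, 16, 5)
  expect_identical(fusePractical(oneHotProbs(cm)), cm)
  allBg <- new("ProbMaps",
               object = oneHot(matrix(0L, 8, 8)),
               contour = matrix(stats::runif(64), 8, 8))
  expect_true(all(fusePractical(allBg) == 0L))
  # constructed agreement with the literal rule: confident background,
  # low contour; both rules return all background
  No <- matrix(0.95, 8, 8)  # background channel, above tO2
  probs <- new("ProbMaps",
               object = array(c(No, (1 - No) / 2, (1 - No) / 2),
                              c(8, 8, 3)),
               contour = matrix(0.1, 8, 8))
  th <- fusionThresholds(0.3, 0.7, 0.5, 0.5)
  expect_identical(fusePractical(probs, th), fuseEq2(No, probs@contour, th))
})

test_that("contour refinement rewrites only near anchors", {
  # epidermis rows 5..10; argmax errs at row 5 fringe (labelled background),
  # contour band covers rows 4..6; anchor above is background, below epidermis
  cls <- matrix(0L, 16, 4)
  cls[6:10, ] <- 1L
  cls[5, ] <- 1L
  Po <- oneHot(cls)
  ctr <- matrix(0, 16, 4)
  ctr[4:6, ] <- 1
  probs <- new("ProbMaps", object = Po, contour = ctr)
  out <- fusePractical(probs)
  # row 4 anchors to background (distance 1 up), row 6 to epidermis (1 down),
  # row 5 ties and takes the smaller class index
  expect_true(all(out[4, ] == 0L))
  expect_true(all(out[5, ] == 0L))
  expect_true(all(out[6, ] == 1L))
  expect_true(all(out[7:10, ] == 1L))
  # pixels beyond maxShiftPx of an anchor keep the object-head class
  ctr2 <- matrix(0, 16, 4)
  ctr2[3:13, ] <- 1  # band much wider than its trained width
  out2 <- fusePractical(new("ProbMaps", object = Po, contour = ctr2))
  expect_true(all(out2[7:10, ] == 1L))
})

test_that("segmentVolume keeps the identity path and value domain", {
  g <- makeVolume(domainPreset("target", "S1", height = 32, width = 32,
                               seed = 3), 2)
  m <- buildModel(depth = 2, baseChannels = 4, seed = 1)
  seg <- segmentVolume(m, g$volume)
  expect_equal(dim(seg), dim(volData(g$volume)))
  expect_true(all(seg %in% 0:2))
  # truth probabilities pass through fusion unchanged
  cm <- classMasks(g$truth)[, , 1]
  expect_identical(fusePractical(oneHotProbs(cm)), cm)
  # reflect-padding handles sizes not divisible by 2^depth
  odd <- new("OCTVolume", data = volData(g$volume)[1:30, 1:30, , drop = FALSE],
             pitchUm = 8)
  seg2 <- segmentVolume(m, odd)
  expect_equal(dim(seg2), c(30L, 30L, 2L))
})

test_that("thickness maps recover boundary separation per A-line", {
  g <- makeVolume(flatParams(width = 20), 3)
  tm <- thicknessMap(classMasks(g$truth), pitchUm = 8)
  expect_true(all(thicknessPx(tm) == 80))
  expect_true(all(thicknessUm(tm) == 640))  # 80 px at 8 um/px
  # A-lines without epidermis are undefined
  m <- matrix(0L, 16, 4)
  m[5:8, c(1, 3)] <- 1L
  tm2 <- thicknessMap(m, pitchUm = 8)
  expect_equal(as.vector(is.na(thicknessPx(tm2))), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(thicknessPx(tm2)[1, 1], 4)
  # the largest run wins; ties go to the shallower run
  m2 <- matrix(0L, 20, 1)
  m2[2:4, 1] <- 1L   # 3-px run
  m2[10:15, 1] <- 1L # 6-px run (largest)
  expect_equal(thicknessPx(thicknessMap(m2))[1, 1], 6)
  m3 <- matrix(0L, 20, 1)
  m3[2:4, 1] <- 1L
  m3[10:12, 1] <- 1L
  expect_equal(thicknessPx(thicknessMap(m3))[1, 1], 3)
})

test_that("thickness is invariant to horizontal B-scan flips", {
  g <- makeVolume(domainPreset("target", "control", height = 64, width = 32,
                               seed = 5), 2)
  cm <- classMasks(g$truth)
  tm <- thicknessPx(thicknessMap(cm))
  flipped <- cm[, rev(seq_len(dim(cm)[2])), , drop = FALSE]
  expect_equal(thicknessPx(thicknessMap(flipped)),
               tm[rev(seq_len(nrow(tm))), , drop = FALSE])
})

test_that("mean thickness statistics respect the validity mask", {
  const <- new("ThicknessMap", px = matrix(80, 10, 2), pitchUm = 8)
  mt <- meanThickness(const)
  expect_equal(unname(mt["meanUm"]), 640)
  expect_equal(unname(mt["sdUm"]), 0)
  half <- new("ThicknessMap", px = matrix(c(10, 30), 10, 2), pitchUm = 8)
  expect_equal(unname(meanThickness(half)["meanUm"]), 20 * 8)
  expect_error(meanThickness(const, region = matrix(FALSE, 10, 2)),
               "undefined")
})

test_that("thickness deviation follows the volume-wise convention", {
  truth <- new("ThicknessMap", px = matrix(40, 8, 2), pitchUm = 8)
  expect_equal(unname(thicknessDeviation(truth, truth)[c("meanUm", "sdUm")]),
               c(0, 0))
  pred <- new("ThicknessMap", px = matrix(42, 8, 2), pitchUm = 8)
  expect_equal(unname(thicknessDeviation(pred, truth)["meanUm"]), 16)
  expect_equal(thicknessDeviation(pred, truth),
               thicknessDeviation(truth, pred))
  pred2 <- new("ThicknessMap", px = matrix(44, 8, 2), pitchUm = 8)
  d <- thicknessDeviation(list(pred, pred2), list(truth, truth))
  expect_equal(unname(d["meanUm"]), mean(c(16, 32)))
  expect_equal(unname(d["n"]), 2)
  bad <- new("ThicknessMap", px = matrix(40, 4, 2), pitchUm = 8)
  expect_error(thicknessDeviation(pred, bad), "grid")
})
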