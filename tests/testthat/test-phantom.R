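test_that("a flat noise-free phantom has exact analytic geometry", {
  bs <- makeBScan(flatParams())
  truth <- bs$truth
  expect_true(all(thicknessPx(truth) == 80))
  b <- boundaries(truth)
  expect_true(all(b$upper == 10))
  expect_true(all(b$lower == 90))
  # epidermis occupies rows 10..89: mask agrees with the boundary rows
  m <- classMasks(truth)[, , 1]
  expect_true(all(m[10:89, ] == 1L))
  expect_true(all(m[1:9, ] == 0L))
  expect_true(all(m[90:128, ] == 0L))
  # at the surface row the attenuation depth is 0: value is exactly reflEpi
  expect_equal(unname(bs$image[10, ]), rep(0.55, 32))
})

test_that("domain presets respect the interspecies thickness regimes", {
  for (s in c("control", "S1", "S2", "S3")) {
    for (seed in 1:3) {
      src <- makeBScan(domainPreset("source", s, height = 64, width = 64,
                                    seed = seed))
      expect_lte(max(thicknessPx(src$truth)), 3)  # < 25 um at 8 um/px
      tgt <- makeBScan(domainPreset("target", s, height = 64, width = 64,
                                    seed = seed))
      expect_gte(min(thicknessPx(tgt$truth)), 7)  # > 50 um at 8 um/px
    }
  }
})

test_that("wound sessions control the scab cap and only scab fields differ", {
  withScab <- makeBScan(domainPreset("target", "S1", height = 64,
                                     width = 64, seed = 2))
  expect_true(any(classMasks(withScab$truth) == 2L))
  noScab <- makeBScan(domainPreset("source", "control", height = 64,
                                   width = 64, seed = 2))
  expect_false(any(classMasks(noScab$truth) == 2L))
  # scab sits strictly on top of the epidermis
  b <- boundaries(withScab$truth)
  has <- !is.na(b$scabTop[, 1])
  expect_true(all(b$scabBottom[has, 1] == b$upper[has, 1] - 1))
  # presets of one domain differ only in scab/session fields
  pCtl <- domainPreset("target", "control", seed = 5)
  pS1 <- domainPreset("target", "S1", seed = 5)
  for (sn in slotNames(pCtl))
    if (!sn %in% c("session", "scab", "scabExtentFrac"))
      expect_identical(slot(pCtl, sn), slot(pS1, sn))
})

test_that("volume generation is deterministic and stacks consistently", {
  p <- domainPreset("target", "S2", height = 64, width = 48, seed = 9)
  g1 <- makeVolume(p, 5)
  g2 <- makeVolume(p, 5)
  expect_identical(volData(g1$volume), volData(g2$volume))
  expect_identical(classMasks(g1$truth), classMasks(g2$truth))
  expect_equal(dim(thicknessPx(g1$truth)), c(48, 5))
  # single-B-scan volume equals makeBScan
  bs <- makeBScan(p)
  v1 <- makeVolume(p, 1)
  expect_identical(bs$image, volData(v1$volume)[, , 1])
  expect_identical(classMasks(bs$truth), classMasks(v1$truth))
})

test_that("constant-thickness phantoms give a constant en-face truth map", {
  p <- flatParams(width = 24)
  g <- makeVolume(p, 4)
  tm <- truthThicknessMap(g$truth, pitchUm = 8)
  expect_equal(stats::var(as.vector(thicknessPx(tm))), 0)
  expect_true(all(thicknessUm(tm) == 640))
})

test_that("infeasible layer geometry fails naming the offending A-line", {
  p <- phantomParams(height = 32L, width = 20L, surfaceDepthPx = 8,
                     surfaceAmpPx = 0, epiMeanPx = 40, epiVarPx = 0,
                     epiMinPx = 1, epiMaxPx = 40, speckleShape = 0,
                     noiseSigma = 0)
  expect_error(makeBScan(p), "A-line")
})

test_that("phantom invariants: label partition, boundary order, contrast", {
  for (seed in 1:5) {
    g <- makeVolume(domainPreset("target", "S1", height = 64, width = 64,
                                 seed = seed), 2)
    m <- classMasks(g$truth)
    expect_true(all(m %in% 0:2))
    b <- boundaries(g$truth)
    expect_true(all(b$lower > b$upper))
    expect_equal(thicknessPx(g$truth), b$lower - b$upper,
                 ignore_attr = TRUE)
  }
  # attenuation-corrected mean reflectivity: epidermis > dermis
  p <- domainPreset("target", "control", height = 64, width = 64, seed = 3)
  p@speckleShape <- 0; p@noiseSigma <- 0
  g <- makeVolume(p, 1)
  img <- volData(g$volume)[, , 1]
  m <- classMasks(g$truth)[, , 1]
  b <- boundaries(g$truth)
  depth <- sweep(matrix(seq_len(64), 64, 64), 2, b$upper[, 1])
  corrected <- img * exp(p@attenPerPx * pmax(depth, 0))
  dermis <- sweep(matrix(seq_len(64), 64, 64), 2, b$lower[, 1], `>=`)
  expect_gt(mean(corrected[m == 1L]), mean(corrected[dermis]))
})
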