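test_that("overlap metrics match hand-counted cases", {
  a <- matrix(FALSE, 4, 4); b <- matrix(FALSE, 4, 4)
  a[1, 1:2] <- TRUE
  b[1, 2:3] <- TRUE
  expect_equal(iou(a, b), 1 / 3)
  expect_equal(dsc(a, b), 0.5)  # 2 * (1/3) / (1 + 1/3)
  expect_equal(iou(a, a), 1)
  expect_equal(dsc(a, a), 1)
  disjoint <- matrix(FALSE, 4, 4); disjoint[4, 4] <- TRUE
  expect_equal(iou(a, disjoint), 0)
  expect_equal(dsc(a, disjoint), 0)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(iou(empty, empty), 1)
  expect_equal(dsc(empty, empty), 1)
  expect_error(iou(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("surface extraction uses 4-connectivity with border background", {
  m <- matrix(FALSE, 7, 7)
  m[3:5, 3:5] <- TRUE
  sp <- surfacePoints(m)
  expect_equal(nrow(sp), 8L)  # 3x3 solid square: all but the centre
  expect_false(any(sp[, 1] == 4 & sp[, 2] == 4))
  single <- matrix(FALSE, 5, 5); single[2, 3] <- TRUE
  expect_equal(surfacePoints(single), cbind(row = 2L, col = 3L))
  # full-foreground mask: the image border is surface
  full <- matrix(TRUE, 4, 5)
  sp2 <- surfacePoints(full)
  expect_equal(nrow(sp2), 2 * 4 + 2 * 5 - 4)
  expect_equal(nrow(surfacePoints(matrix(FALSE, 3, 3))), 0L)
})

test_that("surface distances match hand-derived geometry", {
  a <- matrix(FALSE, 12, 12); b <- matrix(FALSE, 12, 12)
  a[4, 3:9] <- TRUE
  b[7, 3:9] <- TRUE  # same columns, 3 rows apart
  expect_equal(assd(a, b, pitchUm = 8), 24)
  expect_equal(assd(a, a, pitchUm = 8), 0)
  expect_equal(hausdorff(a, a, pitchUm = 8), 0)
  # axis-aligned translation of a square outline far from borders
  sq <- matrix(FALSE, 20, 20); sq[5:10, 5:10] <- TRUE
  sq2 <- matrix(FALSE, 20, 20); sq2[8:13, 5:10] <- TRUE
  expect_equal(hausdorff(sq, sq2, pitchUm = 8), 3 * 8)
  expect_equal(hausdorff(sq, sq2), hausdorff(sq2, sq))
  # empty-mask conventions
  empty <- matrix(FALSE, 12, 12)
  expect_equal(assd(empty, empty), 0)
  expect_equal(hausdorff(empty, empty), 0)
  expect_error(assd(a, empty), "empty")
  expect_error(hausdorff(empty, a), "empty")
})

test_that("distance metrics agree with the exhaustive pairwise oracle", {
  for (seed in 1:12) {
    p <- randomBinaryMask(24, 24, seed)
    g <- randomBinaryMask(24, 24, seed + 100)
    if (!any(p) || !any(g)) next
    o <- surfaceDistOracle(p, g, pitchUm = 8)
    expect_equal(assd(p, g, pitchUm = 8), o$assd, tolerance = 1e-9)
    expect_equal(hausdorff(p, g, pitchUm = 8), o$hd, tolerance = 1e-9)
    expect_lte(assd(p, g), hausdorff(p, g))
  }
})

test_that("metric identities hold on random mask pairs", {
  for (seed in 1:25) {
    p <- randomBinaryMask(16, 16, seed, p = 0.4)
    g <- randomBinaryMask(16, 16, seed + 500, p = 0.4)
    j <- iou(p, g); d <- dsc(p, g)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_true(j >= 0 && j <= d && d <= 1)
  }
})

test_that("ASSD and Hausdorff are translation invariant away from borders", {
  m <- matrix(FALSE, 30, 30); m[10:14, 10:15] <- TRUE
  g <- matrix(FALSE, 30, 30); g[11:16, 12:16] <- TRUE
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    out[(1 + dr):(20 + dr), (1 + dc):(20 + dc)] <- x[1:20, 1:20]
    out
  }
  expect_equal(assd(m, g), assd(shift(m, 5, 3), shift(g, 5, 3)))
  expect_equal(hausdorff(m, g), hausdorff(shift(m, 5, 3), shift(g, 5, 3)))
})

test_that("cohort reports group by session with Table-style columns", {
  g1 <- makeVolume(domainPreset("target", "S1", height = 32, width = 32,
                                seed = 1), 2)
  g2 <- makeVolume(domainPreset("target", "control", height = 32,
                                width = 32, seed = 2), 2)
  preds <- list(v1 = classMasks(g1$truth), v2 = classMasks(g2$truth))
  gts <- list(v1 = classMasks(g1$truth), v2 = classMasks(g2$truth))
  rep <- evaluateCohort(preds, gts, sessions = c("S1", "control"))
  expect_equal(nrow(rep), 2L)  # one row per session present
  expect_equal(rep$mean_iou, c(1, 1))
  expect_equal(rep$dsc, c(1, 1))
  expect_equal(rep$assd_um, c(0, 0))
  expect_equal(rep$hd_um, c(0, 0))
  expect_equal(rep$sd_iou, c(0, 0))  # single volume per group: sd 0
  expect_true(all(c("iou_epidermis", "dsc_scab") %in% names(rep)))
  names(preds)[2] <- "other"
  expect_error(evaluateCohort(preds, gts, c("S1", "control")), "unpaired")
})
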