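test_that("labelled-subset selection has the sizes the protocol demands", {
  manifest <- data.frame(volume_id = sprintf("v%02d", 1:19),
                         n_bscans = 800L)
  expect_equal(nrow(selectLabeledSubset(manifest, 1L)), 19L)
  expect_equal(nrow(selectLabeledSubset(manifest, 3L)), 57L)
  expect_equal(nrow(selectLabeledSubset(manifest, 0L)), 0L)
  expect_error(selectLabeledSubset(manifest, -1L), ">= 0")
  expect_error(selectLabeledSubset(data.frame(volume_id = "a",
                                              n_bscans = 2L), 3L),
               "exceeds")
  # indices are valid and unique per volume
  s3 <- selectLabeledSubset(manifest, 3L, seed = 4)
  expect_true(all(s3$bscan >= 1 & s3$bscan <= 800))
  expect_false(any(duplicated(s3[, c("volume_id", "bscan")])))
})

test_that("method-2 subsets nest the method-1 subsets at equal seed", {
  manifest <- data.frame(volume_id = letters[1:6], n_bscans = 10L)
  s1 <- selectLabeledSubset(manifest, 1L, seed = 99)
  s3 <- selectLabeledSubset(manifest, 3L, seed = 99)
  key <- function(d) paste(d$volume_id, d$bscan)
  expect_true(all(key(s1) %in% key(s3)))
})

test_that("degenerate schedules leave parameters untouched", {
  m <- buildModel(depth = 2, baseChannels = 4, seed = 2)
  data <- tinyTrainSet(2, size = 16)
  pt <- pretrainSource(m, data, epochs = 0, seed = 1)
  expect_identical(netParams(pt$model), netParams(m))
  expect_length(pt$trace, 0)
  ft0 <- finetuneTarget(m, data, epochs = 0, seed = 1)
  expect_identical(netParams(ft0$model), netParams(m))
  # zero learning rate: any number of epochs changes nothing
  ftz <- finetuneTarget(m, data, lr = 0, epochs = 2, seed = 1)
  expect_identical(netParams(ftz$model), netParams(m))
  expect_error(finetuneTarget(m, list(images = list(),
                                      classMasks = list())),
               "empty")
})

test_that("seeded training is reproducible and reduces the loss", {
  m <- buildModel(depth = 2, baseChannels = 4, seed = 3)
  data <- tinyTrainSet(4, size = 32)
  a <- pretrainSource(m, data, epochs = 6, seed = 21)
  b <- pretrainSource(m, data, epochs = 6, seed = 21)
  expect_identical(a$trace, b$trace)
  expect_identical(netParams(a$model), netParams(b$model))
  expect_length(a$trace, 6)
  expect_lt(a$trace[6], a$trace[1])
})

test_that("fine-tuning lowers the transfer loss on the labelled subset", {
  m <- buildModel(depth = 2, baseChannels = 4, seed = 4)
  src <- tinyTrainSet(4, size = 32)
  pt <- pretrainSource(m, src, epochs = 6, seed = 1)
  tgt <- phantomDataset(4, size = 32, seed0 = 900, domain = "target")
  before <- evalTransferLoss(pt$model, tgt)
  ft <- finetuneTarget(pt$model, tgt, lr = 1e-3, epochs = 8, seed = 1)
  expect_lt(evalTransferLoss(ft$model, tgt), before)
  # fine-tuning never alters the architecture hash
  expect_identical(archHash(ft$model), archHash(m))
})

test_that("strategies record faithful provenance", {
  m <- buildModel(depth = 2, baseChannels = 4, seed = 6)
  cohort <- phantomCohort(5, nBScans = 2, size = 32, seed0 = 40)
  manifest <- data.frame(volume_id = names(cohort), n_bscans = 2L)
  base <- runStrategy("baseline", m, manifest, cohort, seed = 1)
  expect_identical(netParams(base$model), netParams(m))
  expect_null(base$provenance$labeled)
  expect_equal(base$provenance$kPerVolume, 0L)
  m1 <- runStrategy("method1", m, manifest, cohort, epochs = 1, seed = 1)
  expect_equal(nrow(m1$provenance$labeled), 5L)
  expect_error(runStrategy("method9", m, manifest, cohort))
})

test_that("few-label fine-tuning recovers the strategy ordering under domain shift", {
  # reduced-scale analogue: thin/high-contrast source, thick/low-contrast
  # target; one or three labels per target volume
  dice <- sapply(1:2, function(s)
    domainShiftExperiment(seed = s,
                          strategies = c("baseline", "method1", "method2"),
                          nSource = 16L, nTargetVolumes = 4L, nBScans = 4L,
                          pretrainEpochs = 20L)$dice)
  expect_lt(mean(dice["baseline", ]), mean(dice["method1", ]))
  expect_lte(mean(dice["method1", ]), mean(dice["method2", ]) + 0.03)
})
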