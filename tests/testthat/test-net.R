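test_that("the network honours its shape and determinism contracts", {
  m <- buildModel(depth = 3, baseChannels = 8, seed = 11)
  img <- makeBScan(domainPreset("source", "control", height = 64,
                                width = 64, seed = 1))$image
  pr <- predictProbs(m, img)
  expect_s4_class(pr, "ProbMaps")
  expect_equal(dim(objectProbs(pr)), c(64L, 64L, 3L))
  expect_equal(dim(contourProbs(pr)), c(64L, 64L))
  sums <- objectProbs(pr)[, , 1] + objectProbs(pr)[, , 2] +
    objectProbs(pr)[, , 3]
  expect_equal(sums, matrix(1, 64, 64), tolerance = 1e-12)
  expect_true(all(contourProbs(pr) >= 0 & contourProbs(pr) <= 1))
  # seeded initialisation is reproducible
  expect_identical(netParams(buildModel(seed = 11)),
                   netParams(buildModel(seed = 11)))
  expect_false(identical(netParams(buildModel(seed = 11)),
                         netParams(buildModel(seed = 12))))
  # forward refuses sizes not divisible by 2^depth, naming the divisor
  expect_error(predictProbs(m, img[1:60, ]), "2\\^depth = 8")
})

test_that("backpropagation matches finite differences on a tiny network", {
  ns <- asNamespace("octskin")
  set.seed(42)
  m <- buildModel(depth = 2L, baseChannels = 4L, lambda = 1e-3, seed = 7L)
  x4 <- array(stats::runif(8 * 8 * 2), c(8L, 8L, 1L, 2L))
  yo <- array(sample(0:2, 128, TRUE), c(8L, 8L, 2L))
  yc <- array(sample(0:1, 128, TRUE), c(8L, 8L, 2L))
  lg <- ns$.loss_grad_total(m@params, m@state, x4, yo, yc, m@config)
  eps <- 1e-5
  set.seed(1)
  for (nm in sample(names(lg$grads), 12)) {
    k <- sample(length(lg$grads[[nm]]), 1)
    p2 <- m@params
    p2[[nm]][k] <- p2[[nm]][k] + eps
    lp <- ns$.loss_grad_total(p2, m@state, x4, yo, yc, m@config)$loss
    p2[[nm]][k] <- p2[[nm]][k] - 2 * eps
    lm <- ns$.loss_grad_total(p2, m@state, x4, yo, yc, m@config)$loss
    fd <- (lp - lm) / (2 * eps)
    expect_equal(lg$grads[[nm]][k], fd, tolerance = 1e-4)
  }
})

test_that("loss values match the analytic cross-entropy expectations", {
  cm <- randomClassMask(16, 12, 4)
  ctm <- makeContourMask(cm)
  P <- length(cm)
  # uniform predictions: P ln 3 (object) + P ln 2 (contour)
  expect_equal(lossTotal(uniformProbs(16, 12), cm, ctm, lambda = 0),
               P * log(3) + P * log(2), tolerance = 1e-6)
  expect_equal(lossTransfer(array(1 / 3, c(16, 12, 3)), cm), log(3),
               tolerance = 1e-6)
  # perfectly confident correct predictions: zero error
  perfect <- new("ProbMaps", object = oneHot(cm),
                 contour = matrix(as.numeric(ctm), 16, 12))
  expect_equal(lossTotal(perfect, cm, ctm, lambda = 0), 0)
  expect_equal(lossTransfer(oneHot(cm), cm), 0)
  # with zero error and lambda = 1 only the L2 term survives
  m <- buildModel(depth = 2, baseChannels = 4, seed = 3)
  psi <- sum(vapply(grep("_(conv[12]|up[0-9]+|out)_w$",
                         names(netParams(m)), value = TRUE),
                    function(n) sum(netParams(m)[[n]]^2), numeric(1)))
  expect_equal(lossTotal(perfect, cm, ctm, model = m, lambda = 1), psi)
  expect_error(lossTotal(perfect, cm, ctm, lambda = -1), "lambda")
})

test_that("the transfer loss is the object term of the total loss", {
  cm <- randomClassMask(16, 12, 9)
  ctm <- makeContourMask(cm)
  set.seed(2)
  z <- array(stats::rnorm(16 * 12 * 3), c(16, 12, 3))
  ez <- exp(z)
  Po <- ez / array(ez[, , 1] + ez[, , 2] + ez[, , 3], dim(ez))
  # contour probabilities matching the contour mask contribute zero
  probs <- new("ProbMaps", object = Po,
               contour = matrix(as.numeric(ctm), 16, 12))
  expect_equal(lossTotal(probs, cm, ctm, lambda = 0),
               lossTransfer(Po, cm) * length(cm), tolerance = 1e-9)
})

test_that("losses are non-negative and bounded by the clamp", {
  cm <- randomClassMask(8, 8, 1)
  ctm <- makeContourMask(cm)
  wrong <- new("ProbMaps", object = oneHot((cm + 1L) %% 3L),
               contour = matrix(1 - as.numeric(ctm), 8, 8))
  l <- lossTotal(wrong, cm, ctm, lambda = 0)
  expect_gte(l, 0)
  expect_true(is.finite(l))  # clamping keeps -log finite
  expect_gte(lossTransfer(oneHot((cm + 1L) %% 3L), cm), 0)
})

test_that("gradients respect the shared-encoder wiring", {
  ns <- asNamespace("octskin")
  m <- buildModel(depth = 2, baseChannels = 4, seed = 5)
  x4 <- array(stats::runif(16 * 16), c(16L, 16L, 1L, 1L))
  yo <- array(sample(0:2, 256, TRUE), c(16L, 16L, 1L))
  yc <- array(sample(0:1, 256, TRUE), c(16L, 16L, 1L))
  # object-only loss: no contour-head gradients, but encoder gradients
  lg <- ns$.loss_grad_transfer(m@params, m@state, x4, yo, m@config)
  expect_false(any(grepl("^ctr_", names(lg$grads))))
  expect_true(any(grepl("^enc", names(lg$grads))))
  expect_true(any(grepl("^obj_", names(lg$grads))))
  # contour-only loss: no object-head gradients
  fw <- ns$.net_fwd(m@params, m@state, x4, m@config, training = TRUE,
                    heads = "ctr")
  gC <- ns$.sigmoid(fw$ctr)
  gC[, , 1, 1] <- gC[, , 1, 1] - yc[, , 1]
  g2 <- ns$.net_bwd(m@params, fw, m@config, gCtr = gC)
  expect_false(any(grepl("^obj_", names(g2))))
  expect_true(any(grepl("^(enc|bott)", names(g2))))
  # an optimisation step on the object loss leaves A_C bit-identical
  data <- tinyTrainSet(2, size = 16)
  ft <- finetuneTarget(m, list(images = data$images[1:2],
                               classMasks = data$classMasks[1:2]),
                       epochs = 1, seed = 1)
  ctr <- grep("^ctr_", names(netParams(m)), value = TRUE)
  expect_identical(netParams(ft$model)[ctr], netParams(m)[ctr])
  enc <- grep("^enc", names(netParams(m)), value = TRUE)
  expect_false(identical(netParams(ft$model)[enc], netParams(m)[enc]))
})
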