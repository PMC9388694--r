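# The packaged domain-shift benchmark: source-domain pretraining vs
# few-label target-domain fine-tuning, on phantoms with analytic truth.
# This is the desk-scale analogue of the clinical transfer setting -- the
# quantity of interest is the ordering of strategies, not absolute values.

#' Build a phantom dataset of labelled source-domain B-scans
#'
#' Cycles the four sessions (control, S1, S2, S3) across B-scans; each
#' image comes from an independent seeded phantom with class and contour
#' masks derived from the analytic truth.
#'
#' @param n number of B-scans.
#' @param size image height/width in pixels.
#' @param seed0 base seed; image `i` uses `seed0 + i`.
#' @param domain phantom domain preset.
#' @return list with `images`, `classMasks`, `contourMasks`.
#' @export
phantomDataset <- function(n, size = 64L, seed0 = 0L, domain = "source") {
  sessions <- rep(c("control", "S1", "S2", "S3"), length.out = n)
  imgs <- vector("list", n); cms <- vector("list", n)
  ctms <- vector("list", n)
  for (i in seq_len(n)) {
    p <- domainPreset(domain, sessions[i], height = size, width = size,
                      seed = seed0 + i)
    bs <- makeBScan(p)
    imgs[[i]] <- bs$image
    cms[[i]] <- classMasks(bs$truth)[, , 1]
    ctms[[i]] <- makeContourMask(cms[[i]])
  }
  list(images = imgs, classMasks = cms, contourMasks = ctms)
}

#' Build a cohort of phantom volumes with ground truth
#'
#' @param nVolumes number of volumes (sessions cycle across volumes).
#' @param nBScans B-scans per volume.
#' @param size image height/width in pixels.
#' @param seed0 base seed; volume `v` uses `seed0 + v`.
#' @param domain phantom domain preset.
#' @return named list of volumes, each a list with `volume`
#'   ([OCTVolume-class]), `truth` ([PhantomTruth-class]), `session`, and
#'   per-B-scan `images` / `classMasks` lists.
#' @export
phantomCohort <- function(nVolumes, nBScans = 4L, size = 64L, seed0 = 0L,
                          domain = "target") {
  sessions <- rep(c("control", "S1", "S2", "S3"), length.out = nVolumes)
  vols <- list()
  for (v in seq_len(nVolumes)) {
    p <- domainPreset(domain, sessions[v], height = size, width = size,
                      seed = seed0 + v)
    g <- makeVolume(p, nBScans)
    vols[[sprintf("vol%02d", v)]] <- list(
      volume = g$volume, truth = g$truth, session = sessions[v],
      images = lapply(seq_len(nBScans),
                      function(j) volData(g$volume)[, , j]),
      classMasks = lapply(seq_len(nBScans),
                          function(j) classMasks(g$truth)[, , j]))
  }
  vols
}

#' Mean epidermis Dice of a model over a phantom cohort
#'
#' Segments every volume with the pipeline defaults and averages the
#' B-scan-wise Dice of the epidermis class against the analytic truth.
#'
#' @param model a [MultitaskUNet-class].
#' @param cohort a [phantomCohort()] list.
#' @param ... forwarded to [segmentVolume()].
#' @return scalar mean Dice.
#' @export
cohortEpidermisDice <- function(model, cohort, ...) {
  ds <- c()
  for (v in cohort) {
    pred <- segmentVolume(model, v$volume, ...)
    gt <- classMasks(v$truth)
    for (j in seq_len(dim(gt)[3]))
      ds <- c(ds, dsc(pred[, , j] == 1, gt[, , j] == 1))
  }
  mean(ds)
}

#' Run the desk-scale domain-shift experiment
#'
#' Pretrains a multitask U-Net on source-domain phantoms (thin,
#' high-contrast epidermis), then evaluates the requested transfer
#' strategies on a held-out cohort of target-domain phantoms (thick,
#' low-contrast epidermis): `baseline` applies the pretrained model
#' unchanged, `method1`/`method2` fine-tune with one/three labelled
#' B-scans per target volume at a lowered learning rate. Reported is the
#' mean epidermis Dice per strategy.
#'
#' @param seed master seed; all phantom generation, initialisation and
#'   shuffling derive from it.
#' @param strategies subset of `c("baseline", "method1", "method2")`.
#' @param nSource source-domain training B-scans.
#' @param nTargetVolumes target volumes for fine-tuning, and again for
#'   held-out evaluation.
#' @param nBScans B-scans per target volume.
#' @param size B-scan height/width (divisible by `2^depth`).
#' @param depth,baseChannels network size.
#' @param pretrainEpochs,pretrainLr source pretraining schedule.
#' @param finetuneEpochs,finetuneLr transfer schedule.
#' @return list with `dice` (named per strategy), `models`, `pretrace`.
#' @export
domainShiftExperiment <- function(seed = 1L,
                                  strategies = c("baseline", "method1"),
                                  nSource = 32L, nTargetVolumes = 8L,
                                  nBScans = 4L, size = 64L, depth = 3L,
                                  baseChannels = 12L,
                                  pretrainEpochs = 30L, pretrainLr = 3e-3,
                                  finetuneEpochs = 50L, finetuneLr = 1e-4) {
  src <- phantomDataset(nSource, size, seed0 = 10000L * seed,
                        domain = "source")
  tgtTrain <- phantomCohort(nTargetVolumes, nBScans, size,
                            seed0 = 10000L * seed + 1000L)
  tgtTest <- phantomCohort(nTargetVolumes, nBScans, size,
                           seed0 = 10000L * seed + 2000L)
  m0 <- buildModel(depth = depth, baseChannels = baseChannels, seed = seed)
  pt <- pretrainSource(m0, src, epochs = pretrainEpochs, lr = pretrainLr,
                       seed = seed)
  manifest <- data.frame(volume_id = names(tgtTrain), n_bscans = nBScans)
  dice <- c(); models <- list()
  for (s in strategies) {
    rs <- runStrategy(s, pt$model, manifest, tgtTrain,
                      lr = finetuneLr, epochs = finetuneEpochs, seed = seed)
    models[[s]] <- rs$model
    dice[s] <- cohortEpidermisDice(rs$model, tgtTest)
  }
  list(dice = dice, models = models, pretrace = pt$trace)
}
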