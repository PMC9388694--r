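# Three-step transfer strategy: (1) pretrain the multitask network on the
# label-rich source domain with the total loss, (2) select a small labelled
# subset of the target domain (one or three B-scans per volume), (3)
# fine-tune with the transfer loss at a lowered learning rate. The
# no-fine-tuning baseline applies the pretrained model to the target domain
# unchanged.

# datasets are lists: images / classMasks / contourMasks, parallel lists of
# matrices
.check_dataset <- function(data, needContour = TRUE) {
  if (length(data$images) == 0L) stop("dataset is empty")
  stopifnot(length(data$classMasks) == length(data$images))
  if (needContour) stopifnot(length(data$contourMasks) == length(data$images))
  invisible(TRUE)
}

.batch4 <- function(images, idx) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, 1L, length(idx)))
  for (k in seq_along(idx)) x[, , 1L, k] <- images[[idx[k]]]
  x
}

.labels3 <- function(masks, idx) {
  H <- nrow(masks[[1]]); W <- ncol(masks[[1]])
  y <- array(0L, c(H, W, length(idx)))
  for (k in seq_along(idx)) y[, , k] <- masks[[idx[k]]]
  y
}

#' Pretrain the multitask network on source-domain data
#'
#' Minimises the total loss (L2 penalty plus pixel-summed object and
#' contour cross-entropies) with Adam over seeded shuffled mini-batches.
#' Both heads and the shared encoder are updated jointly.
#'
#' @param model a [MultitaskUNet-class] object.
#' @param data list with parallel lists `images`, `classMasks`,
#'   `contourMasks`.
#' @param epochs training epochs; 0 returns the model unchanged.
#' @param batchSize mini-batch size.
#' @param lr Adam learning rate.
#' @param seed seed for shuffling (the loss trace is reproducible).
#' @return list with `model` (trained) and `trace` (mean per-image loss per
#'   epoch, length `epochs`).
#' @export
pretrainSource <- function(model, data, epochs = 30L, batchSize = 4L,
                           lr = 3e-3, seed = 1L) {
  stopifnot(is(model, "MultitaskUNet"))
  .check_dataset(data)
  n <- length(data$images)
  params <- model@params
  state <- model@state
  cfg <- model@config
  opt <- .adam_init()
  trace <- numeric(0)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epLoss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
      lg <- .loss_grad_total(params, state,
                             .batch4(data$images, b),
                             .labels3(data$classMasks, b),
                             .labels3(data$contourMasks, b), cfg)
      state <- lg$state
      st <- .adam_step(params, lg$grads, opt, lr)
      params <- st$params
      opt <- st$opt
      epLoss <- epLoss + lg$loss
    }
    trace <- c(trace, epLoss / n)
  }
  model@params <- params
  model@state <- state
  list(model = model, trace = trace)
}

#' Select the labelled subset of a target manifest
#'
#' Draws `kPerVolume` B-scan indices uniformly at random without
#' replacement from each volume. Selection is nested: for a fixed seed the
#' one-image subset is the first element of the three-image subset, so
#' strategy comparisons share labels.
#'
#' @param manifest data frame with columns `volume_id` and `n_bscans`.
#' @param kPerVolume labelled images per volume (0 returns an empty set).
#' @param seed RNG seed.
#' @return data frame with columns `volume_id` and `bscan` (one row per
#'   selected image; `kPerVolume * nrow(manifest)` rows).
#' @export
selectLabeledSubset <- function(manifest, kPerVolume, seed = 1L) {
  if (kPerVolume < 0L) stop("kPerVolume must be >= 0")
  stopifnot(all(c("volume_id", "n_bscans") %in% names(manifest)))
  if (any(kPerVolume > manifest$n_bscans))
    stop("kPerVolume exceeds the number of B-scans in a volume")
  if (kPerVolume == 0L)
    return(data.frame(volume_id = character(0), bscan = integer(0)))
  set.seed(seed)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    perm <- sample.int(manifest$n_bscans[i])
    data.frame(volume_id = manifest$volume_id[i],
               bscan = perm[seq_len(kPerVolume)])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fine-tune a pretrained network on a labelled target subset
#'
#' Starts from the pretrained parameters and minimises the transfer loss
#' (per-pixel mean 3-class cross-entropy of the object head) with Adam. By
#' default only the object head and the shared encoder receive gradients;
#' the contour head is untouched unless `includeContour = TRUE`.
#'
#' @param model a pretrained [MultitaskUNet-class].
#' @param data list with `images` and `classMasks` (and `contourMasks` when
#'   `includeContour`).
#' @param lr Adam learning rate (lowered relative to pretraining).
#' @param epochs fine-tuning epochs.
#' @param batchSize mini-batch size.
#' @param seed shuffling seed.
#' @param includeContour also fine-tune the contour head with its binary
#'   cross-entropy.
#' @param freezeEncoder update head parameters only.
#' @param valData optional validation dataset; transfer loss is evaluated
#'   on it after every epoch.
#' @return list with `model`, `trace` and (when `valData` given) `valTrace`.
#' @export
finetuneTarget <- function(model, data, lr = 1e-4, epochs = 50L,
                           batchSize = 1L, seed = 1L,
                           includeContour = FALSE, freezeEncoder = FALSE,
                           valData = NULL) {
  stopifnot(is(model, "MultitaskUNet"))
  .check_dataset(data, needContour = includeContour)
  if (length(data$images) == 0L)
    stop("empty labelled subset: use the baseline strategy instead")
  n <- length(data$images)
  params <- model@params
  state <- model@state
  cfg <- model@config
  opt <- .adam_init()
  trace <- numeric(0)
  valTrace <- numeric(0)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epLoss <- 0
    nb <- 0L
    for (b in split(ord, ceiling(seq_along(ord) / batchSize))) {
      lg <- .loss_grad_transfer(params, state,
                                .batch4(data$images, b),
                                .labels3(data$classMasks, b), cfg,
                                includeContour = includeContour,
                                yCtr = if (includeContour)
                                  .labels3(data$contourMasks, b),
                                freezeEncoder = freezeEncoder)
      state <- lg$state
      st <- .adam_step(params, lg$grads, opt, lr)
      params <- st$params
      opt <- st$opt
      epLoss <- epLoss + lg$loss
      nb <- nb + 1L
    }
    trace <- c(trace, epLoss / nb)
    if (!is.null(valData)) {
      m2 <- model
      m2@params <- params
      m2@state <- state
      valTrace <- c(valTrace, evalTransferLoss(m2, valData))
    }
  }
  model@params <- params
  model@state <- state
  out <- list(model = model, trace = trace)
  if (!is.null(valData)) out$valTrace <- valTrace
  out
}

#' Mean transfer loss of a model over a dataset
#'
#' Inference-mode evaluation of the per-pixel mean cross-entropy on the
#' object head; used to compare pretrained and fine-tuned models on the
#' target domain.
#'
#' @param model a [MultitaskUNet-class].
#' @param data list with `images` and `classMasks`.
#' @return scalar mean loss over images.
#' @export
evalTransferLoss <- function(model, data) {
  .check_dataset(data, needContour = FALSE)
  losses <- vapply(seq_along(data$images), function(i) {
    pr <- .predict_batch(model, array(data$images[[i]],
                                      c(dim(data$images[[i]]), 1L, 1L)))
    lossTransfer(pr$object[, , , 1], data$classMasks[[i]])
  }, numeric(1))
  mean(losses)
}

#' Run a transfer strategy end to end
#'
#' `baseline` returns the pretrained parameters untouched (zero labelled
#' target images); `method1` fine-tunes with one labelled B-scan per target
#' volume and `method2` with three. The labelled indices of `method2`
#' contain those of `method1` for the same seed (nested sampling).
#'
#' @param strategy `"baseline"`, `"method1"` or `"method2"`.
#' @param pretrained a pretrained [MultitaskUNet-class].
#' @param targetManifest data frame with `volume_id` and `n_bscans`.
#' @param targetData list of per-volume datasets: for each volume, a list
#'   with `images` and `classMasks` indexed by B-scan.
#' @param lr,epochs fine-tuning settings (ignored by the baseline).
#' @param seed seed for subset selection and shuffling.
#' @return list with `model` and a `provenance` record (strategy, seed,
#'   selected labelled indices, epochs, architecture hash).
#' @export
runStrategy <- function(strategy = c("baseline", "method1", "method2"),
                        pretrained, targetManifest, targetData,
                        lr = 1e-4, epochs = 50L, seed = 1L) {
  strategy <- match.arg(strategy)
  k <- switch(strategy, baseline = 0L, method1 = 1L, method2 = 3L)
  prov <- list(strategy = strategy, kPerVolume = k, seed = seed,
               epochs = if (k > 0L) epochs else 0L,
               archHash = archHash(pretrained), labeled = NULL)
  if (k == 0L)
    return(list(model = pretrained, provenance = prov))
  subset <- selectLabeledSubset(targetManifest, k, seed = seed)
  prov$labeled <- subset
  images <- list(); masks <- list()
  for (r in seq_len(nrow(subset))) {
    vol <- targetData[[subset$volume_id[r]]]
    images[[r]] <- vol$images[[subset$bscan[r]]]
    masks[[r]] <- vol$classMasks[[subset$bscan[r]]]
  }
  ft <- finetuneTarget(pretrained, list(images = images, classMasks = masks),
                       lr = lr, epochs = epochs, seed = seed)
  list(model = ft$model, provenance = prov, trace = ft$trace)
}
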