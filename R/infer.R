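# End-task inference: fusing object and contour probability maps into
# class masks, segmenting whole volumes, and mapping en-face epidermal
# thickness per A-line.

#' Fusion thresholds
#'
#' Four thresholds in `[0, 1]`, all defaulting to 0.5. With the default
#' `tO1 == tO2` the literal fusion rule's epidermis branch is empty (see
#' [fuseEq2()]); a warning is raised at construction when they are equal.
#'
#' @param tO1,tO2 object-map thresholds (`tO1 <= tO2`).
#' @param tC1,tC2 contour-map thresholds.
#' @return named numeric vector of class `fusionThresholds`.
#' @export
fusionThresholds <- function(tO1 = 0.5, tO2 = 0.5, tC1 = 0.5, tC2 = 0.5) {
  th <- c(tO1 = tO1, tO2 = tO2, tC1 = tC1, tC2 = tC2)
  if (any(th < 0 | th > 1)) stop("thresholds must lie in [0, 1]")
  if (tO1 > tO2) stop("tO1 must be <= tO2")
  if (tO1 == tO2)
    warning("tO1 == tO2: the epidermis branch of the literal fusion rule is empty")
  structure(th, class = "fusionThresholds")
}

#' Literal threshold fusion of scalar object and contour maps
#'
#' Per-pixel rule: class 2 (scab) where `No < tO1` and `Nc < tC1`; class 1
#' (epidermis) where `tO1 <= No < tO2` and `Nc < tC2`; class 0 otherwise.
#' With all four thresholds at their default 0.5 the epidermis branch is
#' empty -- kept as a documented, testable property of the printed rule;
#' [fusePractical()] is the pipeline default.
#'
#' @param No numeric matrix, scalar object probability map.
#' @param Nc numeric matrix, contour probability map (same shape).
#' @param th a [fusionThresholds()] vector.
#' @return integer class mask.
#' @export
fuseEq2 <- function(No, Nc, th = suppressWarnings(fusionThresholds())) {
  if (!identical(dim(No), dim(Nc)))
    stop("object and contour maps must share shape")
  out <- matrix(0L, nrow(No), ncol(No))
  out[No < th["tO1"] & Nc < th["tC1"]] <- 2L
  out[No >= th["tO1"] & No < th["tO2"] & Nc < th["tC2"]] <- 1L
  out
}

#' Practical fusion of probability maps
#'
#' Class is the argmax over the 3-channel object map, refined by the
#' contour map: pixels whose contour probability reaches `tC1`
#' (boundary-uncertain pixels) are reassigned to the class of the nearest
#' non-contour pixel along their A-line, breaking distance ties toward the
#' smaller class index. Reassignment reaches at most `maxShiftPx` pixels
#' from an anchor -- the half-width of the training contour band -- since a
#' pixel farther than that from every non-contour pixel cannot belong to a
#' genuine band and keeps its object-head class. Without this cap, merged
#' bands around the two boundaries of a layer thinner than about the band
#' width would erase the layer entirely. A-lines that are contour
#' everywhere keep their argmax classes.
#'
#' @param probs a [ProbMaps-class] object.
#' @param th a [fusionThresholds()] vector (only `tC1` is used).
#' @param maxShiftPx reassignment reach in pixels; defaults to the
#'   half-width of the 5-px contour band.
#' @return integer class mask.
#' @export
fusePractical <- function(probs, th = suppressWarnings(fusionThresholds()),
                          maxShiftPx = 2L) {
  stopifnot(is(probs, "ProbMaps"))
  Po <- probs@object
  cls <- .argmax3(Po)
  unc <- probs@contour >= th["tC1"]
  if (!any(unc)) return(cls)
  for (j in seq_len(ncol(cls))) {
    u <- which(unc[, j])
    if (length(u) == 0L) next
    anchor <- which(!unc[, j])
    if (length(anchor) == 0L) next
    for (i in u) {
      d <- abs(anchor - i)
      if (min(d) > maxShiftPx) next
      near <- anchor[d == min(d)]
      cls[i, j] <- min(cls[near, j])
    }
  }
  cls
}

.argmax3 <- function(Po) {
  cls <- matrix(0L, dim(Po)[1], dim(Po)[2])
  best <- Po[, , 1]
  for (k in 2:3) {
    better <- Po[, , k] > best
    cls[better] <- k - 1L
    best[better] <- Po[, , k][better]
  }
  cls
}

# reflect-pad a matrix up to sizes divisible by m, segment, crop back
.pad_reflect <- function(img, m) {
  H <- nrow(img); W <- ncol(img)
  H2 <- ceiling(H / m) * m
  W2 <- ceiling(W / m) * m
  if (H2 > H) img <- rbind(img, img[H - seq_len(H2 - H) + 1L, , drop = FALSE])
  if (W2 > W) img <- cbind(img, img[, W - seq_len(W2 - W) + 1L, drop = FALSE])
  img
}

#' Segment an OCT volume
#'
#' Forward pass per B-scan in inference mode, fusion of the probability
#' maps, and optional per-class largest-connected-component cleanup that
#' suppresses misclassified islands. The default fusion is the plain
#' object-head argmax: on layered phantoms the contour-guided pixel
#' rewrite of [fusePractical()] systematically erodes boundary rows of
#' layers not much thicker than the contour band, so the contour task
#' contributes through the shared encoder during training rather than at
#' fusion time; `"practical"` and the literal `"eq2"` rule remain
#' selectable. B-scans whose size is not divisible by `2^depth` are
#' reflect-padded and cropped back.
#'
#' @param model a [MultitaskUNet-class].
#' @param volume an [OCTVolume-class] or a 3-d array.
#' @param fusion `"argmax"`, `"practical"` or `"eq2"`. The literal rule
#'   needs a scalar object map; the background channel probability is used.
#' @param th a [fusionThresholds()] vector.
#' @param cleanup suppress misclassified islands: per foreground class,
#'   drop connected components smaller than 1/8 of that class's largest
#'   component.
#' @return integer array of class masks, same shape as the volume.
#' @export
segmentVolume <- function(model, volume,
                          fusion = c("argmax", "practical", "eq2"),
                          th = suppressWarnings(fusionThresholds()),
                          cleanup = TRUE) {
  fusion <- match.arg(fusion)
  vol <- if (is(volume, "OCTVolume")) volData(volume) else .stack3(volume)
  d <- dim(vol)
  m <- 2^model@config$depth
  out <- array(0L, d)
  for (j in seq_len(d[3])) {
    img <- .pad_reflect(vol[, , j], m)
    x4 <- array(img, c(dim(img), 1L, 1L))
    pr <- .predict_batch(model, x4)
    probs <- new("ProbMaps", object = pr$object[, , , 1],
                 contour = pr$contour[, , 1, 1])
    mask <- switch(fusion,
      argmax = .argmax3(probs@object),
      practical = fusePractical(probs, th),
      eq2 = fuseEq2(probs@object[, , 1], probs@contour, th))
    mask <- mask[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
    if (cleanup)
      for (k in 1:2) {
        sel <- mask == k
        keep <- .drop_islands(sel)
        mask[sel & !keep] <- 0L
      }
    out[, , j] <- mask
  }
  out
}

#' En-face epidermal thickness map from class masks
#'
#' Per A-line, the thickness in pixels is `bottom - top + 1` of the largest
#' contiguous run of epidermis pixels (ties broken toward the shallower
#' run, robust to speckle islands). A-lines without epidermis are
#' undefined (`NA`) and excluded from statistics.
#'
#' @param masks integer class-mask stack `(depth, width, nBScans)`, a
#'   single matrix, or a [PhantomTruth-class].
#' @param pitchUm axial pitch, micrometres per pixel.
#' @return a [ThicknessMap-class].
#' @export
thicknessMap <- function(masks, pitchUm = 8) {
  if (is(masks, "PhantomTruth")) masks <- classMasks(masks)
  masks <- .stack3(masks)
  d <- dim(masks)
  px <- matrix(NA_real_, d[2], d[3])
  for (j in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      r <- rle(masks[, x, j] == 1L)
      if (!any(r$values)) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]  # which.max: shallower on tie
      px[x, j] <- ends[best] - starts[best] + 1L
    }
  }
  new("ThicknessMap", px = px, pitchUm = pitchUm)
}

#' Mean epidermal thickness of a map
#'
#' @param map a [ThicknessMap-class].
#' @param region optional logical matrix over the en-face grid restricting
#'   the statistic.
#' @return named numeric: `meanUm`, `sdUm` (0 for a single valid A-line)
#'   and `n` (valid A-lines used).
#' @export
meanThickness <- function(map, region = NULL) {
  stopifnot(is(map, "ThicknessMap"))
  v <- thicknessUm(map)
  if (!is.null(region)) {
    stopifnot(identical(dim(region), dim(v)))
    v[!region] <- NA_real_
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("mean thickness is undefined: no valid A-lines in the region")
  c(meanUm = mean(v), sdUm = if (length(v) > 1L) stats::sd(v) else 0,
    n = length(v))
}

#' Volume-wise deviation of mean epidermal thickness
#'
#' For each predicted/truth map pair the absolute difference of the mean
#' thickness (micrometres) is taken; pairs are then aggregated as
#' mean +/- sd across volumes (sd 0 for a single pair). Symmetric in its
#' arguments.
#'
#' @param pred a [ThicknessMap-class] or list of them.
#' @param truth matching map or list.
#' @return named numeric: `meanUm`, `sdUm`, `n` (pairs).
#' @export
thicknessDeviation <- function(pred, truth) {
  if (is(pred, "ThicknessMap")) pred <- list(pred)
  if (is(truth, "ThicknessMap")) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  devs <- vapply(seq_along(pred), function(i) {
    if (!identical(dim(thicknessPx(pred[[i]])),
                   dim(thicknessPx(truth[[i]]))))
      stop("prediction and truth maps must share the en-face grid")
    abs(meanThickness(pred[[i]])["meanUm"] -
          meanThickness(truth[[i]])["meanUm"])
  }, numeric(1))
  c(meanUm = mean(devs), sdUm = if (length(devs) > 1L) stats::sd(devs) else 0,
    n = length(devs))
}
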