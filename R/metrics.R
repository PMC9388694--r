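# Segmentation evaluation: overlap (IoU, Dice), surface distances (ASSD,
# Hausdorff) and cohort reporting. Surface distances are Euclidean in
# isotropic pixel space, then scaled by the axial pitch to micrometres.
# Conventions (documented): a pair of empty masks is perfect agreement
# (IoU = DSC = 1, ASSD = HD = 0); image-border pixels of a full-foreground
# mask count as surface (masks are treated as padded by background).

#' Intersection over union of two binary masks
#'
#' `|pred & gt| / |pred | gt|`; 1 when both masks are empty.
#'
#' @param pred,gt logical or 0/1 matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
iou <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("masks must share shape")
  pred <- pred > 0; gt <- gt > 0
  u <- sum(pred | gt)
  if (u == 0L) return(1)
  sum(pred & gt) / u
}

#' Dice similarity coefficient
#'
#' Computed directly as `2|pred & gt| / (|pred| + |gt|)` and checked
#' against the algebraic identity `2 IoU / (1 + IoU)`; 1 when both masks
#' are empty.
#'
#' @inheritParams iou
#' @return scalar in `[0, 1]`.
#' @export
dsc <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("masks must share shape")
  pred <- pred > 0; gt <- gt > 0
  s <- sum(pred) + sum(gt)
  if (s == 0L) return(1)
  d <- 2 * sum(pred & gt) / s
  j <- iou(pred, gt)
  stopifnot(abs(d - 2 * j / (1 + j)) < 1e-12)
  d
}

#' Surface points of a binary mask
#'
#' Foreground pixels with at least one background 4-neighbour; pixels on
#' the image border are surface (the outside counts as background).
#' Returned in deterministic row-major order.
#'
#' @param mask logical or 0/1 matrix.
#' @return two-column integer matrix of `(row, col)` coordinates; zero rows
#'   for an empty mask.
#' @export
surfacePoints <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  hasbg <- !pad[1:H, 2:(W + 1L)] | !pad[3:(H + 2L), 2:(W + 1L)] |
    !pad[2:(H + 1L), 1:W] | !pad[2:(H + 1L), 3:(W + 2L)]
  surf <- inner & hasbg
  idx <- which(t(surf))  # row-major ordering
  cbind(row = (idx - 1L) %/% W + 1L, col = (idx - 1L) %% W + 1L)
}

# distance from every pixel to the nearest surface point of `mask`,
# via a Euclidean distance map with the surface points as background seeds
.surface_distmap <- function(mask) {
  sp <- surfacePoints(mask)
  seed <- matrix(1, nrow(mask), ncol(mask))
  seed[sp] <- 0
  EBImage::distmap(seed, metric = "euclidean")
}

.directed_dists <- function(fromMask, toDistmap) {
  sp <- surfacePoints(fromMask)
  toDistmap[sp]
}

#' Average symmetric surface distance
#'
#' `(sum_p d(p, S_gt) + sum_q d(q, S_pred)) / (n1 + n2)` over the two
#' surface point sets, Euclidean in pixel space, scaled to micrometres.
#'
#' @inheritParams iou
#' @param pitchUm axial pitch, micrometres per pixel.
#' @return scalar distance in micrometres.
#' @export
assd <- function(pred, gt, pitchUm = 8) {
  if (!identical(dim(pred), dim(gt))) stop("masks must share shape")
  if (sum(pred > 0) == 0L && sum(gt > 0) == 0L) return(0)
  if (sum(pred > 0) == 0L || sum(gt > 0) == 0L)
    stop("surface distance is undefined for a single empty mask")
  dPG <- .directed_dists(pred, .surface_distmap(gt))
  dGP <- .directed_dists(gt, .surface_distmap(pred))
  (sum(dPG) + sum(dGP)) / (length(dPG) + length(dGP)) * pitchUm
}

#' Hausdorff distance
#'
#' Maximum of the two directed maxima of nearest-surface distances, scaled
#' to micrometres. Symmetric; sensitive to outliers by design.
#'
#' @inheritParams assd
#' @return scalar distance in micrometres.
#' @export
hausdorff <- function(pred, gt, pitchUm = 8) {
  if (!identical(dim(pred), dim(gt))) stop("masks must share shape")
  if (sum(pred > 0) == 0L && sum(gt > 0) == 0L) return(0)
  if (sum(pred > 0) == 0L || sum(gt > 0) == 0L)
    stop("surface distance is undefined for a single empty mask")
  dPG <- .directed_dists(pred, .surface_distmap(gt))
  dGP <- .directed_dists(gt, .surface_distmap(pred))
  max(max(dPG), max(dGP)) * pitchUm
}

# metrics of one mask pair; surface metrics NA when exactly one side empty
.pair_metrics <- function(pred, gt, pitchUm) {
  oneEmpty <- xor(sum(pred > 0) == 0L, sum(gt > 0) == 0L)
  c(iou = iou(pred, gt), dsc = dsc(pred, gt),
    assd_um = if (oneEmpty) NA_real_ else assd(pred, gt, pitchUm),
    hd_um = if (oneEmpty) NA_real_ else hausdorff(pred, gt, pitchUm))
}

#' Cohort evaluation report
#'
#' Per-volume metrics are computed B-scan-wise on the union of the
#' foreground classes (epidermis and scab) and averaged within the volume;
#' per-class IoU/Dice breakdowns are included. Volumes are grouped by
#' session and summarised as mean +/- sd (sd 0 for a single volume). One
#' report row per session present.
#'
#' @param predVolumes,gtVolumes named lists of class-mask stacks
#'   `(depth, width, nBScans)`; names pair predictions with ground truth.
#' @param sessions character vector of session tags, parallel to
#'   `predVolumes`.
#' @param pitchUm axial pitch, micrometres per pixel.
#' @return data frame with columns `group`, `n`, `mean_iou`, `dsc`,
#'   `assd_um`, `hd_um` (each with an `sd_` companion) and per-class
#'   `iou_epidermis`, `dsc_epidermis`, `iou_scab`, `dsc_scab`.
#' @export
evaluateCohort <- function(predVolumes, gtVolumes, sessions, pitchUm = 8) {
  stopifnot(length(predVolumes) == length(gtVolumes),
            length(sessions) == length(predVolumes))
  if (!is.null(names(predVolumes)) && !is.null(names(gtVolumes))) {
    if (!setequal(names(predVolumes), names(gtVolumes)))
      stop("unpaired volume ids between predictions and ground truth")
    gtVolumes <- gtVolumes[names(predVolumes)]
  }
  perVol <- lapply(seq_along(predVolumes), function(v) {
    p <- .stack3(predVolumes[[v]]); g <- .stack3(gtVolumes[[v]])
    if (!identical(dim(p), dim(g))) stop("paired volumes must share shape")
    rows <- vapply(seq_len(dim(p)[3]), function(j) {
      c(.pair_metrics(p[, , j] > 0, g[, , j] > 0, pitchUm),
        iou_epidermis = iou(p[, , j] == 1, g[, , j] == 1),
        dsc_epidermis = dsc(p[, , j] == 1, g[, , j] == 1),
        iou_scab = iou(p[, , j] == 2, g[, , j] == 2),
        dsc_scab = dsc(p[, , j] == 2, g[, , j] == 2))
    }, numeric(8))
    rowMeans(rows, na.rm = TRUE)
  })
  perVol <- do.call(rbind, perVol)
  out <- lapply(unique(sessions), function(s) {
    m <- perVol[sessions == s, , drop = FALSE]
    sds <- if (nrow(m) > 1L) apply(m[, 1:4, drop = FALSE], 2, stats::sd)
           else rep(0, 4)
    data.frame(group = s, n = nrow(m),
               mean_iou = mean(m[, "iou"]), sd_iou = sds[1],
               dsc = mean(m[, "dsc"]), sd_dsc = sds[2],
               assd_um = mean(m[, "assd_um"]), sd_assd = sds[3],
               hd_um = mean(m[, "hd_um"]), sd_hd = sds[4],
               iou_epidermis = mean(m[, "iou_epidermis"]),
               dsc_epidermis = mean(m[, "dsc_epidermis"]),
               iou_scab = mean(m[, "iou_scab"]),
               dsc_scab = mean(m[, "dsc_scab"]))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
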