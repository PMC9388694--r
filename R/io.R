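# Formats and bookkeeping: multi-page TIFF volumes with a JSON metadata
# sidecar, PNG label masks with literal pixel values, CSV-style manifests
# with Table-1-style summary arithmetic, train/validation splits,
# checkpoints guarded by an architecture hash, and provenance records.

.sidecar <- function(path) paste0(path, ".json")

#' Write an OCT volume as multi-page TIFF
#'
#' One 16-bit page per B-scan plus a JSON sidecar (`<path>.json`) holding
#' the pixel pitch and shape so metadata round-trips through write/read.
#'
#' @param volume an [OCTVolume-class] (values in `[0, 1]`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "OCTVolume"))
  v <- volData(volume)
  pages <- lapply(seq_len(dim(v)[3]), function(j) v[, , j])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pitchUm = pitchUm(volume), shape = dim(v)),
                       .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' Pages must share one shape; the pitch comes from the JSON sidecar and
#' falls back to 8 um/px with a warning when the sidecar is missing.
#'
#' @param path TIFF file path.
#' @return an [OCTVolume-class].
#' @export
readVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  for (j in seq_along(pages))
    if (!identical(dim(pages[[j]]), d1))
      stop(sprintf("page %d has shape %s, expected %s", j,
                   paste(dim(pages[[j]]), collapse = "x"),
                   paste(d1, collapse = "x")))
  pitch <- 8
  if (file.exists(.sidecar(path))) {
    meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
    pitch <- meta$pitchUm
  } else {
    warning("no metadata sidecar found; assuming a pitch of 8 um/px")
  }
  vol <- array(unlist(pages), c(d1, length(pages)))
  new("OCTVolume", data = vol, pitchUm = pitch)
}

#' Write / read a label mask as PNG
#'
#' Single-channel 8-bit PNG with literal pixel values (0/1/2 for class
#' masks, 0/1 for contour masks). A palette for display is a viewer
#' concern, not a storage one.
#'
#' @param mask integer matrix of small non-negative labels.
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a phantom volume with its ground truth
#'
#' The volume goes to `<prefix>.tiff`, per-B-scan class masks to
#' `<prefix>_mask_###.png`, and boundaries plus generation parameters
#' (including the seed, sufficient for exact regeneration) to
#' `<prefix>_truth.json`.
#'
#' @param volume an [OCTVolume-class].
#' @param truth the matching [PhantomTruth-class].
#' @param params the [PhantomParams-class] used to generate them.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return the TIFF path, invisibly.
#' @export
writePhantom <- function(volume, truth, params, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, prefix)
  writeVolume(volume, paste0(base, ".tiff"))
  cm <- classMasks(truth)
  for (j in seq_len(dim(cm)[3]))
    writeMaskPNG(cm[, , j], sprintf("%s_mask_%03d.png", base, j))
  pn <- slotNames(params)
  pl <- stats::setNames(lapply(pn, function(s) slot(params, s)), pn)
  jsonlite::write_json(
    list(params = pl, boundaries = boundaries(truth)),
    paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA,
    matrix = "columnmajor")
  invisible(paste0(base, ".tiff"))
}

#' Build a volume manifest with summary counts
#'
#' @param specs data frame with columns `volume_id`, `domain`, `session`,
#'   `n_bscans`, `split` and optionally `n_labeled`.
#' @return list with `manifest` (the validated data frame) and `summary`
#'   (total images per domain and split, and labelled totals).
#' @export
buildManifest <- function(specs) {
  need <- c("volume_id", "domain", "session", "n_bscans", "split")
  stopifnot(all(need %in% names(specs)))
  if (anyDuplicated(specs$volume_id))
    stop("duplicate volume ids in manifest")
  totals <- stats::aggregate(
    list(images = specs$n_bscans),
    by = list(domain = specs$domain, split = specs$split), FUN = sum)
  summary <- list(totalImages = sum(specs$n_bscans),
                  imagesBySplit = totals,
                  nVolumes = nrow(specs))
  if ("n_labeled" %in% names(specs))
    summary$totalLabeled <- sum(specs$n_labeled)
  list(manifest = specs, summary = summary)
}

#' Split a labelled set into training and validation halves
#'
#' Seeded shuffle, then the first `ceiling(fraction * n)` items train and
#' the rest validate; disjoint and exhaustive.
#'
#' @param ids vector of item identifiers.
#' @param fraction training fraction in `(0, 1)`.
#' @param seed RNG seed.
#' @return list with `train` and `val`.
#' @export
splitTrainVal <- function(ids, fraction = 0.5, seed = 1L) {
  if (length(ids) == 0L) stop("empty labelled set")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  ord <- sample(ids)
  nTrain <- ceiling(fraction * length(ids))
  if (nTrain == length(ids))
    warning("validation split is empty at this fraction and size")
  list(train = ord[seq_len(nTrain)],
       val = if (nTrain < length(ids)) ord[(nTrain + 1L):length(ids)]
             else ids[0])
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores config, seed, parameters and running statistics;
#' a JSON manifest next to it records the architecture hash and package
#' version, and [loadModel()] refuses checkpoints whose hash disagrees
#' with their manifest.
#'
#' @param model a [MultitaskUNet-class].
#' @param path checkpoint path (`.rds`).
#' @return `path` invisibly for `saveModel`; the model for `loadModel`.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "MultitaskUNet"))
  saveRDS(model, path)
  jsonlite::write_json(
    list(archHash = archHash(model), config = model@config,
         package = as.character(packageVersion("octskin"))),
    .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "MultitaskUNet"))
  if (file.exists(.sidecar(path))) {
    meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
    if (!identical(meta$archHash, archHash(model)))
      stop(sprintf("architecture mismatch: checkpoint %s, manifest %s",
                   archHash(model), meta$archHash))
  }
  model
}

#' Write a provenance record
#'
#' Serialises a run configuration (seeds included) plus the package
#' version to JSON; a run is reproducible from this record alone.
#'
#' @param config named list of run settings.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeProvenance <- function(config, path) {
  jsonlite::write_json(
    c(config, list(package = as.character(packageVersion("octskin")),
                   written = format(Sys.time(), tz = "UTC"))),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
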