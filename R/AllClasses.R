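# S4 containers for volumes, phantom ground truth, network outputs and
# en-face thickness maps. B-scan arrays are (depth row, lateral column);
# row 1 is the shallowest. En-face grids are (lateral column, B-scan index).

#' OCT volume container
#'
#' A 3-d grayscale stack of B-scans, `(depth, lateral, B-scan)`, values in
#' `[0, 1]`, with the axial pixel pitch in micrometres per pixel attached.
#' Each column of a B-scan is an A-line (one depth profile).
#'
#' @slot data numeric array `(depth, width, nBScans)`.
#' @slot pitchUm axial pixel pitch, micrometres per pixel.
#' @export
setClass("OCTVolume",
  representation(data = "array", pitchUm = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-d array (depth, width, nBScans)")
    if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
        object@pitchUm <= 0) return("pitchUm must be a single positive number")
    TRUE
  })

#' Analytic phantom ground truth
#'
#' Layer boundaries, class masks and the en-face thickness map emitted with
#' every synthetic volume. `upper` is the first epidermis row per A-line and
#' `lower` the first dermis row (half-open interval), so the epidermal
#' thickness in pixels is exactly `lower - upper`. Scab boundaries are `NA`
#' where no scab is present.
#'
#' @slot classMasks integer array `(depth, width, nBScans)` with labels
#'   0 (background/other), 1 (epidermis), 2 (scab).
#' @slot upper,lower integer matrices `(width, nBScans)` of epidermis
#'   boundary rows (upper inclusive, lower exclusive).
#' @slot scabTop,scabBottom numeric matrices `(width, nBScans)`; `NA` where
#'   absent. Scab occupies rows `scabTop .. scabBottom` (inclusive),
#'   `scabBottom == upper - 1`.
#' @slot thicknessPx numeric matrix `(width, nBScans)`.
#' @export
setClass("PhantomTruth",
  representation(classMasks = "array", upper = "matrix", lower = "matrix",
                 scabTop = "matrix", scabBottom = "matrix",
                 thicknessPx = "matrix"),
  validity = function(object) {
    if (!all(object@classMasks %in% c(0L, 1L, 2L)))
      return("class labels must be in {0, 1, 2}")
    if (!all(object@lower > object@upper))
      return("lower boundary must lie strictly below upper boundary")
    if (!isTRUE(all.equal(unname(object@thicknessPx),
                          unname(object@lower - object@upper))))
      return("thicknessPx must equal lower - upper")
    TRUE
  })

#' Network probability maps
#'
#' Per-pixel outputs of the multitask network for one B-scan: a 3-channel
#' softmax object map over (background, epidermis, scab) and a single
#' sigmoid contour probability.
#'
#' @slot object numeric array `(depth, width, 3)`; channels sum to 1.
#' @slot contour numeric matrix `(depth, width)` in `[0, 1]`.
#' @export
setClass("ProbMaps",
  representation(object = "array", contour = "matrix"),
  validity = function(object) {
    d <- dim(object@object)
    if (length(d) != 3L || d[3] != 3L)
      return("object map must be (depth, width, 3)")
    if (!identical(d[1:2], dim(object@contour)))
      return("object and contour maps must share spatial shape")
    if (any(object@object < -1e-8) || any(object@object > 1 + 1e-8) ||
        any(object@contour < -1e-8) || any(object@contour > 1 + 1e-8))
      return("probabilities must lie in [0, 1]")
    s <- object@object[, , 1] + object@object[, , 2] + object@object[, , 3]
    if (max(abs(s - 1)) > 1e-6)
      return("object channels must sum to 1 per pixel")
    TRUE
  })

#' En-face epidermal thickness map
#'
#' Per-A-line epidermal thickness on the `(lateral, B-scan)` grid. Entries
#' are `NA` where the A-line contains no epidermis; such entries are
#' excluded from all statistics. The micrometre view is
#' `thicknessPx(x) * pitchUm(x)`.
#'
#' @slot px numeric matrix `(width, nBScans)`, pixels; `NA` = undefined.
#' @slot pitchUm axial pixel pitch, micrometres per pixel.
#' @export
setClass("ThicknessMap",
  representation(px = "matrix", pitchUm = "numeric"),
  validity = function(object) {
    if (any(object@px < 0, na.rm = TRUE)) return("thickness must be >= 0")
    if (length(object@pitchUm) != 1L || object@pitchUm <= 0)
      return("pitchUm must be a single positive number")
    TRUE
  })

#' Multitask U-Net model
#'
#' Shared-encoder U-Net with two decoder heads: a 3-class object head and a
#' binary contour head. Parameters live in a flat named list; names starting
#' `enc`/`bott` form the shared encoder, `obj_` the object head and `ctr_`
#' the contour head. `state` holds batch-normalisation running statistics
#' used at inference. `archHash` identifies the architecture so checkpoints
#' are refused by mismatched configurations.
#'
#' @slot config list: `depth`, `baseChannels`, `slope`, `lambda`, `seed`.
#' @slot params named list of parameter arrays.
#' @slot state named list of running BN statistics.
#' @slot archHash character architecture identifier.
#' @export
setClass("MultitaskUNet",
  representation(config = "list", params = "list", state = "list",
                 archHash = "character"),
  validity = function(object) {
    cf <- object@config
    need <- c("depth", "baseChannels", "slope", "lambda")
    if (!all(need %in% names(cf)))
      return(paste("config must contain", paste(need, collapse = ", ")))
    if (cf$depth < 1L) return("depth must be >= 1")
    if (cf$baseChannels < 4L) return("baseChannels must be >= 4")
    if (cf$lambda < 0) return("lambda must be >= 0")
    TRUE
  })

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("OCTVolume: %d x %d px B-scans, %d B-scans, pitch %.3g um/px\n",
              d[1], d[2], d[3], object@pitchUm))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@classMasks)
  cat(sprintf("PhantomTruth: %d x %d px, %d B-scans; scab %s\n",
              d[1], d[2], d[3],
              if (any(!is.na(object@scabTop))) "present" else "absent"))
})

setMethod("show", "ThicknessMap", function(object) {
  v <- object@px[!is.na(object@px)]
  cat(sprintf("ThicknessMap: %d x %d A-lines, %d valid; pitch %.3g um/px\n",
              nrow(object@px), ncol(object@px), length(v), object@pitchUm))
  if (length(v))
    cat(sprintf("  thickness %.1f +/- %.1f um\n",
                mean(v) * object@pitchUm,
                if (length(v) > 1L) stats::sd(v) * object@pitchUm else 0))
})

setMethod("show", "MultitaskUNet", function(object) {
  cf <- object@config
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "MultitaskUNet: depth %d, base %d channels, %d parameters (hash %s)\n",
    cf$depth, cf$baseChannels, np, object@archHash))
})
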