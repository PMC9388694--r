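# Synthetic layered-skin OCT phantoms with analytic ground truth.
#
# A B-scan is simulated as a piecewise-constant reflectivity field (air,
# optional scab cap, epidermis band, dermis) attenuated exponentially with
# depth below the tissue entry point, multiplied by gamma-distributed
# speckle and perturbed by additive Gaussian noise. Layer boundaries are
# smoothed random fields, so masks and thickness maps are known exactly.

#' Phantom generation parameters
#'
#' All geometry is in pixels; reflectivities are mean backscatter levels in
#' `[0, 1]`. The epidermis occupies rows `upper .. lower-1` per A-line
#' (half-open), the scab -- when enabled -- sits directly on top of the
#' epidermis, and dermis fills the rest of the image below. Thickness
#' profiles are smoothed random fields clamped to `[epiMinPx, epiMaxPx]`,
#' which encodes the domain's thickness regime (thin source-domain
#' epidermis vs thick target-domain epidermis).
#'
#' @slot domain `"source"` or `"target"`.
#' @slot session `"S1"`, `"S2"`, `"S3"` (wound stages with shrinking scab)
#'   or `"control"` (no scab).
#' @slot height,width image size in pixels (depth rows, A-line columns).
#' @slot pitchUm axial pixel pitch, micrometres per pixel.
#' @slot surfaceDepthPx mean depth of the skin surface.
#' @slot surfaceAmpPx,surfaceCorrPx amplitude and lateral correlation length
#'   of the surface undulation.
#' @slot epiMeanPx,epiVarPx,epiCorrPx,epiMinPx,epiMaxPx epidermal thickness
#'   profile: mean, lateral variation amplitude, correlation length, and the
#'   hard clamp range defining the domain regime.
#' @slot scab logical; scab cap present.
#' @slot scabMeanPx,scabVarPx scab thickness profile.
#' @slot scabExtentFrac lateral fraction of the image covered by the
#'   (centred) scab.
#' @slot reflAir,reflScab,reflEpi,reflDermis layer mean reflectivities.
#' @slot attenPerPx attenuation coefficient per pixel of depth in tissue.
#' @slot speckleShape gamma shape of the multiplicative speckle (mean 1);
#'   0 disables speckle.
#' @slot noiseSigma additive Gaussian noise sd.
#' @slot seed RNG seed; equal (params, seed) gives bit-identical output.
#' @export
setClass("PhantomParams",
  representation(domain = "character", session = "character",
                 height = "integer", width = "integer", pitchUm = "numeric",
                 surfaceDepthPx = "numeric", surfaceAmpPx = "numeric",
                 surfaceCorrPx = "numeric",
                 epiMeanPx = "numeric", epiVarPx = "numeric",
                 epiCorrPx = "numeric", epiMinPx = "numeric",
                 epiMaxPx = "numeric",
                 scab = "logical", scabMeanPx = "numeric",
                 scabVarPx = "numeric", scabExtentFrac = "numeric",
                 reflAir = "numeric", reflScab = "numeric",
                 reflEpi = "numeric", reflDermis = "numeric",
                 attenPerPx = "numeric", speckleShape = "numeric",
                 noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@domain %in% c("source", "target"))
      return("domain must be 'source' or 'target'")
    if (!object@session %in% c("S1", "S2", "S3", "control"))
      return("session must be one of S1, S2, S3, control")
    if (object@height < 16L || object@width < 16L)
      return("height and width must be >= 16")
    if (object@pitchUm <= 0) return("pitchUm must be > 0")
    refl <- c(object@reflAir, object@reflScab, object@reflEpi,
              object@reflDermis)
    if (any(refl < 0 | refl > 1)) return("reflectivities must lie in [0, 1]")
    if (object@epiMinPx < 1) return("epiMinPx must be >= 1")
    if (object@epiMaxPx < object@epiMinPx)
      return("epiMaxPx must be >= epiMinPx")
    if (object@scab && object@scabMeanPx < 1)
      return("scabMeanPx must be >= 1 when scab is enabled")
    if (object@scabExtentFrac < 0 || object@scabExtentFrac > 1)
      return("scabExtentFrac must lie in [0, 1]")
    if (object@speckleShape < 0 || object@noiseSigma < 0)
      return("noise parameters must be >= 0")
    TRUE
  })

#' Construct phantom parameters
#'
#' Low-level constructor; most users should start from [domainPreset()].
#'
#' @param domain,session domain and session tags.
#' @param height,width image size in pixels.
#' @param pitchUm axial pixel pitch (micrometres per pixel).
#' @param surfaceDepthPx,surfaceAmpPx,surfaceCorrPx surface profile.
#' @param epiMeanPx,epiVarPx,epiCorrPx,epiMinPx,epiMaxPx epidermal thickness
#'   profile and clamp range.
#' @param scab,scabMeanPx,scabVarPx,scabExtentFrac scab cap settings.
#' @param reflAir,reflScab,reflEpi,reflDermis layer reflectivities in
#'   `[0, 1]`.
#' @param attenPerPx attenuation per pixel of depth in tissue.
#' @param speckleShape gamma speckle shape (0 = off).
#' @param noiseSigma additive noise sd.
#' @param seed RNG seed.
#' @return a [PhantomParams-class] object.
#' @export
phantomParams <- function(domain = "target", session = "control",
                          height = 128L, width = 128L, pitchUm = 8,
                          surfaceDepthPx = height / 4, surfaceAmpPx = 3,
                          surfaceCorrPx = 12,
                          epiMeanPx = 9, epiVarPx = 1.2, epiCorrPx = 10,
                          epiMinPx = 7, epiMaxPx = 12,
                          scab = FALSE, scabMeanPx = 6, scabVarPx = 1,
                          scabExtentFrac = 0, reflAir = 0.02,
                          reflScab = 0.6, reflEpi = 0.55, reflDermis = 0.38,
                          attenPerPx = 0.02, speckleShape = 3,
                          noiseSigma = 0.02, seed = 1L) {
  new("PhantomParams", domain = domain, session = session,
      height = as.integer(height), width = as.integer(width),
      pitchUm = pitchUm, surfaceDepthPx = surfaceDepthPx,
      surfaceAmpPx = surfaceAmpPx, surfaceCorrPx = surfaceCorrPx,
      epiMeanPx = epiMeanPx, epiVarPx = epiVarPx, epiCorrPx = epiCorrPx,
      epiMinPx = epiMinPx, epiMaxPx = epiMaxPx, scab = scab,
      scabMeanPx = scabMeanPx, scabVarPx = scabVarPx,
      scabExtentFrac = scabExtentFrac, reflAir = reflAir,
      reflScab = reflScab, reflEpi = reflEpi, reflDermis = reflDermis,
      attenPerPx = attenPerPx, speckleShape = speckleShape,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' Domain/session phantom presets
#'
#' The two domains encode the interspecies thickness and contrast regimes
#' the transfer strategy must bridge: the source (rodent-like) preset keeps
#' the epidermis at most 3 px thick (under 25 um at 8 um/px) with high
#' epidermis/dermis contrast, while the target (human-like) preset keeps it
#' at least 7 px thick (over 50 um) with markedly reduced contrast, as seen
#' in burn lesions. Wound sessions S1-S3 add a scab cap whose lateral
#' extent shrinks as healing progresses; `control` has no scab. For a fixed
#' seed, presets of the same domain differ only in the scab and session
#' fields.
#'
#' @param domain `"source"` or `"target"`.
#' @param session `"S1"`, `"S2"`, `"S3"` or `"control"`.
#' @param height,width image size in pixels.
#' @param seed RNG seed stored in the preset.
#' @return a [PhantomParams-class] object.
#' @examples
#' p <- domainPreset("source", "control", height = 64, width = 64)
#' bs <- makeBScan(p)
#' max(thicknessPx(bs$truth))  # <= 3 px, i.e. under 25 um at 8 um/px
#' @export
domainPreset <- function(domain = c("source", "target"),
                         session = c("control", "S1", "S2", "S3"),
                         height = 128L, width = 128L, seed = 1L) {
  domain <- match.arg(domain)
  session <- match.arg(session)
  extent <- switch(session, S1 = 0.6, S2 = 0.4, S3 = 0.2, control = 0)
  common <- list(domain = domain, session = session, height = height,
                 width = width, seed = seed, scab = session != "control",
                 scabExtentFrac = extent,
                 surfaceDepthPx = height / 3)  # headroom for the scab cap
  regime <- if (domain == "source") {
    # thin, bright epidermis on a dark dermis: the label-rich regime
    list(epiMeanPx = 2.4, epiVarPx = 0.45, epiMinPx = 1, epiMaxPx = 3,
         reflEpi = 0.85, reflDermis = 0.35, reflScab = 0.72,
         scabMeanPx = 4, scabVarPx = 0.8)
  } else {
    # thick epidermis, contrast compressed relative to the source domain
    list(epiMeanPx = 9, epiVarPx = 1.2, epiMinPx = 7, epiMaxPx = 12,
         reflEpi = 0.55, reflDermis = 0.38, reflScab = 0.6,
         scabMeanPx = 6, scabVarPx = 1)
  }
  do.call(phantomParams, c(common, regime))
}

# generate boundary profiles + masks + image stack; shared by makeBScan and
# makeVolume
.phantom_generate <- function(params, nb) {
  H <- params@height; W <- params@width
  set.seed(params@seed)
  fSurf <- .smooth_field(W, nb, params@surfaceCorrPx / 2)
  fEpi <- .smooth_field(W, nb, params@epiCorrPx / 2)
  fScab <- .smooth_field(W, nb, params@epiCorrPx / 2)  # drawn unconditionally

  upper <- round(params@surfaceDepthPx + params@surfaceAmpPx * fSurf)
  thick <- round(.clamp(params@epiMeanPx + params@epiVarPx * fEpi,
                        params@epiMinPx, params@epiMaxPx))
  thick[thick < 1] <- 1

  scabThick <- matrix(0, W, nb)
  if (params@scab && params@scabExtentFrac > 0) {
    half <- params@scabExtentFrac * W / 2
    inScab <- abs(seq_len(W) - (W + 1) / 2) <= half
    tS <- round(params@scabMeanPx + params@scabVarPx * fScab)
    tS[tS < 1] <- 1
    scabThick[inScab, ] <- tS[inScab, ]
  }

  # the surface profile is clipped to the imaging window: the scab cap must
  # stay inside the image and at least one dermis row must remain below
  lowBound <- 1 + scabThick
  highBound <- H - thick
  bad <- which(lowBound > highBound, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "phantom geometry overflows the %d-px image height at A-line %d of B-scan %d",
      H, bad[1, 1], bad[1, 2]))
  upper <- pmin(pmax(upper, lowBound), highBound)
  lower <- upper + thick

  scabT <- matrix(NA_real_, W, nb)
  scabB <- matrix(NA_real_, W, nb)
  has <- scabThick > 0
  scabT[has] <- upper[has] - scabThick[has]
  scabB[has] <- upper[has] - 1

  masks <- array(0L, c(H, W, nb))
  vol <- array(0, c(H, W, nb))
  rows <- matrix(seq_len(H), H, W)
  for (j in seq_len(nb)) {
    upM <- matrix(upper[, j], H, W, byrow = TRUE)
    loM <- matrix(lower[, j], H, W, byrow = TRUE)
    stM <- matrix(ifelse(is.na(scabT[, j]), Inf, scabT[, j]), H, W,
                  byrow = TRUE)
    m <- matrix(0L, H, W)
    m[rows >= upM & rows < loM] <- 1L
    m[rows >= stM & rows < upM] <- 2L
    refl <- matrix(params@reflAir, H, W)
    refl[m == 1L] <- params@reflEpi
    refl[m == 2L] <- params@reflScab
    refl[m == 0L & rows >= loM] <- params@reflDermis
    entry <- matrix(ifelse(is.na(scabT[, j]), upper[, j], scabT[, j]),
                    H, W, byrow = TRUE)
    img <- refl * exp(-params@attenPerPx * pmax(0, rows - entry))
    if (params@speckleShape > 0)
      img <- img * matrix(rgamma(H * W, shape = params@speckleShape,
                                 rate = params@speckleShape), H, W)
    if (params@noiseSigma > 0)
      img <- img + matrix(rnorm(H * W, sd = params@noiseSigma), H, W)
    vol[, , j] <- .clamp(img, 0, 1)
    masks[, , j] <- m
  }
  truth <- new("PhantomTruth", classMasks = masks,
               upper = matrix(as.integer(upper), W, nb),
               lower = matrix(as.integer(lower), W, nb),
               scabTop = scabT, scabBottom = scabB,
               thicknessPx = lower - upper)
  list(volume = new("OCTVolume", data = vol, pitchUm = params@pitchUm),
       truth = truth)
}

#' Generate a single phantom B-scan
#'
#' @param params a [PhantomParams-class] object.
#' @return list with `image` (a `height x width` matrix in `[0, 1]`) and
#'   `truth` (a single-B-scan [PhantomTruth-class]).
#' @export
makeBScan <- function(params) {
  g <- .phantom_generate(params, 1L)
  list(image = volData(g$volume)[, , 1], truth = g$truth)
}

#' Generate a phantom volume
#'
#' Boundary profiles vary smoothly both laterally and across B-scans; the
#' analytic truth stacks per-B-scan masks and yields a `(width, nBScans)`
#' en-face thickness map.
#'
#' @param params a [PhantomParams-class] object.
#' @param nBScans number of B-scans (>= 1).
#' @return list with `volume` ([OCTVolume-class]) and `truth`
#'   ([PhantomTruth-class]).
#' @export
makeVolume <- function(params, nBScans = 16L) {
  stopifnot(nBScans >= 1L)
  .phantom_generate(params, as.integer(nBScans))
}

#' En-face thickness map of a phantom truth
#'
#' @param truth a [PhantomTruth-class] object.
#' @param pitchUm axial pitch in micrometres per pixel.
#' @return a [ThicknessMap-class] with no undefined entries (phantom
#'   epidermis spans every A-line).
#' @export
truthThicknessMap <- function(truth, pitchUm = 8) {
  new("ThicknessMap", px = truth@thicknessPx, pitchUm = pitchUm)
}
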