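# fixtures built in code: tiny phantoms, random masks, brute-force oracles

# a flat, noise-free phantom whose epidermis occupies rows 10..89 exactly
flatParams <- function(height = 128L, width = 32L, epiRows = 80,
                       surfaceRow = 10, scab = FALSE, atten = 0.02) {
  phantomParams(height = height, width = width,
                surfaceDepthPx = surfaceRow, surfaceAmpPx = 0,
                epiMeanPx = epiRows, epiVarPx = 0, epiMinPx = 1,
                epiMaxPx = epiRows, scab = scab,
                scabExtentFrac = if (scab) 0.5 else 0,
                attenPerPx = atten, speckleShape = 0, noiseSigma = 0,
                seed = 1L)
}

# random 3-class mask with blocky structure
randomClassMask <- function(h, w, seed) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  for (k in 1:2) {
    r0 <- sample(h - 4, 1); c0 <- sample(w - 4, 1)
    m[r0:(r0 + sample(3, 1)), c0:(c0 + sample(3, 1))] <- k
  }
  m
}

randomBinaryMask <- function(h, w, seed, p = 0.3) {
  set.seed(seed)
  matrix(stats::runif(h * w) < p, h, w)
}

# exhaustive O(n) distance-to-boundary contour oracle: boundary pixels are
# foreground pixels with a 4-neighbour of a different class
contourOracle <- function(mask, widthPx = 5L) {
  h <- nrow(mask); w <- ncol(mask)
  r <- (widthPx - 1L) %/% 2L
  bnd <- which(vapply(seq_len(h * w), function(k) {
    i <- (k - 1L) %% h + 1L; j <- (k - 1L) %/% h + 1L
    if (mask[i, j] == 0L) return(FALSE)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
          mask[ii, jj] != mask[i, j]) return(TRUE)
    }
    FALSE
  }, logical(1)))
  out <- matrix(0L, h, w)
  for (k in bnd) {
    i <- (k - 1L) %% h + 1L; j <- (k - 1L) %/% h + 1L
    out[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)] <- 1L
  }
  out
}

# exhaustive pairwise surface-distance oracle
surfaceDistOracle <- function(pred, gt, pitchUm = 8) {
  sp <- surfacePoints(pred); sg <- surfacePoints(gt)
  D <- sqrt(outer(sp[, 1], sg[, 1], `-`)^2 + outer(sp[, 2], sg[, 2], `-`)^2)
  dPG <- apply(D, 1, min)
  dGP <- apply(D, 2, min)
  list(assd = (sum(dPG) + sum(dGP)) / (length(dPG) + length(dGP)) * pitchUm,
       hd = max(max(dPG), max(dGP)) * pitchUm)
}

# per-pixel brute-force evaluation of the literal fusion rule
fuseOracle <- function(No, Nc, th) {
  out <- matrix(0L, nrow(No), ncol(No))
  for (i in seq_len(nrow(No)))
    for (j in seq_len(ncol(No))) {
      if (No[i, j] < th["tO1"] && Nc[i, j] < th["tC1"]) out[i, j] <- 2L
      else if (No[i, j] >= th["tO1"] && No[i, j] < th["tO2"] &&
               Nc[i, j] < th["tC2"]) out[i, j] <- 1L
    }
  out
}

# uniform ProbMaps (1/3 per object class, 1/2 contour)
uniformProbs <- function(h, w) {
  new("ProbMaps", object = array(1 / 3, c(h, w, 3)),
      contour = matrix(0.5, h, w))
}

# ProbMaps that reproduce a class mask exactly (one-hot, zero contour)
oneHotProbs <- function(mask) {
  new("ProbMaps", object = oneHot(mask), contour = matrix(0, nrow(mask),
                                                          ncol(mask)))
}

tinyTrainSet <- function(n = 4, size = 32L, seed0 = 500L) {
  phantomDataset(n, size = size, seed0 = seed0)
}
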