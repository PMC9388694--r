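# internal helpers

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian smoothing of a vector, edge-normalised (kernel renormalised over
# the in-range support so edges are not damped).
.gauss_smooth_vec <- function(v, sigma) {
  n <- length(v)
  if (sigma <= 0 || n == 1L) return(v)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- k[j - i + r + 1L]
    out[i] <- sum(v[j] * w) / sum(w)
  }
  out
}

# Smoothed standard-normal random field (width x nB): white noise filtered
# laterally and across B-scans, then rescaled to unit sd. Draws from the
# current RNG stream.
.smooth_field <- function(width, nb, sigmaLat, sigmaB = sigmaLat / 2) {
  z <- matrix(rnorm(width * nb), width, nb)
  z <- apply(z, 2, .gauss_smooth_vec, sigma = sigmaLat)
  z <- matrix(z, width, nb)
  if (nb > 1L && sigmaB > 0)
    z <- t(apply(z, 1, .gauss_smooth_vec, sigma = sigmaB))
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

# Chebyshev dilation of a logical matrix by radius r (square structuring
# element of side 2r+1), clipped at the image border.
.cheb_dilate <- function(m, r) {
  if (r == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  for (dy in -r:r) {
    ys <- max(1L, 1L - dy):min(H, H - dy)
    yd <- ys + dy
    for (dx in -r:r) {
      xs <- max(1L, 1L - dx):min(W, W - dx)
      xd <- xs + dx
      out[yd, xd] <- out[yd, xd] | m[ys, xs]
    }
  }
  out
}

# pixels whose 4-neighbourhood (replicate-padded at the border) contains a
# different label
.label_edges <- function(m) {
  H <- nrow(m); W <- ncol(m)
  e <- matrix(FALSE, H, W)
  if (H > 1L) {
    d <- m[-1, , drop = FALSE] != m[-H, , drop = FALSE]
    e[-H, ] <- e[-H, , drop = FALSE] | d
    e[-1, ] <- e[-1, , drop = FALSE] | d
  }
  if (W > 1L) {
    d <- m[, -1, drop = FALSE] != m[, -W, drop = FALSE]
    e[, -W] <- e[, -W, drop = FALSE] | d
    e[, -1] <- e[, -1, drop = FALSE] | d
  }
  e
}

.stack3 <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# largest connected component of a logical matrix (8-connectivity);
# all-FALSE input returned unchanged
.largest_cc <- function(m) {
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m * 1)
  tab <- tabulate(lab[lab > 0])
  m & (lab == which.max(tab))
}

# drop connected components smaller than `frac` of the largest one
# (island suppression that keeps all substantial fragments)
.drop_islands <- function(m, frac = 1 / 8) {
  if (!any(m)) return(m)
  lab <- EBImage::bwlabel(m * 1)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= max(tab) * frac)
  m & (lab %in% keep)
}
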