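# Label-space conventions: 3-class masks (0 background/other, 1 epidermis,
# 2 scab), contour bands, one-hot encoding.

#' Generate a contour band mask from a class mask
#'
#' The contour band marks the vicinity of every annotated interface: the
#' outline of the foreground objects (epidermis and scab against
#' background) and the epidermis-scab interface. A pixel belongs to the
#' band iff its Chebyshev distance to a boundary pixel is at most
#' `(widthPx - 1) / 2`, where boundary pixels are foreground pixels with a
#' 4-neighbour of a different class. Measured along an edge normal away
#' from corners, the band is exactly `widthPx` pixels thick.
#'
#' @param mask integer matrix with values in `{0, 1, 2}`.
#' @param widthPx odd band width in pixels (default 5).
#' @return binary integer matrix of the same shape (1 = contour).
#' @examples
#' m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
#' cm <- makeContourMask(m)
#' sum(cm[, 10])  # 10 band pixels in a column crossing both edges
#' @export
makeContourMask <- function(mask, widthPx = 5L) {
  widthPx <- as.integer(widthPx)
  if (widthPx < 1L || widthPx %% 2L == 0L)
    stop("widthPx must be odd and >= 1 (the band is centred on the boundary)")
  stopifnot(is.matrix(mask))
  boundary <- (mask > 0L) & .label_edges(mask)
  band <- .cheb_dilate(boundary, (widthPx - 1L) %/% 2L)
  matrix(as.integer(band), nrow(mask), ncol(mask))
}

#' One-hot encode a class mask
#'
#' @param mask integer matrix with values in `0 .. nClasses-1`.
#' @param nClasses number of classes (3: background, epidermis, scab).
#' @return numeric array `(nrow, ncol, nClasses)`; per pixel exactly one
#'   channel is 1 and channels sum to 1.
#' @export
oneHot <- function(mask, nClasses = 3L) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0L) || any(mask >= nClasses))
    stop(sprintf("mask labels must lie in 0 .. %d", nClasses - 1L))
  out <- array(0, c(dim(mask), nClasses))
  for (k in seq_len(nClasses)) out[, , k] <- as.numeric(mask == (k - 1L))
  out
}
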