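# Image transforms used to probe generalization of identity selectivity:
# grayscale conversion, Mooney two-tone reduction (Gaussian blur followed by
# a luminance threshold anchored to the image center), and face inversion.
# Images are numeric matrices (grayscale) or h x w x 3 arrays with values
# in [0, 1].

checkRange <- function(img) {
  if (any(img < 0 | img > 1))
    stop("pixel values must lie in [0, 1]")
  invisible(img)
}

#' Convert an image to grayscale
#'
#' Uses the standard luminance weights (0.299, 0.587, 0.114). Grayscale
#' input is returned unchanged (idempotent).
#'
#' @param img matrix (grayscale) or h x w x 3 array, values in [0, 1].
#' @return grayscale matrix, values in [0, 1].
#' @examples
#' toGrayscale(array(0.5, c(2, 2, 3)))
#' @export
toGrayscale <- function(img) {
  checkRange(img)
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3L && d[3] == 1L) return(img[, , 1])
  if (length(d) != 3L || d[3] != 3L)
    stop("expected a matrix or an h x w x 3 array")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# separable Gaussian filter with reflective boundary handling; sigma in
# pixels. sigma -> 0 degenerates to the identity (plain thresholding limit).
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1d <- function(m) {        # filter along rows (first dim)
    n <- nrow(m)
    idx <- c(rev(seq_len(min(r, n))), seq_len(n),
             rev(seq_len(n))[seq_len(min(r, n))])  # reflect pad
    if (r > n) stop("blur radius exceeds image size")
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2 * r + 1))
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(blur1d(t(blur1d(img))))
}

#' Mooney two-tone transform
#'
#' Converts an image to a two-tone (black/white) version: grayscale
#' conversion, Gaussian smoothing (SD \code{sigma}), then thresholding at
#' the mean luminance of the cropped image center minus \code{offset}.
#' Output pixels are exactly 0 or 1.
#'
#' @param img matrix or h x w x 3 array in [0, 1].
#' @param sigma SD of the Gaussian smoothing kernel in pixels (default 0.5).
#' @param crop side fraction of the central crop over which the threshold
#'   luminance is computed (default 0.5, i.e. the central 50\% x 50\%
#'   region).
#' @param offset luminance subtracted from the center mean to form the
#'   threshold (default 0.03).
#' @return binary matrix with values in \{0, 1\}.
#' @examples
#' m <- toMooney(matrix(seq(0, 1, length.out = 64), 8, 8))
#' sort(unique(as.vector(m)))
#' @export
toMooney <- function(img, sigma = 0.5, crop = 0.5, offset = 0.03) {
  g <- toGrayscale(img)
  b <- gaussianBlur(g, sigma)
  h <- nrow(g); w <- ncol(g)
  ri <- centerIndices(h, crop); ci <- centerIndices(w, crop)
  if (!length(ri) || !length(ci)) stop("center crop region is empty")
  thr <- mean(b[ri, ci]) - offset
  (b > thr) * 1
}

centerIndices <- function(n, frac) {
  m <- round(n * frac)
  if (m < 1) return(integer(0))
  start <- floor((n - m) / 2) + 1L
  seq.int(start, start + m - 1L)
}

#' Vertical face inversion
#'
#' Mirrors the image top-to-bottom. An involution: applying it twice
#' restores the input exactly.
#'
#' @param img matrix or h x w x c array.
#' @return image of the same shape with rows reversed.
#' @export
invertFace <- function(img) {
  if (is.matrix(img)) return(img[rev(seq_len(nrow(img))), , drop = FALSE])
  d <- dim(img)
  if (length(d) == 3L) return(img[rev(seq_len(d[1])), , , drop = FALSE])
  stop("expected a matrix or a 3-d array")
}
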