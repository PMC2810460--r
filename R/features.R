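# The four-channel per-pixel feature stack: graylevel, local-maximum rank,
# wavelet highpass reconstruction, and the ED8 point-singularity measure.
# Channels are kept on their natural scales; the classifier's covariance
# absorbs scale, so no per-channel standardization is applied.

#' Wavelet specification for the highpass feature
#'
#' @param family wavelet family (only "db4" is provided; its spike-like
#'   shape and 4 vanishing moments make it sensitive to MC-like point
#'   anomalies while annihilating smooth background).
#' @param levels decomposition depth (default 2).
#' @param extension boundary mode; "symmetric" (half-sample) extension.
#' @return list of class "WaveletSpec".
#' @export
waveletSpec <- function(family = "db4", levels = 2L, extension = "symmetric") {
  stopifnot(levels >= 1)
  if (!identical(extension, "symmetric"))
    stop("only symmetric extension is implemented")
  structure(list(family = family, levels = as.integer(levels),
                 extension = extension), class = "WaveletSpec")
}

#' Graylevel feature (x1)
#'
#' Identity copy of the image intensities; microcalcifications are brighter
#' than their surround, so raw graylevel itself is discriminative.
#'
#' @param image a \linkS4class{GrayImage}.
#' @return Numeric matrix equal to the pixel raster.
#' @export
graylevelFeature <- function(image) pixels(image)

#' Local-maximum rank feature (x2)
#'
#' For every pixel, the fraction of its window x window neighborhood (center
#' excluded) holding values strictly below the center:
#' rank = #\{neighbors < center\} / (window^2 - 1). The value is 1 exactly
#' when the center is a strict local maximum, and the statistic is invariant
#' to any strictly monotone intensity remapping. Borders use replicate
#' padding.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param window odd neighborhood edge, default 9 (9 x 9 local histogram).
#' @return Matrix in \[0, 1\].
#' @export
localMaxRank <- function(image, window = 9L) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  m <- pixels(image)
  r <- (window - 1L) / 2L
  p <- .padReplicate(m, r)
  h <- nrow(m); w <- ncol(m)
  cnt <- matrix(0, h, w)
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      cnt <- cnt + (p[(r + 1 + dr):(r + h + dr),
                      (r + 1 + dc):(r + w + dc)] < m)
    }
  }
  cnt / (window^2 - 1)
}

#' Wavelet highpass feature (x3)
#'
#' Decomposes the image with a separable 2-D DWT, zeroes the deepest
#' approximation subband, and reconstructs: the smooth background is
#' suppressed and point anomalies such as microcalcifications stand out.
#' The output is the signed reconstruction (it may be negative); use
#' \code{abs()} downstream if a magnitude response is preferred.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param spec a \code{\link{waveletSpec}}.
#' @return Matrix of the same shape as the input.
#' @export
waveletHighpass <- function(image, spec = waveletSpec()) {
  bank <- .waveletBank(spec$family)
  dec <- .wavedec2(pixels(image), spec$levels, bank)
  dec$approx[] <- 0
  .waverec2(dec, bank)
}

#' ED8 point-singularity feature (x4)
#'
#' Sum of absolute graylevel differences between a pixel and its
#' 8-connected neighbors:
#' ED8(i,j) = sum over k1, k2 in \{-1, 0, 1\} of |I(i+k2, j+k1) - I(i,j)|
#' (the k1 = k2 = 0 term is identically zero). Borders use replicate
#' padding. Point-like bright spots yield large values; flat regions zero.
#'
#' @param image a \linkS4class{GrayImage}.
#' @return Nonnegative matrix.
#' @export
ed8 <- function(image) {
  m <- pixels(image)
  h <- nrow(m); w <- ncol(m)
  p <- .padReplicate(m, 1L)
  out <- matrix(0, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      out <- out + abs(p[(2 + dr):(1 + h + dr), (2 + dc):(1 + w + dc)] - m)
    }
  }
  out
}

#' Assemble the four-channel feature stack
#'
#' Computes x1 (graylevel), x2 (local-max rank), x3 (wavelet highpass) and
#' x4 (ED8), spatially registered so the pattern vector of pixel (i, j) is
#' \code{stack[i, j, ]}.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param spec a \code{\link{waveletSpec}} for x3.
#' @param window neighborhood edge for x2 (default 9).
#' @return h x w x 4 array with channel dimnames
#'   c("gray", "rank", "wavelet", "ed8").
#' @examples
#' img <- GrayImage(matrix(runif(64 * 64, 0, 255), 64, 64))
#' fs <- stackFeatures(img)
#' fs[10, 10, ]   # the pattern vector of pixel (10, 10)
#' @export
stackFeatures <- function(image, spec = waveletSpec(), window = 9L) {
  h <- nrow(pixels(image)); w <- ncol(pixels(image))
  a <- array(0, dim = c(h, w, 4L),
             dimnames = list(NULL, NULL, c("gray", "rank", "wavelet", "ed8")))
  a[, , 1L] <- graylevelFeature(image)
  a[, , 2L] <- localMaxRank(image, window)
  a[, , 3L] <- waveletHighpass(image, spec)
  a[, , 4L] <- ed8(image)
  a
}

# pattern vectors at coords (n x 2 row/col) as an n x 4 matrix
.featuresAt <- function(stack, coords) {
  n <- nrow(coords)
  h <- dim(stack)[1]
  base <- (coords[, 2] - 1L) * h + coords[, 1]
  plane <- h * dim(stack)[2]
  out <- matrix(0, n, dim(stack)[3])
  for (ch in seq_len(dim(stack)[3])) out[, ch] <- stack[base + (ch - 1L) * plane]
  colnames(out) <- dimnames(stack)[[3]]
  out
}
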