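# False-signal reduction: Otsu breast masking (misclassifications
# concentrate outside the breast region and along its border) and the
# physiological cluster rule (calcifications of interest come in groups of
# three or more within 1 cm^2).

#' Otsu threshold of an 8-bit image
#'
#' Exhaustively evaluates all 256 candidate thresholds on the 8-bit
#' histogram and returns the one maximizing the between-class variance
#' w0 * w1 * (mu0 - mu1)^2 (foreground = values strictly above the
#' threshold). Ties resolve to the smallest threshold.
#'
#' @param image a \linkS4class{GrayImage} (values are rounded to 0..255 for
#'   the histogram).
#' @return Integer-valued threshold in 0..254.
#' @export
otsuThreshold <- function(image) {
  v <- round(pmin(pmax(pixels(image), 0), 255))
  if (length(unique(as.vector(v))) < 2L)
    stop("Otsu threshold undefined for a constant image")
  hist <- tabulate(as.vector(v) + 1L, nbins = 256L)
  p <- hist / sum(hist)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[256]
  w1 <- 1 - w0
  num <- (muT * w0 - mu)^2
  den <- w0 * w1
  sigma <- ifelse(den > 0, num / den, 0)
  t_all <- sigma[1:255]              # threshold t = 0..254 splits <=t | >t
  which.max(t_all) - 1L              # which.max returns the first (smallest) tie
}

#' Breast-region mask via Otsu thresholding
#'
#' Thresholds the original graylevel image with \code{\link{otsuThreshold}},
#' keeps the largest 8-connected component, and fills its holes. The result
#' is used to veto detections falling on the dark background or the
#' radiographic label.
#'
#' @param image a \linkS4class{GrayImage}.
#' @return Binary matrix (1 = breast).
#' @export
breastMask <- function(image) {
  th <- otsuThreshold(image)
  m <- (pixels(image) > th) * 1
  lab <- .label8(m)
  if (max(lab) == 0L) return(m * 0)
  sizes <- tabulate(lab[lab > 0L])
  keep <- (lab == which.max(sizes)) * 1
  filled <- EBImage::fillHull(keep)
  matrix(as.numeric(filled > 0), nrow(keep), ncol(keep))
}

#' Physiology-aware cluster filter
#'
#' Removes detections that cannot be clustered microcalcifications:
#' (1) detections outside the breast mask are zeroed (malignant
#' calcifications live in glandular tissue, not in dark background);
#' (2) 8-connected components of the remaining detections are reduced to
#' centroids, the image is tiled into non-overlapping blocks of
#' \code{blockPx} pixels, and a component survives only if the block holding
#' its centroid holds at least \code{minCount} centroids (a cluster is three
#' or more calcifications within 1 cm^2, i.e. 50 x 50 px at 200 um/pixel).
#' The filter is idempotent and never adds detections.
#'
#' @param mask a \linkS4class{DetectionMask}.
#' @param breast binary breast mask (from \code{\link{breastMask}}), or NULL
#'   to skip the masking step.
#' @param blockPx block edge in pixels (e.g.
#'   \code{cmToPixels(1, pixelPitch(image))}).
#' @param minCount minimum centroids per block (default 3).
#' @param sliding use a sliding 1 cm^2 window centered on each candidate
#'   (count of centroids within Chebyshev radius blockPx/2, iterated to a
#'   fixed point) instead of the fixed non-overlapping tiling. The fixed
#'   tiling can split a valid cluster across tile boundaries; the sliding
#'   rule judges every candidate against its own surrounding square
#'   centimeter. Default FALSE.
#' @return A filtered \linkS4class{DetectionMask}.
#' @export
applyPhysiologyFilter <- function(mask, breast, blockPx, minCount = 3L,
                                  sliding = FALSE) {
  stopifnot(blockPx >= 1)
  m <- pixels(mask)
  if (!is.null(breast)) m <- m * (breast > 0)
  lab <- .label8(m)
  cc <- .componentCentroids(lab)
  if (nrow(cc) == 0L) return(DetectionMask(m))
  if (sliding) {
    r <- blockPx / 2
    alive <- rep(TRUE, nrow(cc))
    repeat {
      idx <- which(alive)
      n <- vapply(idx, function(i) {
        sum(abs(cc$row[idx] - cc$row[i]) <= r &
            abs(cc$col[idx] - cc$col[i]) <= r)
      }, numeric(1))
      drop <- idx[n < minCount]
      if (length(drop) == 0L) break
      alive[drop] <- FALSE
    }
    keep <- cc$id[alive]
  } else {
    bi <- paste((cc$row - 1) %/% blockPx, (cc$col - 1) %/% blockPx)
    counts <- table(bi)
    keep <- cc$id[counts[bi] >= minCount]
  }
  out <- matrix(0L, nrow(m), ncol(m))
  out[lab %in% keep & lab > 0L] <- 1L
  DetectionMask(out)
}

#' Convert a physical length to pixels
#'
#' @param lengthCm length in centimeters.
#' @param pixelPitchUm pixel pitch in microns.
#' @return Rounded pixel count; 1 cm at 200 um/pixel is 50 px.
#' @examples
#' cmToPixels(1, 200)    # 50
#' @export
cmToPixels <- function(lengthCm, pixelPitchUm) {
  stopifnot(lengthCm > 0, pixelPitchUm > 0)
  as.integer(round(lengthCm * 10000 / pixelPitchUm))
}
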