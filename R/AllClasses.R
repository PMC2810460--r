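#' @import methods
NULL

#' GrayImage: a grayscale raster with physical pixel pitch
#'
#' Core container for mammograms and derived rasters. Pixels are stored as
#' real numbers in the nominal 8-bit range \[0, 255\] (they are not rescaled
#' to \[0, 1\]); the physical pixel pitch defaults to 200 microns per pixel,
#' the mini-MIAS digitization convention.
#'
#' @slot pixels numeric matrix of intensities (rows = image rows, row 1 at
#'   the top; all coordinates in this package are 1-based R indices).
#' @slot pixelPitchUm microns per pixel edge; strictly positive.
#'
#' @aliases GrayImage-class
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", pixelPitchUm = "numeric"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (!all(is.finite(p))) return("pixels must all be finite")
  if (length(object@pixelPitchUm) != 1L || !is.finite(object@pixelPitchUm) ||
      object@pixelPitchUm <= 0)
    return("pixelPitchUm must be a single positive number")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities, nominal range \[0, 255\].
#' @param pixelPitchUm microns per pixel (default 200, mini-MIAS).
#' @return A \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(100, 8, 8))
#' dim(img)
#' @export
GrayImage <- function(pixels, pixelPitchUm = 200) {
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, pixelPitchUm = as.numeric(pixelPitchUm))
}

#' MCModel: a binary standard model of synthetic microcalcifications
#'
#' The standard model (StdModel) is a binary mask, registered to a target
#' image, marking where synthetic MCs will be planted. The modeling constant
#' K scales the added brightness as a fraction of the underlying tissue
#' graylevel, and H is the lowpass kernel used to smooth the blended pixels.
#'
#' @slot stdModel integer matrix in \{0, 1\}; 1 = synthetic MC pixel.
#' @slot K modeling constant in (0, 1\]; values outside \[0.1, 1\] trigger a
#'   warning at construction (the typical operating range).
#' @slot H nonnegative smoothing kernel, normalized to unit sum.
#'
#' @aliases MCModel-class
#' @exportClass MCModel
setClass("MCModel",
  representation(stdModel = "matrix", K = "numeric", H = "matrix"))

setValidity("MCModel", function(object) {
  m <- object@stdModel
  if (!all(m %in% c(0, 1))) return("stdModel values must be 0 or 1")
  if (length(object@K) != 1L || !is.finite(object@K) || object@K <= 0 ||
      object@K > 1)
    return("K must be a single number in (0, 1]")
  H <- object@H
  if (any(H < 0) || !all(is.finite(H))) return("H must be nonnegative and finite")
  if (abs(sum(H) - 1) > 1e-8) return("H must sum to 1")
  TRUE
})

#' Construct an MCModel
#'
#' @param stdModel binary matrix (1 = synthetic MC pixel), e.g. from
#'   \code{\link{makeStdModel}}.
#' @param K modeling constant in (0, 1\]; warns outside the typical range
#'   \[0.1, 1\].
#' @param H smoothing kernel; default a 3 x 3 normalized Gaussian
#'   (sigma = 0.8).
#' @return An \linkS4class{MCModel}.
#' @export
MCModel <- function(stdModel, K, H = gaussianKernel(3, 0.8)) {
  storage.mode(stdModel) <- "double"
  if (is.finite(K) && K > 0 && K < 0.1)
    warning("K = ", K, " is below the typical range [0.1, 1]")
  new("MCModel", stdModel = stdModel, K = as.numeric(K), H = H)
}

#' HybridImage: mammogram with blended synthetic microcalcifications
#'
#' Result of \code{\link{blendModel}}: the input image with the MC model
#' blended in. Identical to the source image everywhere outside the
#' synthetic support dilated by the smoothing kernel footprint.
#'
#' @slot syntheticCoords integer matrix (n x 2) of (row, col) positions where
#'   the standard model is 1; these pixels are the MC-class training samples.
#'
#' @aliases HybridImage-class
#' @exportClass HybridImage
setClass("HybridImage",
  contains = "GrayImage",
  representation(syntheticCoords = "matrix"))

#' ClassParams: Gaussian class parameters for the Bayesian classifier
#'
#' Mean vector and covariance matrix of one class in feature space, with the
#' cached log-determinant and inverse needed by the quadratic decision
#' function d(x) = -1/2 ln|C| - 1/2 (x-m)' C^-1 (x-m).
#'
#' @slot mean numeric mean vector m.
#' @slot cov symmetric positive-definite covariance matrix C (after ridge
#'   regularization if the sample covariance was near-singular).
#' @slot logDet ln|C|.
#' @slot invCov C^-1.
#' @slot nSamples number of training samples used.
#'
#' @aliases ClassParams-class
#' @exportClass ClassParams
setClass("ClassParams",
  representation(mean = "numeric", cov = "matrix", logDet = "numeric",
                 invCov = "matrix", nSamples = "integer"))

setValidity("ClassParams", function(object) {
  d <- length(object@mean)
  if (!identical(dim(object@cov), c(d, d))) return("cov dimension mismatch")
  if (max(abs(object@cov - t(object@cov))) > 1e-8) return("cov must be symmetric")
  if (!is.finite(object@logDet)) return("logDet must be finite")
  if (object@nSamples < 5L) return("nSamples must be >= 5")
  TRUE
})

#' TrainingSets: pixel coordinates of the two training classes
#'
#' MC-class coordinates come from the blended standard model; healthy-class
#' coordinates come from two square background regions of interest. The
#' healthy set must be at least three times the MC set.
#'
#' @slot mcCoords integer matrix (n x 2) of MC-class (row, col).
#' @slot bgCoords integer matrix (m x 2) of healthy-class (row, col).
#' @slot bgRoiBoxes list of two ROI boxes, each c(row0, col0, row1, col1).
#'
#' @aliases TrainingSets-class
#' @exportClass TrainingSets
setClass("TrainingSets",
  representation(mcCoords = "matrix", bgCoords = "matrix",
                 bgRoiBoxes = "list"))

setValidity("TrainingSets", function(object) {
  if (length(object@bgRoiBoxes) != 2L) return("exactly two background ROIs required")
  key <- function(m) paste(m[, 1], m[, 2])
  if (length(intersect(key(object@mcCoords), key(object@bgCoords))) > 0)
    return("MC and background coordinates must be disjoint")
  if (nrow(object@bgCoords) < 3L * nrow(object@mcCoords))
    return("background set must be at least 3x the MC set")
  TRUE
})

#' DetectionMask: binary per-pixel classification result
#'
#' 1 marks pixels classified as microcalcification, 0 healthy tissue.
#'
#' @slot labels integer matrix in \{0, 1\}, same shape as the source image.
#'
#' @aliases DetectionMask-class
#' @exportClass DetectionMask
setClass("DetectionMask", representation(labels = "matrix"))

setValidity("DetectionMask", function(object) {
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  TRUE
})

#' Construct a DetectionMask
#' @param labels binary matrix (coerced to integer 0/1).
#' @return A \linkS4class{DetectionMask}.
#' @export
DetectionMask <- function(labels) {
  storage.mode(labels) <- "integer"
  new("DetectionMask", labels = labels)
}

#' BlockReport: block-based detection outcome of one mammogram
#'
#' The image is tiled into non-overlapping blocks (50 x 50 px = 1 cm^2 at
#' 200 um/pixel by default). Blocks intersecting annotated MC regions are
#' excluded from the healthy census; each remaining block is a false
#' positive if it holds at least \code{fpMinCount} detected component
#' centroids, otherwise a true negative. Each annotated region scores one
#' TP (hit) or FN (miss).
#'
#' @slot blockPx block edge length in pixels.
#' @slot fpMinCount centroids needed for a block to count as FP.
#' @slot blockLabels character matrix over the block grid with values
#'   "FP", "TN" or "excluded".
#' @slot TP,FN annotated-region outcomes (NA when no located annotations).
#' @slot FP,TN healthy-block outcomes.
#' @slot sensitivity,specificity percentages (NA when undefined).
#' @slot components data.frame of detected components (id, row, col, area,
#'   block_row, block_col).
#'
#' @aliases BlockReport-class
#' @exportClass BlockReport
setClass("BlockReport",
  representation(blockPx = "integer", fpMinCount = "integer",
                 blockLabels = "matrix", TP = "integer", FN = "integer",
                 FP = "integer", TN = "integer", sensitivity = "numeric",
                 specificity = "numeric", components = "data.frame"))

setValidity("BlockReport", function(object) {
  if (!all(object@blockLabels %in% c("FP", "TN", "excluded")))
    return("block labels must be FP, TN or excluded")
  ok <- function(x) is.na(x) || (x >= 0 && x <= 100)
  if (!ok(object@sensitivity) || !ok(object@specificity))
    return("sensitivity/specificity must be in [0, 100] or NA")
  TRUE
})
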