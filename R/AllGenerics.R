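#' Accessors for mcdetect classes
#'
#' \code{pixels} returns the raw intensity matrix of a \linkS4class{GrayImage}
#' (or the binary matrix of a \linkS4class{DetectionMask});
#' \code{pixelPitch} the pixel pitch in microns.
#'
#' @param x object.
#' @return \code{pixels}: a matrix; \code{pixelPitch}: a number.
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "DetectionMask", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("pixelPitch", "GrayImage", function(x) x@pixelPitchUm)

#' @describeIn GrayImage image dimensions c(height, width).
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

setMethod("show", "GrayImage", function(object) {
  p <- object@pixels
  cat(sprintf("GrayImage %d x %d px, pitch %g um/px, range [%.1f, %.1f]\n",
              nrow(p), ncol(p), object@pixelPitchUm, min(p), max(p)))
})

setMethod("show", "HybridImage", function(object) {
  cat(sprintf("HybridImage %d x %d px, %d synthetic MC pixels\n",
              nrow(object@pixels), ncol(object@pixels),
              nrow(object@syntheticCoords)))
})

setMethod("show", "MCModel", function(object) {
  cat(sprintf("MCModel: %d synthetic pixels (%.3f%% of image), K = %g, H %d x %d\n",
              sum(object@stdModel), 100 * mean(object@stdModel), object@K,
              nrow(object@H), ncol(object@H)))
})

setMethod("show", "ClassParams", function(object) {
  cat(sprintf("ClassParams: %d-D Gaussian from %d samples\n",
              length(object@mean), object@nSamples))
  cat("  mean:", signif(object@mean, 5), "\n")
  cat("  ln|C|:", signif(object@logDet, 5), "\n")
})

setMethod("show", "TrainingSets", function(object) {
  cat(sprintf("TrainingSets: %d MC pixels, %d background pixels (ratio %.1f)\n",
              nrow(object@mcCoords), nrow(object@bgCoords),
              nrow(object@bgCoords) / max(1L, nrow(object@mcCoords))))
})

setMethod("show", "DetectionMask", function(object) {
  cat(sprintf("DetectionMask %d x %d, %d positive pixels\n",
              nrow(object@labels), ncol(object@labels), sum(object@labels)))
})

setMethod("show", "BlockReport", function(object) {
  cat(sprintf("BlockReport (%d x %d px blocks, FP rule >= %d centroids)\n",
              object@blockPx, object@blockPx, object@fpMinCount))
  cat(sprintf("  TP %s  FN %s  FP %d  TN %d\n",
              ifelse(is.na(object@TP), "NA", object@TP),
              ifelse(is.na(object@FN), "NA", object@FN),
              object@FP, object@TN))
  cat(sprintf("  sensitivity %s%%  specificity %s%%\n",
              ifelse(is.na(object@sensitivity), "NA",
                     sprintf("%.1f", object@sensitivity)),
              ifelse(is.na(object@specificity), "NA",
                     sprintf("%.1f", object@specificity))))
})
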