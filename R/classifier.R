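# Self-learning Gaussian Bayesian classifier: training-set selection from
# the hybrid image, class parameter estimation, and maximum-a-posteriori
# pixel classification with the quadratic decision function
#   d_j(x) = -1/2 ln|C_j| - 1/2 (x - m_j)' C_j^-1 (x - m_j)
# (equal priors; the common (n/2) ln 2pi term is dropped).

#' Select self-learning training samples
#'
#' MC-class coordinates are all pixels of the binary standard model. The
#' healthy class comes from two square regions of interest placed uniformly
#' at random (seeded) in the image, kept disjoint from the dilated model,
#' from any exclusion circles (e.g. annotated real MCs), and from each
#' other. With the default budget of about 4300 background samples the
#' healthy set is roughly 50 times a typical MC set; at minimum it must be
#' 3 times larger, which is enforced.
#'
#' @param modelMask binary standard-model matrix (1 = MC training pixel).
#' @param bgTotal total background samples wanted across both ROIs
#'   (default 4300); each ROI is a square of side ceiling(sqrt(bgTotal/2)).
#' @param seed integer seed for ROI placement.
#' @param exclusion optional annotation data.frame (center_row, center_col,
#'   radius_px) whose circles the ROIs must avoid.
#' @param withinMask optional binary matrix; when given, ROIs must lie
#'   entirely inside it (e.g. an eroded breast mask, so background samples
#'   are breast tissue rather than dark background).
#' @param roiBoxes optional list of two explicit boxes c(row0, col0, row1,
#'   col1), bypassing random placement.
#' @param maxTries placement attempts before giving up.
#' @return A \linkS4class{TrainingSets}.
#' @export
selectTrainingSamples <- function(modelMask, bgTotal = 4300L, seed = 1L,
                                  exclusion = NULL, withinMask = NULL,
                                  roiBoxes = NULL, maxTries = 500L) {
  mc <- .maskCoords(modelMask)
  if (nrow(mc) == 0L) stop("standard model is empty")
  if (bgTotal < 3L * nrow(mc))
    stop("bgTotal = ", bgTotal, " cannot satisfy the >= 3x class size ratio (",
         nrow(mc), " MC samples)")
  h <- nrow(modelMask); w <- ncol(modelMask)
  forbidden <- .dilateByFootprint(modelMask, matrix(1, 5, 5))
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    for (i in seq_len(nrow(exclusion))) {
      if (is.na(exclusion$center_row[i])) next
      forbidden <- .stampDisc(forbidden, exclusion$center_row[i],
                              exclusion$center_col[i],
                              exclusion$radius_px[i] + 2)
    }
  }
  side <- ceiling(sqrt(bgTotal / 2))
  if (side > min(h, w)) stop("image too small for background ROIs")
  boxOK <- function(b, other = NULL) {
    sub <- forbidden[b[1]:b[3], b[2]:b[4]]
    if (sum(sub) > 0) return(FALSE)
    if (!is.null(withinMask) &&
        any(withinMask[b[1]:b[3], b[2]:b[4]] == 0)) return(FALSE)
    if (!is.null(other) &&
        !(b[3] < other[1] || other[3] < b[1] ||
          b[4] < other[2] || other[4] < b[2])) return(FALSE)
    TRUE
  }
  if (is.null(roiBoxes)) {
    boxes <- list()
    withr::with_seed(as.integer(seed), {
      for (k in 1:2) {
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          r0 <- sample.int(h - side + 1L, 1L)
          c0 <- sample.int(w - side + 1L, 1L)
          b <- c(r0, c0, r0 + side - 1L, c0 + side - 1L)
          if (boxOK(b, if (k == 2) boxes[[1]] else NULL)) {
            boxes[[k]] <- b
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place two disjoint background ROIs after ",
               maxTries, " tries")
      }
    })
  } else {
    stopifnot(length(roiBoxes) == 2L)
    boxes <- roiBoxes
    for (k in 1:2)
      if (!boxOK(boxes[[k]], if (k == 2) boxes[[1]] else NULL))
        stop("explicit ROI box ", k, " overlaps excluded regions")
  }
  bg <- do.call(rbind, lapply(boxes, function(b) {
    as.matrix(expand.grid(row = b[1]:b[3], col = b[2]:b[4]))
  }))
  if (nrow(bg) < 3L * nrow(mc))
    stop("background sample (", nrow(bg), ") is below 3x the MC sample (",
         nrow(mc), ")")
  new("TrainingSets", mcCoords = mc, bgCoords = bg, bgRoiBoxes = boxes)
}

#' Estimate Gaussian class parameters
#'
#' Sample mean and unbiased (n - 1) covariance of the pattern vectors at the
#' given coordinates. A near-singular covariance (smallest eigenvalue below
#' eps * trace / d with eps = 1e-6) is ridge-regularized by adding
#' eps * trace / d on the diagonal; a fully degenerate sample (every channel
#' constant) is an error naming the degenerate channels.
#'
#' @param features h x w x d feature array (from \code{\link{stackFeatures}})
#'   or directly an n x d sample matrix.
#' @param coords n x 2 (row, col) matrix; ignored when \code{features} is
#'   already a sample matrix.
#' @return A \linkS4class{ClassParams}.
#' @export
estimateParams <- function(features, coords = NULL) {
  X <- if (is.matrix(features)) features else .featuresAt(features, coords)
  n <- nrow(X); d <- ncol(X)
  if (n < 5L) stop("need at least 5 samples, got ", n)
  m <- colMeans(X)
  C <- stats::cov(X)
  vars <- diag(C)
  if (all(vars <= 0)) {
    ch <- colnames(X)
    if (is.null(ch)) ch <- paste0("x", seq_len(d))
    stop("degenerate training sample: channel(s) ",
         paste(ch[vars <= 0], collapse = ", "), " are constant")
  }
  eps <- 1e-6
  ridge <- eps * sum(diag(C)) / d
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < ridge) C <- C + diag(ridge, d)
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  new("ClassParams", mean = as.numeric(m), cov = C, logDet = ld,
      invCov = solve(C), nSamples = as.integer(n))
}

#' Gaussian Bayes decision value
#'
#' Evaluates d(x) = -1/2 ln|C| - 1/2 (x - m)' C^-1 (x - m): the class
#' log-posterior under equal priors, up to the constant (n/2) ln 2pi shared
#' by all classes. A pixel is assigned to the class with the larger value.
#'
#' @param x numeric feature vector.
#' @param params a \linkS4class{ClassParams}.
#' @return A single numeric decision value.
#' @examples
#' p <- estimateParams(matrix(rnorm(400), 100, 4))
#' decisionValue(p@mean, p)    # Mahalanobis term vanishes at the mean
#' @export
decisionValue <- function(x, params) {
  if (!all(is.finite(x))) stop("non-finite feature vector")
  xc <- x - params@mean
  as.numeric(-0.5 * params@logDet - 0.5 * (xc %*% params@invCov %*% xc))
}

# vectorized decision values for an n x d sample matrix
.decisionValues <- function(X, params) {
  Xc <- sweep(X, 2L, params@mean)
  -0.5 * params@logDet - 0.5 * rowSums((Xc %*% params@invCov) * Xc)
}

#' Classify every pixel into MC versus healthy tissue
#'
#' Maximum-a-posteriori rule over the two classes: label 1 (MC) where the MC
#' decision value strictly exceeds the healthy one, label 0 otherwise (exact
#' ties go to healthy, so a detection requires strict evidence).
#'
#' @param features h x w x d feature array.
#' @param mcParams,bgParams \linkS4class{ClassParams} of the MC and healthy
#'   classes.
#' @return A \linkS4class{DetectionMask}.
#' @export
classifyPixels <- function(features, mcParams, bgParams) {
  h <- dim(features)[1]; w <- dim(features)[2]; d <- dim(features)[3]
  if (length(mcParams@mean) != d || length(bgParams@mean) != d)
    stop("feature dimension mismatch between stack and class parameters")
  X <- matrix(features, h * w, d)
  lab <- .decisionValues(X, mcParams) > .decisionValues(X, bgParams)
  DetectionMask(matrix(as.integer(lab), h, w))
}

#' Interclass mean-difference and NMD diagnostics
#'
#' Reports, channel by channel, the difference of the estimated class means
#' and the ratio of the class variances -- the quantities used to judge
#' whether the modeling constant K produced a workable separation -- plus
#' the normalized mean difference
#' NMD = (mean graylevel over the MC model - mean graylevel over the breast
#' region) / normalizer. A very large mean difference means the classifier
#' keys on a single bright tone (K too large); a very small one means weak
#' class separation and many false signals (K too small).
#'
#' @param mcParams,bgParams \linkS4class{ClassParams}.
#' @param image the (hybrid) \linkS4class{GrayImage}.
#' @param breastMask binary breast-region matrix.
#' @param modelMask binary standard-model matrix.
#' @param normalizer NMD denominator (default 255, the 8-bit range).
#' @return list with elements \code{meanDiff} (per channel),
#'   \code{varRatio} (per channel) and \code{nmd}.
#' @export
meanDifferenceDiagnostic <- function(mcParams, bgParams, image, breastMask,
                                     modelMask, normalizer = 255) {
  if (sum(breastMask) == 0 || sum(modelMask) == 0)
    stop("breast or model mask is empty")
  p <- pixels(image)
  list(meanDiff = mcParams@mean - bgParams@mean,
       varRatio = diag(mcParams@cov) / diag(bgParams@cov),
       nmd = (mean(p[modelMask > 0]) - mean(p[breastMask > 0])) / normalizer)
}
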