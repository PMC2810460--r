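# Synthetic microcalcification construction: the binary standard model
# (disc-shaped MCs grouped into clusters) and its intensity blending into a
# mammogram under the modeling constant K.

#' Build the binary standard model of synthetic microcalcifications
#'
#' Plants clusters of small filled discs into an all-zero mask. Each cluster
#' spec gives a center, a number of MCs (>= 3, the clinical cluster
#' definition), a disc radius range and a cluster radius. Disc radii of 1-3
#' px correspond to roughly 0.2-1 mm calcifications at 200 um/pixel, and a
#' cluster radius of up to 25 px keeps a cluster inside one 1 cm^2 block.
#' Discs are placed at seeded-random offsets and kept mutually non-adjacent
#' so each synthetic MC is a separate connected component.
#'
#' @param shape c(height, width) of the target image.
#' @param clusters list of cluster specs, each a list with elements
#'   \code{center} (c(row, col)), \code{n_mcs} (>= 3),
#'   \code{mc_radius_range} (c(min, max), within \[1, 3\]) and
#'   \code{cluster_radius} (<= 25).
#' @param seed integer seed; the output is a pure function of
#'   (shape, clusters, seed).
#' @param maxTries placement retries per disc before giving up.
#' @return Binary matrix (1 = synthetic MC pixel). Total synthetic area is
#'   checked against 1\% of the image (MCs occupy no more than about 1\% of
#'   a mammogram).
#' @examples
#' m <- makeStdModel(c(100, 100),
#'   list(list(center = c(50, 50), n_mcs = 3,
#'             mc_radius_range = c(1, 2), cluster_radius = 15)), seed = 1)
#' sum(m)
#' @export
makeStdModel <- function(shape, clusters, seed, maxTries = 200L) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0, h, w)
  if (length(clusters) == 0L) return(mask)
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      cl$center <- unlist(cl$center)             # tolerate YAML/JSON lists
      nmc <- unlist(cl$n_mcs)
      rr <- if (is.null(cl$mc_radius_range)) c(1, 3) else
        unlist(cl$mc_radius_range)
      crad <- if (is.null(cl$cluster_radius)) 20 else
        unlist(cl$cluster_radius)
      if (nmc < 3L) stop("cluster ", ci, ": a cluster needs >= 3 MCs")
      if (rr[1] < 1 || rr[2] > 3)
        stop("cluster ", ci, ": mc_radius_range must lie within [1, 3]")
      if (crad > 25)
        stop("cluster ", ci, ": cluster_radius must be <= 25 (one 50 px block)")
      for (m in seq_len(nmc)) {
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          rad <- stats::runif(1, rr[1], rr[2])
          ang <- stats::runif(1, 0, 2 * pi)
          dist <- sqrt(stats::runif(1)) * max(0, crad - rad)
          r0 <- cl$center[1] + dist * sin(ang)
          c0 <- cl$center[2] + dist * cos(ang)
          if (r0 - rad < 1 || r0 + rad > h || c0 - rad < 1 || c0 + rad > w)
            next
          cand <- .stampDisc(matrix(0, h, w), r0, c0, rad)
          # require separation so discs stay distinct components
          if (sum(.dilateByFootprint(cand, matrix(1, 3, 3)) * mask) == 0) {
            mask <- pmax(mask, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("cluster ", ci, ": could not place ", nmc,
               " disjoint discs within the cluster radius")
      }
    }
  })
  if (sum(mask) > 0.01 * h * w)
    stop("synthetic pixels exceed 1% of the image area")
  mask
}

#' Blend the MC model into a mammogram
#'
#' Each synthetic pixel receives an added brightness proportional (by the
#' modeling constant K) to its underlying mammogram graylevel:
#' L = K * I * StdModel. The raw hybrid I + L is then smoothed with the
#' lowpass kernel H, but only pixels within the synthetic support dilated by
#' H's footprint are replaced, so the image is untouched away from the
#' planted MCs. The result is clipped to \[0, 255\].
#'
#' @param image a \linkS4class{GrayImage}.
#' @param model an \linkS4class{MCModel} (standard model + K + H).
#' @param K optional override of the modeling constant; K = 0 is accepted
#'   here (useful for limit checks) but negative values are an error.
#' @return A \linkS4class{HybridImage}.
#' @export
blendModel <- function(image, model, K = NULL) {
  I <- pixels(image)
  M <- model@stdModel
  if (!identical(dim(I), dim(M))) stop("image and standard model shapes differ")
  k <- if (is.null(K)) model@K else K
  if (k < 0) stop("K must be nonnegative")
  if (k == 0 || sum(M) == 0)                 # exact identity in the K -> 0 limit
    return(new("HybridImage", pixels = I, pixelPitchUm = pixelPitch(image),
               syntheticCoords = .maskCoords(M)))
  raw <- I + k * I * M
  region <- .dilateByFootprint(M, model@H)
  out <- raw
  if (any(region > 0)) {
    sm <- .conv2Replicate(raw, model@H)
    out[region > 0] <- sm[region > 0]
  }
  out <- pmin(pmax(out, 0), 255)
  new("HybridImage", pixels = out, pixelPitchUm = pixelPitch(image),
      syntheticCoords = .maskCoords(M))
}

#' Choose the modeling constant K from tissue statistics
#'
#' Small K suits dense-glandular tissue (low MC contrast against bright,
#' high-variance tissue) while larger K suits fatty tissue: the defaults are
#' K = 0.2 for dense-glandular (the best operating point of the K sweep) and
#' K = 0.5 for fatty or fatty-glandular. Without a tissue hint the
#' breast-region graylevel variance decides: above \code{varThreshold} the
#' dense rule applies.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param breastMask binary matrix marking the breast region.
#' @param tissueHint optional one of "fatty", "fatty-glandular",
#'   "dense-glandular".
#' @param varThreshold breast-region variance above which tissue is treated
#'   as dense (default 400, i.e. sd 20 graylevels).
#' @param denseK,fattyK the two operating points (defaults 0.2 and 0.5).
#' @return Numeric K.
#' @export
chooseK <- function(image, breastMask, tissueHint = NULL, varThreshold = 400,
                    denseK = 0.2, fattyK = 0.5) {
  if (!is.null(tissueHint)) {
    tissueHint <- match.arg(tissueHint,
                            c("fatty", "fatty-glandular", "dense-glandular"))
    return(if (tissueHint == "dense-glandular") denseK else fattyK)
  }
  if (sum(breastMask) == 0) stop("breast mask is empty")
  v <- stats::var(pixels(image)[breastMask > 0])
  if (v > varThreshold) denseK else fattyK
}
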