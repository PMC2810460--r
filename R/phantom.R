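# Synthetic-mammogram phantom: a half-ellipse breast of correlated Gaussian
# texture on a dark background, planted MC clusters with known ground truth,
# and an optional radiographic marker. Stands in for annotated screening
# data in tests; tissue presets follow the ordering seen in real film
# (dense-glandular tissue is brighter and more variable than fatty).

# breast_sd is the total tissue sd; structure_sd is the share carried by a
# coarse (corr ~12 px) glandular-structure field, the rest by fine-scale
# grain. Dense-glandular tissue owes its larger variance to structure, not
# to fine noise, so the grain component is common to both presets.
.phantomPresets <- list(
  fatty = list(breast_mean = 120, breast_sd = 12, structure_sd = 0,
               mc_contrast = 52),
  dense = list(breast_mean = 170, breast_sd = 25, structure_sd = 22,
               mc_contrast = 45))

#' Phantom specification
#'
#' Tissue presets (calibration constants of this generator, not measured
#' values): fatty breast mean 120 sd 12, dense breast mean 170 sd 25, both
#' over a dark background of level 10. The tissue texture is the sum of a
#' fine-scale grain field (correlation length \code{textureCorrPx}, shared
#' by both tissues) and, for dense tissue, a coarser glandular-structure
#' field (sd 22, correlation length \code{structureCorrPx}) that carries the
#' extra dense-tissue variance -- tissue is a lowpass background at the MC
#' scale, with calcifications as the only point anomalies. Default MC
#' contrasts put the planted clusters at a normalized mean difference of
#' roughly 0.15 (fatty) and 0.12-0.2 (dense), comfortably above the 0.1
#' working floor; fatty-tissue MCs carry the larger contrast relative to
#' their texture, as in real mammograms.
#'
#' @param shape c(height, width), default 1024 x 1024.
#' @param tissue "fatty" or "dense".
#' @param nClusters number of auto-placed MC clusters (ignored when
#'   \code{mcClusters} is given).
#' @param mcClusters explicit cluster specs as in \code{\link{makeStdModel}},
#'   or NULL for seeded auto-placement inside the breast.
#' @param mcContrast additive brightness of planted MCs (graylevels);
#'   NULL = tissue preset.
#' @param bgLevel dark background mean.
#' @param textureCorrPx correlation length (Gaussian blur sigma) of the
#'   fine-grain tissue texture.
#' @param structureCorrPx correlation length of the coarse structural field
#'   (dense preset only).
#' @param marker plant a bright rectangular film label outside the breast.
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class "PhantomSpec".
#' @export
phantomSpec <- function(shape = c(1024L, 1024L),
                        tissue = c("fatty", "dense"),
                        nClusters = 2L, mcClusters = NULL, mcContrast = NULL,
                        bgLevel = 10, textureCorrPx = 3, structureCorrPx = 12,
                        marker = TRUE, seed = 1L) {
  tissue <- match.arg(tissue)
  pre <- .phantomPresets[[tissue]]
  structure(list(
    shape = as.integer(shape), tissue = tissue, nClusters = as.integer(nClusters),
    mcClusters = mcClusters,
    mcContrast = if (is.null(mcContrast)) pre$mc_contrast else mcContrast,
    breastMean = pre$breast_mean, breastSd = pre$breast_sd,
    structureSd = pre$structure_sd,
    bgLevel = bgLevel, textureCorrPx = textureCorrPx,
    structureCorrPx = structureCorrPx, marker = marker,
    seed = as.integer(seed)), class = "PhantomSpec")
}

# half-ellipse breast region anchored at the left edge
.breastEllipse <- function(h, w) {
  a <- 0.42 * h; b <- 0.62 * w
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  (((r - h / 2) / a)^2 + ((c_ - 1) / b)^2 <= 1) * 1
}

#' Generate a synthetic mammogram phantom
#'
#' Deterministic for a fixed spec (bit-exact under the same seed). The
#' breast is a half-ellipse of spatially correlated Gaussian texture
#' rescaled to the tissue preset's mean/sd; MC clusters are groups of >= 3
#' small bright discs (radius 1-2.5 px) with additive contrast, smoothed at
#' their edges; the ground-truth mask marks exactly the planted MC pixels
#' and each annotation circumscribes one cluster.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{image} (\linkS4class{GrayImage}),
#'   \code{truth} (binary MC mask), \code{annotations} (MIAS-convention
#'   data.frame, one row per cluster) and \code{breast} (the true breast
#'   region mask).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(256, 256), seed = 7))
#' sum(ph$truth)
#' @export
generatePhantom <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  breast <- .breastEllipse(h, w)

  img <- withr::with_seed(.deriveSeed(spec$seed, "texture"), {
    sel <- breast > 0
    std <- function(sigma) {
      f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = sigma)
      f <- matrix(as.numeric(f), h, w)
      (f - mean(f[sel])) / stats::sd(f[sel])
    }
    fineSd <- sqrt(spec$breastSd^2 - spec$structureSd^2)
    tex <- fineSd * std(spec$textureCorrPx)
    if (spec$structureSd > 0)
      tex <- tex + spec$structureSd * std(spec$structureCorrPx)
    out <- spec$bgLevel + matrix(stats::rnorm(h * w, sd = 2), h, w)
    out[sel] <- spec$breastMean + tex[sel]
    out
  })

  clusters <- spec$mcClusters
  if (is.null(clusters) && spec$nClusters > 0) {
    margin <- 30
    interior <- EBImage::erode(breast, EBImage::makeBrush(2 * margin + 1,
                                                          "box"))
    coords <- .maskCoords(matrix(as.numeric(interior > 0), h, w))
    if (nrow(coords) == 0L) stop("breast region too small for clusters")
    clusters <- withr::with_seed(.deriveSeed(spec$seed, "place"), {
      out <- list(); chosen <- NULL
      tries <- 0L
      while (length(out) < spec$nClusters && tries < 2000L) {
        tries <- tries + 1L
        ctr <- coords[sample.int(nrow(coords), 1L), ]
        if (!is.null(chosen) &&
            any(sqrt((chosen[, 1] - ctr[1])^2 +
                     (chosen[, 2] - ctr[2])^2) < 70)) next
        chosen <- rbind(chosen, ctr)
        out[[length(out) + 1L]] <- list(center = as.numeric(ctr), n_mcs = 5L,
                                        mc_radius_range = c(1, 2.5),
                                        cluster_radius = 15)
      }
      if (length(out) < spec$nClusters)
        stop("could not place ", spec$nClusters, " well-separated clusters")
      out
    })
  }
  if (is.null(clusters)) clusters <- list()

  truth <- matrix(0, h, w)
  ann <- NULL
  tcode <- if (spec$tissue == "dense") "dense-glandular" else "fatty"
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (breast[round(cl$center[1]), round(cl$center[2])] == 0)
      stop("cluster ", i, " center lies outside the breast region")
    cm <- makeStdModel(c(h, w), list(cl), seed = .deriveSeed(spec$seed,
                                                             paste0("mc", i)))
    truth <- pmax(truth, cm)
    px <- .maskCoords(cm)
    rad <- max(sqrt((px[, 1] - cl$center[1])^2 + (px[, 2] - cl$center[2])^2)) + 2
    ann <- rbind(ann, data.frame(
      ref_id = sprintf("phantom-%03d", i), tissue = tcode,
      abnormality = "CALC", severity = "benign",
      center_row = cl$center[1], center_col = cl$center[2], radius_px = rad))
  }
  if (is.null(ann))
    ann <- data.frame(ref_id = character(), tissue = character(),
                      abnormality = character(), severity = character(),
                      center_row = numeric(), center_col = numeric(),
                      radius_px = numeric())

  if (sum(truth) > 0) {
    layer <- .conv2Replicate(spec$mcContrast * truth, gaussianKernel(3, 0.7))
    img <- img + layer
  }
  if (isTRUE(spec$marker)) {
    rr <- max(1, round(0.04 * h)):max(1, round(0.09 * h))
    cc <- max(1, round(0.88 * w)):max(1, round(0.96 * w))
    img[rr, cc] <- 220
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = GrayImage(img), truth = truth, annotations = ann,
       breast = breast)
}

#' Normalized mean difference of a phantom (or any labeled image)
#'
#' NMD = (mean graylevel over the MC mask - mean graylevel over the breast
#' region) / normalizer. Used to calibrate planted-MC contrast and to guide
#' the choice of the modeling constant K.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param truthMask binary MC mask.
#' @param breastRegion binary breast mask.
#' @param normalizer denominator (default 255).
#' @return Numeric NMD.
#' @export
phantomNmd <- function(image, truthMask, breastRegion, normalizer = 255) {
  if (sum(truthMask) == 0 || sum(breastRegion) == 0)
    stop("empty mask")
  p <- pixels(image)
  (mean(p[truthMask > 0]) - mean(p[breastRegion > 0])) / normalizer
}
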