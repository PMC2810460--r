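# Pipeline orchestration: standard model -> blend -> features -> self-learn
# -> classify -> post-process, plus the K sweep and file-based entry points
# used by the command-line wrapper (inst/scripts/mcdetect.R).

.defaultConfig <- function() {
  list(k = NULL, tissue = NULL, seed = 1L, bg_samples = 4300L, window = 9L,
       wavelet = "db4", levels = 2L, block_px = NULL, min_count = 3L,
       sliding = TRUE, n_train_clusters = 3L, variant = 50L)
}

# merge user config over defaults; unknown keys are an error; a character
# argument is taken as a YAML (or JSON) config file path
.resolveConfig <- function(config) {
  def <- .defaultConfig()
  if (is.null(config)) return(def)
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  def[names(config)] <- config
  if (!is.null(def$k) && (def$k <= 0 || def$k > 1))
    stop("config: k must be in (0, 1]")
  if (!def$variant %in% c(50L, 87L))
    stop("config: variant must be 50 or 87")
  def
}

# auto-place small training clusters for the standard model inside the
# breast region (seeded); returns a cluster-spec list
.autoTrainClusters <- function(breast, n, seed) {
  margin <- 20L
  interior <- EBImage::erode(breast, EBImage::makeBrush(2L * margin + 1L,
                                                        "box"))
  coords <- .maskCoords(matrix(as.numeric(interior > 0), nrow(breast),
                               ncol(breast)))
  if (nrow(coords) == 0L) stop("breast region too small to place the MC model")
  withr::with_seed(as.integer(seed), {
    out <- list(); chosen <- NULL; tries <- 0L
    while (length(out) < n && tries < 2000L) {
      tries <- tries + 1L
      ctr <- coords[sample.int(nrow(coords), 1L), ]
      if (!is.null(chosen) &&
          any(sqrt((chosen[, 1] - ctr[1])^2 + (chosen[, 2] - ctr[2])^2) < 60))
        next
      chosen <- rbind(chosen, ctr)
      out[[length(out) + 1L]] <- list(center = as.numeric(ctr), n_mcs = 4L,
                                      mc_radius_range = c(1, 2),
                                      cluster_radius = 12)
    }
    if (length(out) < n)
      stop("could not place ", n, " training clusters inside the breast")
    out
  })
}

#' Run the full microcalcification detection pipeline
#'
#' Steps: (1) Otsu breast mask; (2) choose the modeling constant K from the
#' tissue hint or breast statistics unless given; (3) build the binary
#' standard model (small disc clusters auto-placed inside the breast,
#' seeded) and blend it into the image; (4) extract the four-channel feature
#' stack of both the original and the hybrid image; (5) self-learn: MC-class
#' parameters from the hybrid stack at the synthetic pixels, healthy-class
#' parameters from two background ROIs; (6) classify every pixel of the
#' *original* image's stack (so the synthetic MCs themselves cannot surface
#' as detections); (7) post-process with the breast mask and the >= 3 per
#' 1 cm^2 cluster rule.
#'
#' @param image a \linkS4class{GrayImage} (or a path readable by
#'   \code{\link{readGray}}).
#' @param config named list overriding defaults: k, tissue, seed,
#'   bg_samples, window, wavelet, levels, block_px, min_count, sliding,
#'   n_train_clusters, variant. Unknown keys raise an error. The pipeline
#'   applies the cluster rule with a sliding 1 cm^2 window by default
#'   (sliding = TRUE) so that clusters straddling tile boundaries are not
#'   penalized; set sliding = FALSE for the fixed tiling.
#' @param annotations optional annotation data.frame; annotated circles are
#'   excluded from background ROI placement.
#' @param trainClusters optional explicit cluster specs for the standard
#'   model (as in \code{\link{makeStdModel}}).
#' @return list of class "MCDetection": raw and filtered
#'   \linkS4class{DetectionMask}s, class parameters, training sets,
#'   diagnostics (interclass mean differences, variance ratios, NMD), the
#'   resolved config and derived seeds, K, the breast mask and standard
#'   model.
#' @export
detectMC <- function(image, config = NULL, annotations = NULL,
                     trainClusters = NULL) {
  if (is.character(image)) image <- readGray(image)
  cfg <- .resolveConfig(config)
  breast <- breastMask(image)
  K <- if (is.null(cfg$k)) chooseK(image, breast, cfg$tissue) else cfg$k
  seeds <- list(std = .deriveSeed(cfg$seed, "stdmodel"),
                place = .deriveSeed(cfg$seed, "place"),
                roi = .deriveSeed(cfg$seed, "roi"))
  if (is.null(trainClusters))
    trainClusters <- .autoTrainClusters(breast, cfg$n_train_clusters,
                                        seeds$place)
  stdModel <- makeStdModel(dim(image), trainClusters, seed = seeds$std)
  model <- MCModel(stdModel, K)
  hybrid <- blendModel(image, model)

  spec <- waveletSpec(cfg$wavelet, cfg$levels)
  stack <- stackFeatures(image, spec, cfg$window)
  hybridStack <- stackFeatures(hybrid, spec, cfg$window)

  inner <- EBImage::erode(breast, EBImage::makeBrush(11L, "box"))
  inner <- matrix(as.numeric(inner > 0), nrow(breast), ncol(breast))
  training <- selectTrainingSamples(stdModel, bgTotal = cfg$bg_samples,
                                    seed = seeds$roi, exclusion = annotations,
                                    withinMask = inner)
  mcParams <- estimateParams(hybridStack, training@mcCoords)
  bgParams <- estimateParams(stack, training@bgCoords)

  raw <- classifyPixels(stack, mcParams, bgParams)
  blockPx <- if (is.null(cfg$block_px))
    cmToPixels(1, pixelPitch(image)) else as.integer(cfg$block_px)
  filtered <- applyPhysiologyFilter(raw, breast, blockPx, cfg$min_count,
                                    sliding = cfg$sliding)
  diag <- meanDifferenceDiagnostic(mcParams, bgParams, hybrid, breast,
                                   stdModel)
  structure(list(detection = raw, filtered = filtered, mcParams = mcParams,
                 bgParams = bgParams, training = training,
                 diagnostics = diag, K = K, breast = breast,
                 stdModel = stdModel, blockPx = blockPx, config = cfg,
                 seeds = seeds), class = "MCDetection")
}

#' @export
print.MCDetection <- function(x, ...) {
  cat(sprintf("MCDetection: K = %g, %d raw / %d filtered positive pixels\n",
              x$K, sum(pixels(x$detection)), sum(pixels(x$filtered))))
  cat(sprintf("  NMD = %.3f, graylevel mean difference = %.2f\n",
              x$diagnostics$nmd, x$diagnostics$meanDiff[1]))
  invisible(x)
}

#' Serialize / restore Gaussian class parameters
#'
#' @param params a \linkS4class{ClassParams}.
#' @param path JSON file path.
#' @return \code{writeClassParams}: invisibly the path;
#'   \code{readClassParams}: a \linkS4class{ClassParams}.
#' @rdname classParamsIO
#' @export
writeClassParams <- function(params, path) {
  jsonlite::write_json(list(mean = params@mean, cov = params@cov,
                            n_samples = params@nSamples),
                       path, digits = NA)
  invisible(path)
}

#' @rdname classParamsIO
#' @export
readClassParams <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  C <- as.matrix(js$cov)
  new("ClassParams", mean = as.numeric(js$mean), cov = C,
      logDet = as.numeric(determinant(C, logarithm = TRUE)$modulus),
      invCov = solve(C), nSamples = as.integer(js$n_samples))
}

#' File-based detection run
#'
#' Runs \code{\link{detectMC}} on an image file and writes: the raw and
#' filtered detection masks (PNG, 0/255), both classes' parameters (JSON),
#' the diagnostic record (JSON) and a run log capturing the full resolved
#' configuration and all derived seeds. Two runs with identical logs produce
#' identical outputs.
#'
#' @param imagePath input PGM/PNG mammogram.
#' @param outDir output directory (created if missing).
#' @param config,annotations as in \code{\link{detectMC}}.
#' @return The "MCDetection" result, invisibly.
#' @export
runDetect <- function(imagePath, outDir, config = NULL, annotations = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- detectMC(imagePath, config = config, annotations = annotations)
  writeGray(GrayImage(pixels(res$detection) * 255),
            file.path(outDir, "mask.png"))
  writeGray(GrayImage(pixels(res$filtered) * 255),
            file.path(outDir, "mask_filtered.png"))
  writeClassParams(res$mcParams, file.path(outDir, "params_mc.json"))
  writeClassParams(res$bgParams, file.path(outDir, "params_bg.json"))
  jsonlite::write_json(res$diagnostics, file.path(outDir, "diagnostics.json"),
                       digits = NA, auto_unbox = TRUE)
  log <- c(sprintf("image: %s", imagePath),
           sprintf("K: %g", res$K),
           sprintf("config: %s",
                   jsonlite::toJSON(res$config, auto_unbox = TRUE,
                                    null = "null")),
           sprintf("seeds: %s",
                   jsonlite::toJSON(res$seeds, auto_unbox = TRUE)))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(res)
}

#' Sweep the modeling constant K
#'
#' Re-runs the pipeline for each K (everything else, seeds included, held
#' fixed) and evaluates the filtered mask against the annotations. Duplicate
#' K values are dropped with a warning.
#'
#' @param image a \linkS4class{GrayImage} or path.
#' @param kValues numeric vector of modeling constants in (0, 1].
#' @param annotations ground-truth annotation data.frame (e.g. a phantom's).
#' @param config as in \code{\link{detectMC}}.
#' @return data.frame with one row per K: sensitivity, specificity, FP, TN.
#' @export
sweepK <- function(image, kValues, annotations, config = NULL) {
  if (length(kValues) < 1L) stop("at least one K value required")
  if (anyDuplicated(kValues)) {
    warning("duplicate K values dropped")
    kValues <- unique(kValues)
  }
  if (is.character(image)) image <- readGray(image)
  cfg <- .resolveConfig(config)
  rows <- lapply(kValues, function(k) {
    cfg$k <- k
    res <- detectMC(image, config = cfg, annotations = annotations)
    rep <- labelBlocks(res$filtered, annotations, blockPx = res$blockPx,
                       fpMinCount = cfg$min_count)
    data.frame(K = k, sensitivity = rep@sensitivity,
               specificity = rep@specificity, FP = rep@FP, TN = rep@TN)
  })
  do.call(rbind, rows)
}

#' Evaluate a detection mask against annotations
#'
#' Block evaluation with the primary 50-px / >= 3-centroid rule or the
#' 87-px / single-MC comparison variant.
#'
#' @param mask a \linkS4class{DetectionMask}, binary matrix, or mask image
#'   path (nonzero = detection).
#' @param annotations annotation data.frame or MIAS-format file path.
#' @param variant 50 (default) or 87.
#' @param blockPx optional override of the block size.
#' @return A \linkS4class{BlockReport}.
#' @export
evaluateMask <- function(mask, annotations, variant = 50L, blockPx = NULL) {
  if (is.character(mask)) mask <- DetectionMask((pixels(readGray(mask)) > 0) * 1L)
  if (is.matrix(mask)) mask <- DetectionMask(mask)
  if (is.character(annotations))
    annotations <- parseMiasAnnotations(annotations, nrow(pixels(mask)))
  if (variant == 87L) {
    if (is.null(blockPx)) blockPx <- 87L
    labelBlocks(mask, annotations, blockPx = blockPx, fpMinCount = 1L)
  } else {
    if (is.null(blockPx)) blockPx <- 50L
    labelBlocks(mask, annotations, blockPx = blockPx, fpMinCount = 3L)
  }
}
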