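# Block-based evaluation: the detection mask is tiled into non-overlapping
# blocks (50 x 50 px = 1 cm^2 at the mini-MIAS pitch); annotated MC regions
# score TP/FN, the remaining healthy blocks score FP/TN, and sensitivity /
# specificity follow as TP/(TP+FN) and TN/(TN+FP).

#' Label evaluation blocks and compute the report
#'
#' Tiles the mask into non-overlapping \code{blockPx} x \code{blockPx}
#' blocks (residual rows/columns beyond the last full block are dropped).
#' Blocks intersecting any annotation circle are excluded from the healthy
#' census. Each annotated region scores TP if at least one detected
#' component centroid falls inside its circle, FN otherwise. Every remaining
#' block is FP if it holds at least \code{fpMinCount} component centroids
#' (the clustered-MC rule), else TN.
#'
#' @param mask a \linkS4class{DetectionMask}.
#' @param annotations annotation data.frame (columns center_row, center_col,
#'   radius_px); may be empty or all-NA, in which case TP/FN are NA.
#' @param blockPx block edge in pixels (default 50).
#' @param fpMinCount centroids required for a false-positive block
#'   (default 3).
#' @param breast optional binary breast mask; when supplied, blocks lying
#'   entirely outside the breast are excluded from the healthy census too.
#' @return A \linkS4class{BlockReport}.
#' @export
labelBlocks <- function(mask, annotations = NULL, blockPx = 50L,
                        fpMinCount = 3L, breast = NULL) {
  m <- pixels(mask)
  h <- nrow(m); w <- ncol(m)
  if (blockPx > min(h, w)) stop("blockPx exceeds the image size")
  nbr <- h %/% blockPx; nbc <- w %/% blockPx

  lab <- .label8(m)
  cc <- .componentCentroids(lab)
  cc$block_row <- ifelse(cc$row <= nbr * blockPx,
                         (cc$row - 1) %/% blockPx + 1L, NA_integer_)
  cc$block_col <- ifelse(cc$col <= nbc * blockPx,
                         (cc$col - 1) %/% blockPx + 1L, NA_integer_)

  ann <- annotations
  if (!is.null(ann)) ann <- ann[!is.na(ann$center_row), , drop = FALSE]
  hasAnn <- !is.null(ann) && nrow(ann) > 0

  # annotated-region outcomes
  TP <- NA_integer_; FN <- NA_integer_
  if (hasAnn) {
    hit <- vapply(seq_len(nrow(ann)), function(i) {
      if (nrow(cc) == 0L) return(FALSE)
      any((cc$row - ann$center_row[i])^2 + (cc$col - ann$center_col[i])^2 <=
            ann$radius_px[i]^2)
    }, logical(1))
    TP <- sum(hit); FN <- sum(!hit)
  }

  # healthy-block census
  labels <- matrix("TN", nbr, nbc)
  if (hasAnn) {
    for (i in seq_len(nrow(ann))) {
      for (br in seq_len(nbr)) {
        r0 <- (br - 1) * blockPx + 1; r1 <- br * blockPx
        dr <- pmax(0, pmax(r0 - ann$center_row[i], ann$center_row[i] - r1))
        for (bc in seq_len(nbc)) {
          c0 <- (bc - 1) * blockPx + 1; c1 <- bc * blockPx
          dc <- max(0, max(c0 - ann$center_col[i], ann$center_col[i] - c1))
          if (dr^2 + dc^2 <= ann$radius_px[i]^2) labels[br, bc] <- "excluded"
        }
      }
    }
  }
  if (!is.null(breast)) {
    for (br in seq_len(nbr)) {
      for (bc in seq_len(nbc)) {
        if (labels[br, bc] == "excluded") next
        sub <- breast[((br - 1) * blockPx + 1):(br * blockPx),
                      ((bc - 1) * blockPx + 1):(bc * blockPx)]
        if (all(sub == 0)) labels[br, bc] <- "excluded"
      }
    }
  }
  inTile <- !is.na(cc$block_row) & !is.na(cc$block_col)
  if (any(inTile)) {
    tb <- table(factor(paste(cc$block_row[inTile], cc$block_col[inTile]),
                       levels = as.vector(outer(seq_len(nbr), seq_len(nbc),
                                                paste))))
    counts <- matrix(as.integer(tb), nbr, nbc)
  } else {
    counts <- matrix(0L, nbr, nbc)
  }
  fpSel <- labels != "excluded" & counts >= fpMinCount
  labels[fpSel] <- "FP"
  FP <- sum(fpSel)
  TN <- sum(labels == "TN")

  mm <- blockMetrics(TP, FN, TN, FP)
  new("BlockReport", blockPx = as.integer(blockPx),
      fpMinCount = as.integer(fpMinCount), blockLabels = labels,
      TP = as.integer(TP), FN = as.integer(FN), FP = as.integer(FP),
      TN = as.integer(TN), sensitivity = mm$sensitivity,
      specificity = mm$specificity, components = cc)
}

#' Sensitivity and specificity from block counts
#'
#' sensitivity = 100 * TP / (TP + FN); specificity = 100 * TN / (TN + FP).
#' A zero denominator (or NA counts) yields NA for that metric rather than
#' NaN.
#'
#' @param TP,FN,TN,FP block/region counts.
#' @return list(sensitivity, specificity) in percent.
#' @examples
#' blockMetrics(TP = 21, FN = 2, TN = 986, FP = 14)
#' @export
blockMetrics <- function(TP, FN, TN, FP) {
  sens <- if (is.na(TP) || is.na(FN) || TP + FN == 0) NA_real_ else
    100 * TP / (TP + FN)
  spec <- if (is.na(TN) || is.na(FP) || TN + FP == 0) NA_real_ else
    100 * TN / (TN + FP)
  list(sensitivity = sens, specificity = spec)
}

#' Mean false positives per image
#'
#' @param reports list of \linkS4class{BlockReport}s, one per mammogram.
#' @return Mean FP count across the reports.
#' @export
fpPerImage <- function(reports) {
  if (length(reports) == 0L) stop("no reports given")
  mean(vapply(reports, function(r) as.numeric(r@FP), numeric(1)))
}

#' Comparison evaluation variant: 87 x 87 blocks, single-MC FP rule
#'
#' Re-labels the mask with 87-pixel blocks and counts a false positive
#' whenever a single MC is detected in a healthy block (fpMinCount = 1),
#' the convention used by earlier two-stage detection studies.
#'
#' @inheritParams labelBlocks
#' @return A \linkS4class{BlockReport}.
#' @export
evaluateVariant87 <- function(mask, annotations = NULL, breast = NULL) {
  labelBlocks(mask, annotations, blockPx = 87L, fpMinCount = 1L,
              breast = breast)
}

#' Serialize a BlockReport
#'
#' Writes the summary as JSON and the per-block labels plus component table
#' as CSV.
#'
#' @param report a \linkS4class{BlockReport}.
#' @param prefix output path prefix; files <prefix>.json,
#'   <prefix>_blocks.csv and <prefix>_components.csv are written.
#' @return Invisibly, the JSON path.
#' @export
writeBlockReport <- function(report, prefix) {
  js <- list(block_px = report@blockPx, fp_min_count = report@fpMinCount,
             TP = report@TP, FN = report@FN, FP = report@FP, TN = report@TN,
             sensitivity = report@sensitivity,
             specificity = report@specificity)
  jsonlite::write_json(js, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  grid <- expand.grid(block_row = seq_len(nrow(report@blockLabels)),
                      block_col = seq_len(ncol(report@blockLabels)))
  grid$label <- as.vector(report@blockLabels)
  utils::write.csv(grid, paste0(prefix, "_blocks.csv"), row.names = FALSE)
  utils::write.csv(report@components, paste0(prefix, "_components.csv"),
                   row.names = FALSE)
  invisible(paste0(prefix, ".json"))
}
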