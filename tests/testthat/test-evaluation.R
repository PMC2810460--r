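test_that("an empty mask scores FN for the annotated region, TN elsewhere", {
  mask <- DetectionMask(matrix(0L, 300, 300))
  ann <- data.frame(center_row = 80, center_col = 80, radius_px = 20)
  rep <- labelBlocks(mask, ann, blockPx = 50L)
  expect_equal(rep@FN, 1L); expect_equal(rep@TP, 0L)
  expect_equal(rep@FP, 0L)
  expect_equal(rep@TN, sum(rep@blockLabels == "TN"))
  expect_equal(rep@sensitivity, 0)
})

test_that("detections only inside the annotation circle give TP without FP", {
  m <- matrix(0L, 300, 300)
  m[78, 80] <- 1L; m[82, 85] <- 1L
  ann <- data.frame(center_row = 80, center_col = 80, radius_px = 20)
  rep <- labelBlocks(DetectionMask(m), ann, blockPx = 50L)
  expect_equal(rep@TP, 1L); expect_equal(rep@FN, 0L)
  expect_equal(rep@FP, 0L)
  expect_equal(rep@sensitivity, 100)
})

test_that("a 1024 image tiles into 400 blocks; one loaded block is the FP", {
  m <- matrix(0L, 1024, 1024)
  m[10, 10] <- 1L; m[20, 20] <- 1L; m[30, 30] <- 1L
  m[15, 40] <- 1L; m[40, 15] <- 1L                  # 5 detections, block (1,1)
  rep <- labelBlocks(DetectionMask(m), NULL, blockPx = 50L)
  expect_equal(dim(rep@blockLabels), c(20L, 20L))
  expect_equal(rep@FP, 1L)
  expect_equal(rep@TN, 399L)
  expect_true(is.na(rep@TP)); expect_true(is.na(rep@sensitivity))
})

test_that("block metrics reproduce the defining ratios", {
  m <- blockMetrics(TP = 21, FN = 2, TN = 986, FP = 14)
  expect_equal(round(m$sensitivity, 1), 91.3)
  expect_equal(round(m$specificity, 1), 98.6)
  expect_equal(blockMetrics(0, 5, 10, 0)$sensitivity, 0)
  expect_true(is.na(blockMetrics(0, 0, 5, 5)$sensitivity))
  expect_true(is.na(blockMetrics(5, 5, 0, 0)$specificity))
})

test_that("metrics are invariant to a common scaling of all counts", {
  base <- blockMetrics(7, 3, 120, 9)
  for (k in c(2, 5, 10)) {
    sc <- blockMetrics(7 * k, 3 * k, 120 * k, 9 * k)
    expect_equal(sc$sensitivity, base$sensitivity)
    expect_equal(sc$specificity, base$specificity)
  }
})

test_that("block census is conserved and FP grows monotonically", {
  set.seed(15)
  ann <- data.frame(center_row = 125, center_col = 125, radius_px = 30)
  m <- matrix(0L, 500, 500)
  idx <- sample(500 * 500, 150)
  prev_fp <- -1L; prev_tn <- .Machine$integer.max
  for (frac in c(0.3, 0.6, 1)) {
    mm <- matrix(0L, 500, 500)
    mm[idx[seq_len(round(150 * frac))]] <- 1L
    rep <- labelBlocks(DetectionMask(mm), ann, blockPx = 50L)
    total <- sum(rep@blockLabels == "excluded") + rep@FP + rep@TN
    expect_equal(total, 100L)
    expect_gte(rep@FP, prev_fp); expect_lte(rep@TN, prev_tn)
    prev_fp <- rep@FP; prev_tn <- rep@TN
  }
})

test_that("blocks touching annotation circles are excluded from the census", {
  ann <- data.frame(center_row = 50, center_col = 50, radius_px = 10)
  rep <- labelBlocks(DetectionMask(matrix(0L, 200, 200)), ann, blockPx = 50L)
  # circle touches the four central blocks around (50, 50)
  expect_equal(sum(rep@blockLabels == "excluded"), 4L)
})

test_that("fpPerImage averages FP counts over reports", {
  mk <- function(fp) {
    m <- matrix(0L, 400, 400)
    if (fp > 0) for (b in seq_len(fp)) {
      r0 <- (b - 1) * 50 + 1
      m[r0, 1] <- 1L; m[r0 + 2, 3] <- 1L; m[r0 + 4, 5] <- 1L
    }
    labelBlocks(DetectionMask(m), NULL, blockPx = 50L)
  }
  expect_equal(fpPerImage(list(mk(6))), 6)
  expect_equal(fpPerImage(list(mk(1), mk(3))), 2)
  expect_error(fpPerImage(list()), "no reports")
})

test_that("the 87-px comparison variant counts single detections as FP", {
  m <- matrix(0L, 300, 300)
  m[100, 100] <- 1L                     # one lone detection
  r87 <- evaluateVariant87(DetectionMask(m))
  expect_equal(r87@blockPx, 87L); expect_equal(r87@fpMinCount, 1L)
  expect_equal(r87@FP, 1L)
  r50 <- labelBlocks(DetectionMask(m), NULL, blockPx = 50L, fpMinCount = 3L)
  expect_equal(r50@FP, 0L)
  empty <- evaluateVariant87(DetectionMask(matrix(0L, 300, 300)))
  expect_equal(empty@FP, 0L)
})

test_that("block reports serialize to JSON and CSV", {
  m <- matrix(0L, 200, 200); m[5, 5] <- 1L
  rep <- labelBlocks(DetectionMask(m), NULL, blockPx = 50L)
  pre <- tempfile()
  writeBlockReport(rep, pre)
  js <- jsonlite::read_json(paste0(pre, ".json"))
  expect_equal(js$FP, rep@FP)
  tab <- read.csv(paste0(pre, "_blocks.csv"))
  expect_equal(nrow(tab), 16L)
  expect_true(all(tab$label %in% c("FP", "TN", "excluded")))
})

test_that("oversized blocks are rejected", {
  expect_error(labelBlocks(DetectionMask(matrix(0L, 40, 40)), NULL,
                           blockPx = 50L), "exceeds")
})
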