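test_that("training-set selection reproduces the ~50x background ratio", {
  std <- matrix(0, 400, 400)
  set.seed(1)
  ones <- sample(400 * 400, 86)
  std[ones] <- 1
  ts <- selectTrainingSamples(std, bgTotal = 4300, seed = 5)
  expect_equal(nrow(ts@mcCoords), 86)
  expect_equal(nrow(ts@bgCoords), 2 * 47^2)          # two 47 x 47 ROIs = 4418
  ratio <- nrow(ts@bgCoords) / nrow(ts@mcCoords)
  expect_gt(ratio, 45); expect_lt(ratio, 56)         # "about 50 times"

  ts2 <- selectTrainingSamples(std, bgTotal = 4300, seed = 5)
  expect_identical(ts@bgRoiBoxes, ts2@bgRoiBoxes)

  expect_error(selectTrainingSamples(std, bgTotal = 100, seed = 1), "3x")
  expect_error(selectTrainingSamples(matrix(0, 50, 50), seed = 1), "empty")
})

test_that("background ROIs avoid the model, exclusions and each other", {
  std <- matrix(0, 200, 200)
  std[91:100, 91:100] <- 1   # central blob of 100 pixels
  excl <- data.frame(center_row = 40, center_col = 40, radius_px = 25)
  ts <- selectTrainingSamples(std, bgTotal = 800, seed = 11, exclusion = excl)
  b <- ts@bgRoiBoxes
  for (k in 1:2) {
    box <- b[[k]]
    sub <- std[box[1]:box[3], box[2]:box[4]]
    expect_equal(sum(sub), 0)
    # ROI pixels stay out of the exclusion circle
    gx <- expand.grid(r = box[1]:box[3], c = box[2]:box[4])
    expect_true(all((gx$r - 40)^2 + (gx$c - 40)^2 > 25^2))
  }
  expect_true(b[[1]][3] < b[[2]][1] || b[[2]][3] < b[[1]][1] ||
              b[[1]][4] < b[[2]][2] || b[[2]][4] < b[[1]][2])
})

test_that("parameter estimation recovers a known Gaussian", {
  set.seed(42)
  n <- 2e4
  mu <- c(10, -3, 0.5, 100)
  A <- matrix(c(2, 0.3, 0, 0.1,  0.3, 1, 0.2, 0,  0, 0.2, 0.5, 0,
                0.1, 0, 0, 3), 4, 4)
  Sigma <- crossprod(A)
  X <- matrix(rnorm(n * 4), n, 4) %*% chol(Sigma)
  X <- sweep(X, 2, mu, "+")
  p <- estimateParams(X)
  sds <- sqrt(diag(Sigma))
  expect_true(all(abs(p@mean - mu) < 3 * sds / sqrt(n)))
  relF <- norm(p@cov - Sigma, "F") / norm(Sigma, "F")
  expect_lt(relF, 0.05)
  expect_equal(p@invCov %*% p@cov, diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate training samples are rejected, near-singular ridged", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4)
  expect_error(estimateParams(X), "constant")
  expect_error(estimateParams(matrix(rnorm(8), 2, 4)), "at least 5")

  # one constant channel: ridge keeps the covariance invertible
  set.seed(3)
  Y <- cbind(rnorm(50), 7, rnorm(50), rnorm(50))
  p <- estimateParams(Y)
  expect_true(is.finite(p@logDet))
  expect_true(all(is.finite(p@invCov)))
})

test_that("decision value equals the closed form at simple points", {
  p <- new("ClassParams", mean = c(0, 0, 0, 0), cov = diag(4),
           logDet = 0, invCov = diag(4), nSamples = 10L)
  expect_equal(decisionValue(c(0, 0, 0, 0), p), 0)
  expect_equal(decisionValue(c(2, 0, 0, 0), p), -2)
  expect_error(decisionValue(c(1, NA, 0, 0), p), "finite")
})

test_that("decision value matches an independent linear-solve oracle", {
  set.seed(7)
  for (i in 1:200) {
    A <- matrix(rnorm(16), 4, 4)
    C <- crossprod(A) + diag(4) * 0.1
    m <- rnorm(4); x <- rnorm(4, sd = 3)
    p <- new("ClassParams", mean = m, cov = C,
             logDet = as.numeric(determinant(C, TRUE)$modulus),
             invCov = solve(C), nSamples = 10L)
    oracle <- -0.5 * log(det(C)) -
      0.5 * sum((x - m) * solve(C, x - m))
    expect_equal(decisionValue(x, p), oracle, tolerance = 1e-9)
  }
})

test_that("classification ties go to healthy and separated classes split cleanly", {
  h <- 10; w <- 10
  fs <- array(rnorm(h * w * 4), dim = c(h, w, 4))
  p <- estimateParams(matrix(rnorm(100 * 4), 100, 4))
  same <- classifyPixels(fs, p, p)
  expect_true(all(pixels(same) == 0))

  # two classes 10 sigma apart: empirical error far below 1%
  set.seed(8)
  n <- 20000
  Xmc <- matrix(rnorm(n * 4, mean = 10), n, 4)
  Xbg <- matrix(rnorm(n * 4, mean = 0), n, 4)
  pmc <- estimateParams(Xmc); pbg <- estimateParams(Xbg)
  test <- array(c(matrix(rnorm(2500 * 4, mean = 10), 2500, 4)),
                dim = c(50, 50, 4))
  lab <- pixels(classifyPixels(test, pmc, pbg))
  expect_gt(mean(lab), 0.99)
  test0 <- array(c(matrix(rnorm(2500 * 4, mean = 0), 2500, 4)),
                 dim = c(50, 50, 4))
  lab0 <- pixels(classifyPixels(test0, pmc, pbg))
  expect_lt(mean(lab0), 0.01)
})

test_that("classification is invariant under common per-channel affine maps", {
  set.seed(9)
  n <- 400
  Xmc <- matrix(rnorm(n * 4, mean = 1.5), n, 4)
  Xbg <- matrix(rnorm(n * 4), n, 4)
  test <- array(rnorm(20 * 20 * 4, mean = 0.7), dim = c(20, 20, 4))
  lab1 <- pixels(classifyPixels(test, estimateParams(Xmc),
                                estimateParams(Xbg)))
  scale <- c(3, 0.2, 10, 1.7); shift <- c(-5, 2, 100, 0)
  tr <- function(X) sweep(sweep(X, 2, scale, "*"), 2, shift, "+")
  testT <- test
  for (ch in 1:4) testT[, , ch] <- test[, , ch] * scale[ch] + shift[ch]
  lab2 <- pixels(classifyPixels(testT, estimateParams(tr(Xmc)),
                                estimateParams(tr(Xbg))))
  expect_identical(lab1, lab2)
})

test_that("mean-difference diagnostic reports NMD on the stated scale", {
  img <- GrayImage(matrix(188, 20, 20))
  model <- matrix(0, 20, 20); model[5, 5] <- 1
  px <- pixels(img); px[5, 5] <- 200.75
  img <- GrayImage(px)
  breast <- matrix(1, 20, 20); breast[5, 5] <- 0
  p <- estimateParams(matrix(rnorm(40), 10, 4))
  d <- meanDifferenceDiagnostic(p, p, img, breast, model)
  expect_equal(d$nmd, (200.75 - 188) / 255)   # 0.05
  expect_equal(d$meanDiff, rep(0, 4))
  expect_equal(d$varRatio, rep(1, 4))
  expect_error(meanDifferenceDiagnostic(p, p, img, matrix(0, 20, 20), model),
               "empty")
})

test_that("larger K raises the graylevel interclass mean difference", {
  img <- randImage(120, 120, seed = 31)
  std <- makeStdModel(c(120, 120), list(clusterSpec(c(60, 60), n = 4L)),
                      seed = 4)
  gaps <- vapply(c(0.2, 0.5, 1), function(k) {
    hyb <- blendModel(img, MCModel(std, K = k))
    mean(pixels(hyb)[std > 0]) - mean(pixels(hyb)[std == 0])
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("class parameters survive a JSON round trip", {
  p <- estimateParams(matrix(rnorm(200), 50, 4))
  f <- tempfile(fileext = ".json")
  writeClassParams(p, f)
  q <- readClassParams(f)
  expect_equal(q@mean, p@mean)
  expect_equal(q@cov, p@cov, ignore_attr = TRUE)
  expect_equal(q@nSamples, p@nSamples)
})
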