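test_that("graylevel feature is the identity", {
  img <- randImage(12, 15, seed = 1)
  expect_identical(graylevelFeature(img), pixels(img))
  expect_true(all(graylevelFeature(GrayImage(matrix(42, 4, 4))) == 42))
})

test_that("local-max rank matches the double-loop oracle and its bounds", {
  img <- randImage(16, 16, seed = 21)
  got <- localMaxRank(img, window = 9L)
  expect_equal(got, rankLoop(pixels(img), 9))
  expect_true(all(got >= 0 & got <= 1))

  expect_true(all(localMaxRank(GrayImage(matrix(5, 10, 10))) == 0))

  spike <- matrix(0, 15, 15); spike[8, 8] <- 255
  expect_equal(localMaxRank(GrayImage(spike), 9L)[8, 8], 1)

  expect_error(localMaxRank(img, window = 8L), "odd")
})

test_that("local-max rank is invariant to strictly monotone remapping", {
  img <- randImage(20, 20, seed = 22)
  a <- localMaxRank(img, 5L)
  remapped <- GrayImage(255 * (pixels(img) / 255)^3 + 0.01 * pixels(img))
  b <- localMaxRank(remapped, 5L)
  expect_equal(a, b)
})

test_that("wavelet analysis/synthesis is a perfect-reconstruction pair", {
  img <- randImage(128, 128, seed = 23)
  bank <- mcdetect:::.waveletBank("db4")
  dec <- mcdetect:::.wavedec2(pixels(img), 2, bank)
  rec <- mcdetect:::.waverec2(dec, bank)
  expect_lt(max(abs(rec - pixels(img))), 1e-6)
})

test_that("wavelet highpass annihilates constants and near-annihilates ramps", {
  expect_lt(max(abs(waveletHighpass(GrayImage(matrix(9, 64, 64))))), 1e-6)
  ramp <- GrayImage(outer(1:128, 1:128, function(i, j) i + 2 * j))
  hp <- waveletHighpass(ramp)
  # db4 vanishing moments annihilate a ramp away from the boundary-effect
  # zone (filter support spreads ~(L-1)*2^levels = 28 px inward)
  expect_lt(max(abs(hp[30:99, 30:99])), 1e-6)
})

test_that("highpass + approximation-only reconstruction add back to the input", {
  img <- randImage(96, 96, seed = 24)
  bank <- mcdetect:::.waveletBank("db4")
  dec <- mcdetect:::.wavedec2(pixels(img), 2, bank)
  hp <- waveletHighpass(img)
  decA <- dec
  for (l in seq_along(decA$details)) {
    decA$details[[l]]$LH[] <- 0
    decA$details[[l]]$HL[] <- 0
    decA$details[[l]]$HH[] <- 0
  }
  approxOnly <- mcdetect:::.waverec2(decA, bank)
  expect_lt(max(abs(hp + approxOnly - pixels(img))), 1e-6)
})

test_that("db4 subbands and highpass match frozen reference coefficients", {
  # reference values computed once with an independent DWT implementation
  # (PyWavelets 1.9, mode = symmetric) on this formula-defined matrix
  m <- outer(1:12, 1:12, function(i, j) ((i * 13 + j * 7) %% 11) +
               ((i * j) %% 5) * 0.25)
  bank <- mcdetect:::.waveletBank("db4")
  d1 <- mcdetect:::.wavedec2(m, 1, bank)
  expect_equal(d1$approx[1, 1], 11.171174035044675, tolerance = 1e-12)
  expect_equal(d1$approx[3, 4], 8.545990114440102, tolerance = 1e-12)
  expect_equal(d1$details[[1]]$HH[4, 4], 3.1547266019853595, tolerance = 1e-12)
  d2 <- mcdetect:::.wavedec2(m, 2, bank)
  d2$approx[] <- 0
  hp <- mcdetect:::.waverec2(d2, bank)
  expect_equal(hp[1, 1], 3.990916284427441, tolerance = 1e-10)
  expect_equal(hp[6, 8], -2.770776415262896, tolerance = 1e-10)
  expect_equal(hp[12, 12], 3.7617644309759104, tolerance = 1e-10)
  expect_equal(sum(abs(hp)), 400.779809097874, tolerance = 1e-9)
})

test_that("images smaller than the filter support are rejected", {
  expect_error(waveletHighpass(GrayImage(matrix(1:16 + 0, 4, 4))),
               "too small")
})

test_that("ED8 matches Eq-style nested-loop oracle exactly", {
  img <- randImage(32, 32, seed = 25)
  expect_equal(ed8(img), ed8Loop(pixels(img)))

  expect_true(all(ed8(GrayImage(matrix(3, 8, 8))) == 0))

  m <- matrix(0, 3, 3); m[2, 2] <- 10
  expect_equal(ed8(GrayImage(m))[2, 2], 80)   # 8 neighbors, |0 - 10| each
})

test_that("ED8 is translation-equivariant in the interior and 1-homogeneous", {
  img <- randImage(24, 24, seed = 26)
  m <- pixels(img)
  shifted <- m[c(2:24, 24), c(3:24, 24, 24)]    # shift by (-1, -2)
  a <- ed8(GrayImage(m)); b <- ed8(GrayImage(shifted))
  expect_equal(a[3:21, 4:20], b[2:20, 2:18])

  expect_equal(ed8(GrayImage(2.5 * m)), 2.5 * ed8(img))
})

test_that("stackFeatures registers all four channels spatially", {
  img <- randImage(48, 48, seed = 27)
  fs <- stackFeatures(img)
  expect_equal(dim(fs), c(48, 48, 4))
  expect_identical(fs[, , "gray"], pixels(img))
  expect_equal(fs[, , "rank"], localMaxRank(img, 9L))
  expect_equal(fs[, , "ed8"], ed8(img))

  flat <- stackFeatures(GrayImage(matrix(7, 32, 32)))
  expect_true(all(flat[, , "rank"] == 0))
  expect_lt(max(abs(flat[, , "wavelet"])), 1e-6)
  expect_true(all(flat[, , "ed8"] == 0))

  # a bright blob drives the ED8 channel hardest at its rim
  blob <- matrix(100, 64, 64)
  blob <- mcdetect:::.stampDisc(blob, 32, 32, 2.2, value = 200)
  fs2 <- stackFeatures(GrayImage(blob))
  peak <- which(fs2[, , "ed8"] == max(fs2[, , "ed8"]), arr.ind = TRUE)[1, ]
  expect_lt(abs(sqrt(sum((peak - c(32, 32))^2)) - 2.2), 1.6)
})

test_that(".featuresAt pulls registered pattern vectors", {
  img <- randImage(20, 20, seed = 28)
  fs <- stackFeatures(img)
  co <- cbind(c(3L, 17L), c(5L, 11L))
  X <- mcdetect:::.featuresAt(fs, co)
  expect_equal(X[1, ], fs[3, 5, ], ignore_attr = TRUE)
  expect_equal(X[2, ], fs[17, 11, ], ignore_attr = TRUE)
})
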