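test_that("quantisation is the floor-binning map and identity at full depth", {
  img <- grayImage(matrix(sample(0:255, 100, TRUE), 10, 10))
  expect_identical(pixels(quantizeImage(img, 256)), pixels(img))
  two <- quantizeImage(grayImage(matrix(c(0, 255), 1)), 2)
  expect_identical(as.vector(pixels(two)), c(0, 1))
  set.seed(3)
  img <- grayImage(matrix(runif(64, 0, 255), 8, 8))
  q <- pixels(quantizeImage(img, 8))
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (cc in 1:8)
    oracle[r, cc] <- min(floor(pixels(img)[r, cc] / 256 * 8), 7)
  expect_identical(q, oracle)
  expect_error(quantizeImage(img, 1), "Q")
})

test_that("direction offsets follow the four-direction table", {
  expect_identical(directionOffset(0), c(0L, 1L))
  expect_identical(directionOffset(45), c(-1L, 1L))
  expect_identical(directionOffset(90), c(-1L, 0L))
  expect_identical(directionOffset(135), c(-1L, -1L))
  expect_error(directionOffset(30), "theta")
})

test_that("co-occurrence counting matches hand counts and the worked example", {
  # 3x3 constant image, d=1, horizontal: 3 rows x 2 in-bounds pairs
  g <- computeGLCM(grayImage(matrix(4, 3, 3), c(0, 7)), 1, 0, 8)
  expect_equal(glcmCounts(g)[5, 5], 6)
  expect_equal(sum(glcmCounts(g)), 6)

  ex <- glcmExampleImage()
  gex <- computeGLCM(ex, d = 1, theta = 0, Q = 5)
  expect_equal(glcmCounts(gex)[1, 3], 2)   # pair (0, 2) occurs twice

  # oversized displacement: all-zero matrix, not an error
  gz <- computeGLCM(ex, d = 10, theta = 0, Q = 5)
  expect_true(all(glcmCounts(gz) == 0))
})

test_that("co-occurrence counting equals the exhaustive pair oracle", {
  set.seed(20)
  for (k in 1:100) {
    Q <- sample(c(4L, 8L), 1)
    H <- sample(6:12, 1); W <- sample(6:12, 1)
    lev <- matrix(sample(0:(Q - 1), H * W, TRUE), H, W)
    img <- grayImage(lev, c(0, Q - 1))
    d <- sample(1:3, 1)
    th <- sample(c(0, 45, 90, 135), 1)
    expect_identical(glcmCounts(computeGLCM(img, d, th, Q)),
                     bruteGLCM(lev, d, th, Q))
  }
})

test_that("in-bounds pair totals match their closed forms", {
  set.seed(6)
  for (k in 1:20) {
    H <- sample(5:12, 1); W <- sample(5:12, 1); d <- sample(1:3, 1)
    lev <- matrix(sample(0:3, H * W, TRUE), H, W)
    img <- grayImage(lev, c(0, 3))
    expect_equal(sum(glcmCounts(computeGLCM(img, d, 0, 4))), H * (W - d))
    expect_equal(sum(glcmCounts(computeGLCM(img, d, 90, 4))), (H - d) * W)
    expect_equal(sum(glcmCounts(computeGLCM(img, d, 45, 4))), (H - d) * (W - d))
    expect_equal(sum(glcmCounts(computeGLCM(img, d, 135, 4))), (H - d) * (W - d))
  }
})

test_that("symmetrisation adds the transpose and doubles the total", {
  ex <- glcmExampleImage()
  g <- computeGLCM(ex, 1, 0, 5)
  s <- symmetrizeGLCM(g)
  expect_identical(glcmCounts(s), glcmCounts(g) + t(glcmCounts(g)))
  expect_identical(glcmCounts(s), t(glcmCounts(s)))
  expect_equal(sum(glcmCounts(s)), 2 * sum(glcmCounts(g)))
  # a single off-diagonal entry mirrors
  expect_equal(glcmCounts(s)[1, 3], glcmCounts(s)[3, 1])
})

test_that("normalisation yields a probability matrix and rejects empty counts", {
  ex <- glcmExampleImage()
  n <- normalizeGLCM(symmetrizeGLCM(computeGLCM(ex, 1, 0, 5)))
  expect_equal(sum(glcmProbs(n)), 1, tolerance = 1e-12)
  expect_identical(glcmProbs(n), t(glcmProbs(n)))
  g <- computeGLCM(ex, 1, 0, 5)
  expect_equal(glcmProbs(normalizeGLCM(g)), glcmCounts(g) / sum(glcmCounts(g)))
  gz <- computeGLCM(ex, 10, 0, 5)
  expect_error(normalizeGLCM(gz), "all-zero")
})

test_that("Haralick features honour analytic anchors", {
  # constant image: single-cell distribution
  g <- computeGLCM(grayImage(matrix(2, 6, 6), c(0, 7)), 1, 0, 8)
  f <- haralickFeatures(normalizeGLCM(symmetrizeGLCM(g)))
  expect_equal(f[["ASM"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_true(all(is.finite(f)))

  # 2-level perfect checkerboard: every horizontal pair differs by one level
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  fcb <- haralickFeatures(normalizeGLCM(symmetrizeGLCM(
    computeGLCM(grayImage(cb, c(0, 1)), 1, 0, 2))))
  expect_equal(fcb[["Contrast"]], 1)
})

test_that("Haralick features agree with an independent literal transcription", {
  set.seed(14)
  for (k in 1:25) {
    Q <- 8L
    lev <- matrix(sample(0:(Q - 1), 100, TRUE, prob = runif(Q)), 10, 10)
    g <- symmetrizeGLCM(computeGLCM(grayImage(lev, c(0, Q - 1)), 1,
                                    sample(c(0, 45, 90, 135), 1), Q))
    P <- glcmProbs(normalizeGLCM(g))
    got <- haralickFeatures(new("NGLCM", probs = P))
    expect_equal(unname(got), bruteHaralick(P), tolerance = 1e-8)
  }
})

test_that("feature bounds and transposition invariance hold", {
  set.seed(9)
  for (k in 1:15) {
    lev <- matrix(sample(0:7, 144, TRUE), 12, 12)
    img <- grayImage(lev, c(0, 7))
    fourDir <- function(m) {
      fs <- sapply(c(0, 45, 90, 135), function(th)
        haralickFeatures(normalizeGLCM(symmetrizeGLCM(
          computeGLCM(m, 1, th, 8)))))
      rowMeans(fs)
    }
    f <- fourDir(img)
    ft <- fourDir(grayImage(t(lev), c(0, 7)))
    expect_equal(f, ft, tolerance = 1e-10)
    expect_gte(f[["ASM"]], 0); expect_lte(f[["ASM"]], 1)
    expect_gte(f[["Entropy"]], 0)
    expect_gte(f[["Contrast"]], 0)
  }
  # contrast is zero iff the matrix is diagonal
  diagP <- diag(c(0.25, 0.75))
  expect_equal(haralickFeatures(new("NGLCM", probs = diagP))[["Contrast"]], 0)
})

test_that("texture maps have the promised scalar counts in both modes", {
  img <- grayImage(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  # whole-ROI mode: 30 distances x 4 directions = 120 NGLCMs, 1680 scalars
  fr <- textureFeatureMap(img, glcmConfig(Q = 32, distances = 1:30,
                                          window = NULL))
  expect_equal(nrow(fr@features), 120)
  expect_equal(nrow(fr@features) * 14, 1680)
  # one distance, one direction: 14 scalars per window
  f1 <- textureFeatureMap(img, glcmConfig(Q = 16, distances = 1,
                                          directions = 0, window = 9,
                                          stride = 16))
  perWin <- table(f1@features$win)
  expect_true(all(perWin == 1))
  expect_equal(ncol(f1@features) - 5L, 14L)
  expect_error(textureFeatureMap(img, glcmConfig(window = 65)), "window")
})

test_that("windowed features equal the single-matrix chain and translate within halves", {
  set.seed(2)
  img <- grayImage(matrix(runif(23 * 23, 0, 255), 23, 23))
  cfg <- glcmConfig(Q = 8, distances = c(1, 3), window = 11, stride = 6)
  fmap <- textureFeatureMap(img, cfg)
  q <- quantizeImage(img, 8)
  for (i in sample(nrow(fmap@features), 12)) {
    row <- fmap@features[i, ]
    sub <- grayImage(pixels(q)[row$row:(row$row + 10), row$col:(row$col + 10)],
                     c(0, 7))
    ref <- haralickFeatures(normalizeGLCM(symmetrizeGLCM(
      computeGLCM(sub, row$d, row$theta, 8))))
    expect_equal(unname(as.numeric(row[haralickFeatureNames()])), unname(ref),
                 tolerance = 1e-8)
  }

  # half-dark / half-bright image: windows inside one half share features
  hb <- matrix(40, 40, 40); hb[, 21:40] <- 200
  fm <- textureFeatureMap(grayImage(hb), glcmConfig(Q = 8, distances = 1,
                                                    window = 9, stride = 2))
  feat <- fm@features
  leftWins <- feat[feat$col + 8 <= 20, ]
  byD <- split(leftWins, interaction(leftWins$d, leftWins$theta))
  for (blk in byD) {
    if (nrow(blk) < 2) next
    rng <- apply(blk[haralickFeatureNames()], 2, function(v) diff(range(v)))
    expect_lt(max(rng), 1e-12)
  }
})

test_that("the initial texture mask finds phantom lungs and is reproducible", {
  cfg <- glcmMapConfig(window = 9L, stride = 2L)
  dscs <- c()
  for (s in 1:4) {
    ph <- generatePhantom(phantomParams(seed = s))
    den <- wienerDenoise(ph@image)
    fmap <- textureFeatureMap(den, cfg)
    m1 <- initialTextureSegmentation(fmap, den, seed = 7)
    m2 <- initialTextureSegmentation(fmap, den, seed = 7)
    expect_identical(pixels(m1), pixels(m2))
    expect_false(isTRUE(m1@metadata$fallback))
    dscs <- c(dscs, dice(m1, ph@mask))
  }
  expect_gte(mean(dscs), 0.80)

  # uniform texture: degenerate, falls back and is flagged
  u <- grayImage(matrix(128, 64, 64))
  fu <- textureFeatureMap(u, cfg)
  mu <- initialTextureSegmentation(fu, u, seed = 7)
  expect_true(mu@metadata$fallback)
  expect_true(all(pixels(mu) == 0) || all(pixels(mu) == 1))
})
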