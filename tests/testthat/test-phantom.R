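test_that("phantoms are seeded-reproducible and piecewise constant without texture", {
  p <- phantomParams(seed = 5)
  a <- generatePhantom(p); b <- generatePhantom(p)
  expect_identical(pixels(a@image), pixels(b@image))
  expect_identical(pixels(a@mask), pixels(b@mask))
  c2 <- generatePhantom(phantomParams(seed = 6))
  expect_false(identical(pixels(a@image), pixels(c2@image)))

  flat <- generatePhantom(phantomParams(seed = 5, textureAmplitude = 0,
                                        noise = noiseModel(0, 0)))
  vals <- sort(unique(as.vector(pixels(flat@image))))
  expect_length(vals, 3)               # air, lung, thorax
  expect_lt(vals[2], vals[3])
  expect_error(phantomParams(lungIntensity = 200, thoraxIntensity = 150),
               "lungIntensity")
  expect_error(phantomParams(size = 16), "size")
})

test_that("lungs are darker than the thorax ring across many seeds", {
  for (s in 1:50) {
    ph <- generatePhantom(phantomParams(seed = s))
    img <- pixels(ph@image); mk <- pixels(ph@mask) == 1
    thoraxRing <- !mk & img > 150     # bright chest wall pixels
    expect_gt(mean(img[thoraxRing]), mean(img[mk]))
  }
})

test_that("the lung area fraction stays within its band for seeds 0..99", {
  for (s in 0:99) {
    ph <- generatePhantom(phantomParams(seed = s))
    frac <- mean(pixels(ph@mask))
    expect_gte(frac, 0.10)
    expect_lte(frac, 0.45)
  }
})

test_that("reticular texture carries more GLCM contrast than ground glass", {
  higher <- 0L
  for (s in 1:10) {
    inLungWindow <- function(kind) {
      ph <- generatePhantom(phantomParams(seed = s, textureKind = kind,
                                          noise = noiseModel(0, 0)))
      mk <- pixels(ph@mask)
      # window centred in the left lung field
      px <- which(mk == 1, arr.ind = TRUE)
      px <- px[px[, 2] < ncol(mk) / 2, , drop = FALSE]
      ctr <- round(colMeans(px))
      win <- pixels(ph@image)[(ctr[1] - 4):(ctr[1] + 4), (ctr[2] - 4):(ctr[2] + 4)]
      q <- quantizeImage(grayImage(win), 32)
      f <- haralickFeatures(normalizeGLCM(symmetrizeGLCM(
        computeGLCM(q, 1, 0, 32))))
      f[["Contrast"]]
    }
    if (inLungWindow("reticular") > inLungWindow("ground_glass"))
      higher <- higher + 1L
  }
  expect_equal(higher, 10L)
})

test_that("datasets land on disk with manifests the reader understands", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(6, phantomParams(), seed = 9, dir = dir)
  expect_length(ds$samples, 6)
  expect_length(list.files(dir, pattern = "^img_.*png$"), 6)
  expect_length(list.files(dir, pattern = "^mask_.*png$"), 6)
  mf <- readManifest(ds$manifest)
  expect_equal(nrow(mf), 6)
  expect_true(all(file.exists(mf$image)), all(file.exists(mf$mask)))

  # per-sample seeds make samples pairwise distinct
  sums <- vapply(ds$samples, function(s) sum(pixels(s@image)), 0)
  expect_equal(length(unique(sums)), 6)

  # round-trip: written images reload to the generated pixels
  img1 <- readGrayImage(mf$image[1])
  expect_equal(pixels(img1), pixels(ds$samples[[1]]@image), tolerance = 0.51)
  expect_identical(pixels(readMask(mf$mask[1])), pixels(ds$samples[[1]]@mask))
  expect_error(generateDataset(0, phantomParams(), 1, dir), "n must be")
})
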