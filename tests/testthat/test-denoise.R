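test_that("additive Gaussian noise has the configured moments and is seeded", {
  img <- grayImage(matrix(128, 512, 512))
  # degenerate noise: exact identity
  out0 <- addGaussianNoise(img, noiseModel(mu = 0, sigma = 0, seed = 1))
  expect_identical(pixels(out0), pixels(img))

  n1 <- addGaussianNoise(img, noiseModel(mu = 0, sigma = 10, seed = 99))
  n2 <- addGaussianNoise(img, noiseModel(mu = 0, sigma = 10, seed = 99))
  expect_identical(pixels(n1), pixels(n2))
  n3 <- addGaussianNoise(img, noiseModel(mu = 0, sigma = 10, seed = 100))
  expect_false(identical(pixels(n1), pixels(n3)))

  # law of large numbers at n = 512^2 (no clipping at these settings)
  expect_lt(abs(mean(pixels(n1)) - 128), 0.2)
  expect_lt(abs(sd(pixels(n1)) - 10), 0.2)

  # residual normality sanity: skewness of the noise field
  res <- pixels(n1) - 128
  skew <- mean(res^3) / sd(res)^3
  expect_lt(abs(skew), 0.1)

  # clipping keeps the declared range
  big <- addGaussianNoise(img, noiseModel(mu = 200, sigma = 50, seed = 1))
  expect_lte(max(pixels(big)), 255)
  expect_error(noiseModel(sigma = -1), "sigma")
})

test_that("mseImage matches hand arithmetic and a double-loop oracle", {
  expect_equal(mseImage(grayImage(matrix(5, 3, 3)), grayImage(matrix(5, 3, 3))), 0)
  a <- grayImage(matrix(c(0, 0), 1)); b <- grayImage(matrix(c(3, 4), 1))
  expect_equal(mseImage(a, b), 12.5)
  set.seed(8)
  x <- grayImage(matrix(runif(60, 0, 255), 6, 10))
  y <- grayImage(matrix(runif(60, 0, 255), 6, 10))
  acc <- 0
  for (r in 1:6) for (cc in 1:10) acc <- acc + (pixels(x)[r, cc] - pixels(y)[r, cc])^2
  expect_equal(mseImage(x, y), acc / 60, tolerance = 1e-9)
  expect_error(mseImage(x, grayImage(matrix(0, 2, 2))), "mismatch")
})

test_that("Wiener filtering passes constants through exactly and needs a fitting window", {
  cimg <- grayImage(matrix(77, 16, 16))
  for (w in c(3L, 5L, 7L))
    expect_identical(pixels(wienerDenoise(cimg, wienerConfig(window = w))),
                     pixels(cimg))
  expect_error(wienerDenoise(grayImage(matrix(1, 4, 4)), wienerConfig(window = 5)),
               "window")
  expect_error(wienerConfig(window = 4), "odd")
  expect_error(wienerConfig(noiseVariance = -2), "noiseVariance")
})

test_that("Wiener filtering reduces noise on phantoms and pure-noise fields", {
  # pure noise on a constant: output variance drops
  base <- grayImage(matrix(128, 64, 64))
  noisy <- addGaussianNoise(base, noiseModel(0, 20, seed = 5))
  den <- wienerDenoise(noisy)
  expect_lt(var(as.vector(pixels(den))), var(as.vector(pixels(noisy))))

  # seeded clean phantom + noise: MSE to the clean image shrinks
  clean <- generatePhantom(phantomParams(seed = 2,
                                         noise = noiseModel(0, 0)))@image
  noisy <- addGaussianNoise(clean, noiseModel(0, 15, seed = 3))
  den <- wienerDenoise(noisy)
  expect_lt(mseImage(den, clean), mseImage(noisy, clean))

  # across sigmas and seeds, denoising helps in >= 95% of trials
  wins <- 0L; total <- 0L
  for (sg in c(5, 10, 20)) for (k in 1:7) {
    clean <- generatePhantom(phantomParams(seed = k, noise = noiseModel(0, 0)))@image
    noisy <- addGaussianNoise(clean, noiseModel(0, sg, seed = 100 + k))
    den <- wienerDenoise(noisy)
    total <- total + 1L
    if (mseImage(den, clean) < mseImage(noisy, clean)) wins <- wins + 1L
  }
  expect_gte(wins / total, 0.95)
})
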