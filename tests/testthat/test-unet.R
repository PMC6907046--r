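# analytic conv parameter count: k^2 * cin * cout weights + cout biases
convP <- function(k, cin, cout) k * k * cin * cout + cout

test_that("construction yields the doubling channel ladder and the analytic parameter count", {
  model <- buildUNet(unetConfig(depth = 3, inChannels = 2, baseChannels = 16,
                                numClasses = 2), seed = 7)
  expect_equal(model$params$enc1_conv1$cout, 16)
  expect_equal(model$params$enc2_conv1$cout, 32)
  expect_equal(model$params$enc3_conv1$cout, 64)
  expect_equal(model$params$bottleneck_conv1$cout, 128)
  expect_equal(model$params$dec3_conv1$cout, 64)
  expect_equal(model$params$dec1_conv2$cout, 16)

  # layer-by-layer closed-form sum, derived by hand before coding
  expected <- convP(3, 2, 16) + convP(3, 16, 16) +      # enc1
    convP(3, 16, 32) + convP(3, 32, 32) +               # enc2
    convP(3, 32, 64) + convP(3, 64, 64) +               # enc3
    convP(3, 64, 128) + convP(3, 128, 128) +            # bottleneck
    (2 * 2 * 128 * 64 + 64) + convP(3, 128, 64) + convP(3, 64, 64) +  # dec3
    (2 * 2 * 64 * 32 + 32) + convP(3, 64, 32) + convP(3, 32, 32) +    # dec2
    (2 * 2 * 32 * 16 + 16) + convP(3, 32, 16) + convP(3, 16, 16) +    # dec1
    convP(1, 16, 2)                                     # head
  expect_equal(countParams(model), expected)

  # doubling base channels scales conv weights by the predicted factor (4x)
  m32 <- buildUNet(unetConfig(baseChannels = 32), seed = 7)
  w16 <- length(model$params$enc2_conv2$W)
  w32 <- length(m32$params$enc2_conv2$W)
  expect_equal(w32 / w16, 4)

  # seeded initialisation is reproducible
  m2 <- buildUNet(unetConfig(), seed = 7)
  expect_identical(model$params, m2$params)
  m3 <- buildUNet(unetConfig(), seed = 8)
  expect_false(identical(model$params$enc1_conv1$W, m3$params$enc1_conv1$W))
})

test_that("forward passes have the contracted shapes and softmax normalisation", {
  model <- buildUNet(unetConfig(baseChannels = 4), seed = 1)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2))
  s <- unetForward(model, x)
  expect_equal(dim(s), c(64, 64, 2))
  sm <- softmaxScores(s)
  expect_equal(apply(sm, c(1, 2), sum), matrix(1, 64, 64), tolerance = 1e-6)

  expect_error(unetForward(model, array(0, c(63, 63, 2))), "divisible by 8")
  expect_error(unetForward(model, array(0, c(64, 64, 3))), "H x W x 2")

  # valid-padding variant shrinks deterministically (20 -> 4 at depth 1)
  mv <- buildUNet(unetConfig(depth = 1, baseChannels = 2, padding = "valid"),
                  seed = 1)
  sv <- ildseg:::unetForwardCore(mv, array(runif(20 * 20 * 2), c(20, 20, 2)))$scores
  expect_equal(dim(sv), c(4, 4, 2))
})

test_that("the weighted cross-entropy matches analytic values and an independent oracle", {
  # uniform logits, two classes, unit weights: ln 2 per pixel
  s <- array(0, c(4, 4, 2))
  lab <- matrix(sample(0:1, 16, TRUE), 4, 4)
  expect_equal(weightedCELoss(s, lab), log(2), tolerance = 1e-12)
  # all-zero weights kill the loss
  expect_equal(weightedCELoss(s, lab, matrix(0, 4, 4)), 0)

  set.seed(5)
  sc <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  w <- matrix(runif(16), 4, 4)
  # from-scratch softmax + log oracle
  acc <- 0
  for (r in 1:4) for (cc in 1:4) {
    z <- sc[r, cc, ]
    pr <- exp(z) / sum(exp(z))
    acc <- acc - w[r, cc] * log(pr[lab[r, cc] + 1])
  }
  expect_equal(weightedCELoss(sc, lab, w), acc / 16, tolerance = 1e-7)
  expect_gte(weightedCELoss(sc, lab, w), 0)
  expect_error(weightedCELoss(sc, matrix(0, 2, 2)), "labels")
})

test_that("backpropagated gradients match central finite differences", {
  set.seed(2)
  model <- buildUNet(unetConfig(depth = 2, baseChannels = 3), seed = 5)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  lab <- matrix(rbinom(256, 1, 0.5), 16, 16)
  w <- matrix(runif(256, 0.5, 1.5), 16, 16)
  lg <- ildseg:::unetLossAndGrads(model, x, lab, w)
  eps <- 1e-6
  for (nm in c("enc1_conv1", "enc2_conv2", "bottleneck_conv1", "dec2_up",
               "dec1_conv2", "head")) {
    i <- sample(length(model$params[[nm]]$W), 1)
    mp <- model; mp$params[[nm]]$W[i] <- mp$params[[nm]]$W[i] + eps
    mm <- model; mm$params[[nm]]$W[i] <- mm$params[[nm]]$W[i] - eps
    num <- (ildseg:::unetLossAndGrads(mp, x, lab, w)$loss -
            ildseg:::unetLossAndGrads(mm, x, lab, w)$loss) / (2 * eps)
    expect_equal(lg$grads[[nm]]$W[i], num, tolerance = 1e-4)
  }
})

test_that("training is seeded-deterministic and records one loss per epoch", {
  set.seed(1)
  ds <- lapply(1:3, function(i)
    list(stack = array(runif(16 * 16 * 2), c(16, 16, 2)),
         mask = matrix(rbinom(256, 1, 0.4), 16, 16)))
  model <- buildUNet(unetConfig(depth = 2, baseChannels = 4), seed = 3)
  f1 <- trainUNet(model, ds, trainConfig(batchSize = 2, learningRate = 1e-3,
                                         epochs = 4, seed = 11))
  f2 <- trainUNet(model, ds, trainConfig(batchSize = 2, learningRate = 1e-3,
                                         epochs = 4, seed = 11))
  expect_length(f1$lossHistory, 4)
  expect_equal(f1$lossHistory, f2$lossHistory, tolerance = 1e-6)
  expect_identical(f1$model$params, f2$model$params)
  expect_error(trainUNet(model, list(), trainConfig()), "nonempty")
})

test_that("prediction is binary and class channels are symmetric", {
  case <- phantomTrainingCase(seed = 7)
  model <- buildUNet(unetConfig(baseChannels = 4), seed = 2)
  # distinct head biases so no pixel is exactly tied between classes
  model$params$head$b <- c(0.05, -0.07)
  pm <- predictMask(model, case$denoised, case$init)
  expect_true(all(pixels(pm) %in% c(0, 1)))

  # permuting the class channels and relabelling flips every decision
  swapped <- model
  swapped$params$head$W <- model$params$head$W[, 2:1, drop = FALSE]
  swapped$params$head$b <- model$params$head$b[2:1]
  ps <- predictMask(swapped, case$denoised, case$init)
  s <- unetForward(model, stackInputs(case$denoised, case$init))
  ties <- sum(abs(s[, , 1] - s[, , 2]) < 1e-12)
  expect_equal(ties, 0)
  expect_identical(pixels(ps), 1 - pixels(pm))
})

test_that("a one-sample fit makes steady optimisation progress", {
  case <- phantomTrainingCase(seed = 7)
  ds <- list(list(stack = case$stack, mask = case$phantom@mask))
  model <- buildUNet(unetConfig(), seed = 7)
  fit <- trainUNet(model, ds, trainConfig(batchSize = 1, learningRate = 1e-3,
                                          epochs = 50, seed = 7))
  h <- fit$lossHistory
  # strong net reduction, and after the transient Adam bumps settle the
  # tail of the curve stays far below the starting loss
  expect_lt(h[50], 0.05 * h[1])
  expect_true(all(diff(cummin(h)) <= 0))
  expect_lt(max(h[26:50]), 0.1 * h[1])
})
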