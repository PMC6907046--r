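#' Train a U-Net with Adam
#'
#' Minimises the weighted softmax cross-entropy over the dataset with the
#' Adam optimiser. Gradients are averaged over each mini-batch; sample
#' order is reshuffled every epoch under the training seed, so two runs
#' with the same seed produce identical loss histories.
#'
#' @param model a [buildUNet()] handle.
#' @param dataset nonempty list; each element a list with \code{stack}
#'   (array H x W x inChannels) and \code{mask} (\code{BinaryMask} or
#'   0/1 matrix).
#' @param cfg a [trainConfig()].
#' @return list(model, lossHistory) where lossHistory has one mean-loss
#'   entry per epoch (the training curve).
#' @export
trainUNet <- function(model, dataset, cfg = trainConfig()) {
  stopifnot(inherits(model, "UNetModel"), inherits(cfg, "TrainConfig"))
  if (length(dataset) < 1L) stopDomain("dataset must be nonempty")
  for (s in dataset) {
    if (is.null(s$stack) || is.null(s$mask))
      stopDomain("each dataset element needs $stack and $mask")
  }
  n <- length(dataset)
  P <- model$params
  mState <- lapply(P, function(p) list(W = p$W * 0, b = p$b * 0))
  vState <- mState
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0L
  history <- numeric(cfg$epochs)

  weightsFor <- function(mask) {
    m <- if (is(mask, "BinaryMask")) pixels(mask) else mask
    if (cfg$weightMapMode == "uniform") matrix(1, nrow(m), ncol(m))
    else borderWeights(m)
  }

  withLocalSeed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      epochLoss <- 0
      for (start in seq(1L, n, by = cfg$batchSize)) {
        idx <- ord[start:min(start + cfg$batchSize - 1L, n)]
        acc <- NULL
        batchLoss <- 0
        for (i in idx) {
          s <- dataset[[i]]
          lg <- unetLossAndGrads(model, s$stack, s$mask, weightsFor(s$mask))
          batchLoss <- batchLoss + lg$loss
          acc <- if (is.null(acc)) lg$grads else
            mapply(function(a, g) list(W = a$W + g$W, b = a$b + g$b),
                   acc, lg$grads, SIMPLIFY = FALSE)
        }
        nb <- length(idx)
        epochLoss <- epochLoss + batchLoss
        t <- t + 1L
        lrT <- cfg$learningRate * sqrt(1 - beta2^t) / (1 - beta1^t)
        for (nm in names(model$params)) {
          gW <- acc[[nm]]$W / nb; gb <- acc[[nm]]$b / nb
          mState[[nm]]$W <- beta1 * mState[[nm]]$W + (1 - beta1) * gW
          mState[[nm]]$b <- beta1 * mState[[nm]]$b + (1 - beta1) * gb
          vState[[nm]]$W <- beta2 * vState[[nm]]$W + (1 - beta2) * gW^2
          vState[[nm]]$b <- beta2 * vState[[nm]]$b + (1 - beta2) * gb^2
          model$params[[nm]]$W <- model$params[[nm]]$W -
            lrT * mState[[nm]]$W / (sqrt(vState[[nm]]$W) + eps)
          model$params[[nm]]$b <- model$params[[nm]]$b -
            lrT * mState[[nm]]$b / (sqrt(vState[[nm]]$b) + eps)
        }
      }
      history[epoch] <- epochLoss / n
    }
  })
  list(model = model, lossHistory = history)
}

# Exponential distance-to-boundary weight map: pixels near the lung
# boundary get weight up to 1 + amplitude, decaying with distance.
borderWeights <- function(m, amplitude = 9, scale = 3) {
  inside <- m > 0.5
  edge <- (inside & !erodeOnce(inside)) | (!inside & !erodeOnce(!inside))
  if (!any(edge)) return(matrix(1, nrow(m), ncol(m)))
  d <- distanceToSet(edge)
  1 + amplitude * exp(-d / scale)
}

erodeOnce <- function(b) {
  out <- b
  out[-1, ] <- out[-1, ] & b[-nrow(b), ]
  out[-nrow(b), ] <- out[-nrow(b), ] & b[-1, ]
  out[, -1] <- out[, -1] & b[, -ncol(b)]
  out[, -ncol(b)] <- out[, -ncol(b)] & b[, -1]
  out
}

# Chamfer-style two-pass L1 distance transform to the TRUE set.
distanceToSet <- function(edge) {
  H <- nrow(edge); W <- ncol(edge)
  d <- matrix(ifelse(edge, 0, H + W), H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (i > 1) d[i, j] <- min(d[i, j], d[i - 1, j] + 1)
    if (j > 1) d[i, j] <- min(d[i, j], d[i, j - 1] + 1)
  }
  for (i in H:1) for (j in W:1) {
    if (i < H) d[i, j] <- min(d[i, j], d[i + 1, j] + 1)
    if (j < W) d[i, j] <- min(d[i, j], d[i, j + 1] + 1)
  }
  d
}

#' Build the 2-channel U-Net input stack
#'
#' Channel 1: the image scaled to [0, 1] by its declared range; channel 2:
#' the current binary mask.
#'
#' @param image a \code{GrayImage}.
#' @param mask a \code{BinaryMask} of the same shape.
#' @return array H x W x 2.
#' @export
stackInputs <- function(image, mask) {
  stopifnot(is(image, "GrayImage"), is(mask, "BinaryMask"))
  r <- intensityRange(image)
  p <- (pixels(image) - r[1]) / (r[2] - r[1])
  m <- pixels(mask)
  if (!identical(dim(p), dim(m))) stopDomain("image/mask shape mismatch")
  array(c(p, m), c(nrow(p), ncol(p), 2L))
}

#' Predict a refined mask
#'
#' Stacks the image and the current mask, runs the network, and takes the
#' per-pixel argmax over softmax channels (class 1 = lung).
#'
#' @param model a trained "UNetModel" (same padding).
#' @param image a \code{GrayImage} whose sides are divisible by 2^depth.
#' @param initialMask the current \code{BinaryMask}.
#' @return the refined \code{BinaryMask}.
#' @export
predictMask <- function(model, image, initialMask) {
  if (model$cfg$padding != "same")
    stopDomain("predictMask requires a same-padding model (valid mode crops the output)")
  scores <- unetForward(model, stackInputs(image, initialMask))
  binaryMask(scores[, , 2] > scores[, , 1])
}

#' Save / load a U-Net checkpoint
#'
#' A checkpoint is a single serialized file holding the weights, the
#' architecture config, the build seed and the package version.
#'
#' @param model a "UNetModel".
#' @param path checkpoint file.
#' @return \code{loadUNet}: the restored "UNetModel".
#' @export
saveUNet <- function(model, path) {
  stopifnot(inherits(model, "UNetModel"))
  saveRDS(list(format = "ildseg-unet-1", params = model$params,
               cfg = model$cfg, seed = model$seed,
               version = as.character(packageVersion("ildseg"))), path)
  invisible(path)
}

#' @rdname saveUNet
#' @export
loadUNet <- function(path) {
  if (!file.exists(path)) stopDomain("checkpoint not found: %s", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "ildseg-unet-1"))
    stopDomain("'%s' is not a U-Net checkpoint", path)
  structure(list(cfg = ck$cfg, seed = ck$seed, params = ck$params),
            class = "UNetModel")
}
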