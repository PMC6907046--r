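#' Compact U-Net configuration
#'
#' A depth-3 encoder/decoder with 3x3 convolutions (each followed by ReLU),
#' 2x2 max pooling, 2x2 up-convolutions with crop-and-concatenate skip
#' connections, a two-conv bottleneck between the paths, and a 1x1
#' classification head. Channels double per level (base 16: ladder
#' 16/32/64 down, 128 at the bottom, mirrored up).
#'
#' @param depth number of down/up blocks (default 3).
#' @param inChannels input channels (default 2: denoised image + initial
#'   mask).
#' @param baseChannels channels of the first block (default 16).
#' @param numClasses output channels R (default 2: background/lung).
#' @param padding "same" (output size = input size, requires the input side
#'   divisible by 2^depth) or "valid" (unpadded convolutions with
#'   centre-cropped skips, the tile-arithmetic variant).
#' @return a list of class "UNetConfig".
#' @export
unetConfig <- function(depth = 3L, inChannels = 2L, baseChannels = 16L,
                       numClasses = 2L, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  depth <- as.integer(depth); baseChannels <- as.integer(baseChannels)
  inChannels <- as.integer(inChannels); numClasses <- as.integer(numClasses)
  if (depth < 1L) stopDomain("depth must be >= 1")
  if (baseChannels < 1L) stopDomain("baseChannels must be >= 1")
  if (numClasses < 2L) stopDomain("numClasses must be >= 2")
  structure(list(depth = depth, inChannels = inChannels,
                 baseChannels = baseChannels, numClasses = numClasses,
                 padding = padding, kernel = 3L, pool = 2L),
            class = "UNetConfig")
}

#' Training configuration
#'
#' Defaults are the desk-scale recipe for 64x64 phantoms; the full-scale
#' recipe for 512x512 ROIs (batch 20, learning rate 1e-4, 500 epochs)
#' ships in \code{inst/extdata/config-full-scale.yaml}.
#'
#' @param batchSize samples per gradient step (>= 1).
#' @param learningRate Adam step size (> 0).
#' @param epochs passes over the training set (>= 1).
#' @param seed integer seed for weight init and shuffling.
#' @param weightMapMode "uniform" (omega = 1 everywhere) or "border"
#'   (exponential emphasis near mask boundaries).
#' @return a list of class "TrainConfig".
#' @export
trainConfig <- function(batchSize = 5L, learningRate = 1e-3, epochs = 30L,
                        seed = 7L, weightMapMode = c("uniform", "border")) {
  weightMapMode <- match.arg(weightMapMode)
  if (batchSize < 1L) stopDomain("batchSize must be >= 1")
  if (learningRate <= 0) stopDomain("learningRate must be > 0")
  if (epochs < 1L) stopDomain("epochs must be >= 1")
  structure(list(batchSize = as.integer(batchSize),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 seed = as.integer(seed), weightMapMode = weightMapMode),
            class = "TrainConfig")
}

heInit <- function(nin, nout, fanIn) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / fanIn)), nin, nout)
}

#' Build a seeded U-Net
#'
#' Allocates all convolution weights (He-normal initialisation, zero
#' biases) reproducibly under \code{seed}; the caller's RNG stream is
#' untouched.
#'
#' @param cfg a [unetConfig()].
#' @param seed integer seed.
#' @return a list of class "UNetModel" with elements cfg, seed, params.
#' @export
buildUNet <- function(cfg = unetConfig(), seed = 7L) {
  stopifnot(inherits(cfg, "UNetConfig"))
  k <- cfg$kernel
  params <- list()
  addConv <- function(name, cin, cout, kk) {
    params[[name]] <<- list(W = heInit(kk * kk * cin, cout, kk * kk * cin),
                            b = numeric(cout), k = kk, cin = cin, cout = cout)
  }
  withLocalSeed(seed, {
    cin <- cfg$inChannels
    ch <- cfg$baseChannels
    for (l in seq_len(cfg$depth)) {
      addConv(sprintf("enc%d_conv1", l), cin, ch, k)
      addConv(sprintf("enc%d_conv2", l), ch, ch, k)
      cin <- ch; ch <- ch * 2L
    }
    addConv("bottleneck_conv1", cin, ch, k)
    addConv("bottleneck_conv2", ch, ch, k)
    for (l in rev(seq_len(cfg$depth))) {
      # 2x2 up-convolution halving channels, then two 3x3 convs on the
      # concatenated (up + skip) stack
      up <- ch %/% 2L
      params[[sprintf("dec%d_up", l)]] <- list(
        W = heInit(4L * ch, up, 4L * ch), b = numeric(up), k = 2L,
        cin = ch, cout = up)
      addConv(sprintf("dec%d_conv1", l), 2L * up, up, k)
      addConv(sprintf("dec%d_conv2", l), up, up, k)
      ch <- up
    }
    addConv("head", ch, cfg$numClasses, 1L)
  })
  structure(list(cfg = cfg, seed = as.integer(seed), params = params),
            class = "UNetModel")
}

#' @export
print.UNetModel <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("UNetModel: depth %d, base %d, in %d, classes %d, %s padding, %s parameters (seed %d)\n",
              x$cfg$depth, x$cfg$baseChannels, x$cfg$inChannels,
              x$cfg$numClasses, x$cfg$padding, format(np, big.mark = ","),
              x$seed))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param model a "UNetModel".
#' @return integer count of weights plus biases.
#' @export
countParams <- function(model) {
  stopifnot(inherits(model, "UNetModel"))
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), 0))
}

convFw <- function(p, x, pad) .conv2d_fw(x, p$W, p$b, p$k, pad)

cropCenter <- function(x, h, w) {
  dh <- dim(x)[1] - h; dw <- dim(x)[2] - w
  if (dh < 0 || dw < 0) stopDomain("skip smaller than decoder map; invalid tiling")
  r0 <- dh %/% 2L; c0 <- dw %/% 2L
  x[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), , drop = FALSE]
}

# Forward pass; when train = TRUE a tape of intermediate activations is
# kept for the backward pass.
unetForwardCore <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  pad <- if (cfg$padding == "same") 1L else 0L
  P <- model$params
  tape <- list()
  act <- function(name, z) {            # conv + ReLU with cached mask
    y <- pmax(z, 0)
    if (train) tape[[name]] <<- list(mask = z > 0)
    y
  }
  convStep <- function(name, x) {
    if (train) tape[[paste0(name, ".x")]] <<- x
    convFw(P[[name]], x, pad)
  }
  skips <- list()
  for (l in seq_len(cfg$depth)) {
    x <- act(sprintf("enc%d_conv1", l), convStep(sprintf("enc%d_conv1", l), x))
    x <- act(sprintf("enc%d_conv2", l), convStep(sprintf("enc%d_conv2", l), x))
    skips[[l]] <- x
    if (dim(x)[1] %% 2L || dim(x)[2] %% 2L)
      stopDomain("feature map %d x %d not poolable at level %d; input size must be divisible by %d (same padding)",
                 dim(x)[1], dim(x)[2], l, 2L^cfg$depth)
    mp <- .maxpool_fw(x)
    if (train) tape[[sprintf("pool%d", l)]] <- mp$idx
    x <- mp$y
  }
  x <- act("bottleneck_conv1", convStep("bottleneck_conv1", x))
  x <- act("bottleneck_conv2", convStep("bottleneck_conv2", x))
  for (l in rev(seq_len(cfg$depth))) {
    nm <- sprintf("dec%d_up", l)
    if (train) tape[[paste0(nm, ".x")]] <- x
    x <- .upconv_fw(x, P[[nm]]$W, P[[nm]]$b)
    s <- cropCenter(skips[[l]], dim(x)[1], dim(x)[2])
    if (train) tape[[sprintf("skipdim%d", l)]] <- dim(skips[[l]])
    cat2 <- array(0, c(dim(x)[1], dim(x)[2], dim(x)[3] + dim(s)[3]))
    cat2[, , seq_len(dim(x)[3])] <- x
    cat2[, , dim(x)[3] + seq_len(dim(s)[3])] <- s
    x <- cat2
    x <- act(sprintf("dec%d_conv1", l), convStep(sprintf("dec%d_conv1", l), x))
    x <- act(sprintf("dec%d_conv2", l), convStep(sprintf("dec%d_conv2", l), x))
  }
  if (train) tape[["head.x"]] <- x
  scores <- convFw(P[["head"]], x, 0L)
  list(scores = scores, tape = tape)
}

#' U-Net forward pass
#'
#' @param model a trained or freshly built "UNetModel".
#' @param stack numeric array H x W x inChannels.
#' @return the score map: array H' x W' x numClasses of real activations
#'   (apply [softmaxScores()] for per-pixel class probabilities). With
#'   "same" padding H' = H, W' = W and the input side must be divisible by
#'   2^depth.
#' @export
unetForward <- function(model, stack) {
  stopifnot(inherits(model, "UNetModel"))
  if (length(dim(stack)) != 3L || dim(stack)[3] != model$cfg$inChannels)
    stopDomain("stack must be H x W x %d", model$cfg$inChannels)
  if (model$cfg$padding == "same") {
    div <- 2L^model$cfg$depth
    if (dim(stack)[1] %% div || dim(stack)[2] %% div)
      stopDomain("input %d x %d: height and width must be divisible by %d for same padding at depth %d",
                 dim(stack)[1], dim(stack)[2], div, model$cfg$depth)
  }
  unetForwardCore(model, stack, train = FALSE)$scores
}

#' Per-pixel softmax of a score map
#'
#' @param scores array H x W x R.
#' @return array of the same shape; channel values sum to 1 per pixel.
#' @export
softmaxScores <- function(scores) {
  mx <- apply(scores, c(1, 2), max)
  e <- exp(sweep(scores, c(1, 2), mx, "-"))
  sweep(e, c(1, 2), apply(e, c(1, 2), sum), "/")
}

#' Weighted softmax cross-entropy loss
#'
#' E = (1/N) sum_x omega(x) * (-log softmax(alpha(x))_{l(x)}) over the N
#' pixels, with l(x) the true class at x. Uniform unit weights and uniform
#' logits over 2 classes give ln 2 per pixel; an all-zero weight map gives
#' 0.
#'
#' @param scores array H x W x R of activations.
#' @param labels a \code{BinaryMask} or integer matrix of class indices
#'   (0-based) of shape H x W.
#' @param weights per-pixel weight matrix omega (default all 1).
#' @return scalar loss >= 0.
#' @export
weightedCELoss <- function(scores, labels, weights = NULL) {
  lab <- if (is(labels, "BinaryMask")) pixels(labels) else labels
  d <- dim(scores)
  if (!identical(dim(lab), d[1:2]))
    stopDomain("labels %s do not match scores %d x %d",
               paste(dim(lab), collapse = " x "), d[1], d[2])
  if (is.null(weights)) weights <- matrix(1, d[1], d[2])
  if (!identical(dim(weights), d[1:2])) stopDomain("weight map shape mismatch")
  ls <- logSoftmax(scores)
  n <- d[1] * d[2]
  picked <- pickChannel(ls, lab)
  -sum(weights * picked) / n
}

logSoftmax <- function(scores) {
  mx <- apply(scores, c(1, 2), max)
  sh <- sweep(scores, c(1, 2), mx, "-")
  lse <- log(apply(exp(sh), c(1, 2), sum))
  sweep(sh, c(1, 2), lse, "-")
}

pickChannel <- function(a, lab) {
  d <- dim(a)
  idx <- cbind(as.vector(row(lab)), as.vector(col(lab)), as.vector(lab) + 1L)
  matrix(a[idx], d[1], d[2])
}

# Gradient of weightedCELoss wrt scores: (softmax - onehot) * omega / N.
ceLossGrad <- function(scores, lab, weights) {
  d <- dim(scores)
  sm <- softmaxScores(scores)
  for (r in seq_len(d[3]))
    sm[, , r] <- sm[, , r] - (lab == r - 1L)
  sweep(sm, c(1, 2), weights, "*") / (d[1] * d[2])
}

#' @keywords internal
unetLossAndGrads <- function(model, stack, labels, weights = NULL) {
  fw <- unetForwardCore(model, stack, train = TRUE)
  d <- dim(fw$scores)
  lab <- if (is(labels, "BinaryMask")) pixels(labels) else labels
  if (is.null(weights)) weights <- matrix(1, d[1], d[2])
  loss <- weightedCELoss(fw$scores, lab, weights)
  gscores <- ceLossGrad(fw$scores, lab, weights)
  grads <- backwardThroughUNet(model, fw$tape, gscores)
  list(loss = loss, grads = grads, scores = fw$scores)
}

# Reverse-mode pass over the whole network. The forward decoder runs
# levels depth..1, so the backward decoder walks 1..depth, then the
# bottleneck, then encoder levels depth..1, adding each skip gradient
# where its encoder map branched.
backwardThroughUNet <- function(model, tape, gscores) {
  cfg <- model$cfg
  pad <- if (cfg$padding == "same") 1L else 0L
  P <- model$params
  grads <- list()
  convBack <- function(name, g, padHere = pad) {
    x <- tape[[paste0(name, ".x")]]
    bw <- .conv2d_bw(x, P[[name]]$W, P[[name]]$k, padHere, g)
    grads[[name]] <<- list(W = bw$gW, b = as.numeric(bw$gb))
    bw$gx
  }
  reluBack <- function(name, g) g * tape[[name]]$mask

  g <- convBack("head", gscores, 0L)
  gSkips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    g <- reluBack(sprintf("dec%d_conv2", l), g)
    g <- convBack(sprintf("dec%d_conv2", l), g)
    g <- reluBack(sprintf("dec%d_conv1", l), g)
    g <- convBack(sprintf("dec%d_conv1", l), g)
    nm <- sprintf("dec%d_up", l)
    nUp <- P[[nm]]$cout
    gUp <- g[, , seq_len(nUp), drop = FALSE]
    gSkipCrop <- g[, , (nUp + 1):dim(g)[3], drop = FALSE]
    sdim <- tape[[sprintf("skipdim%d", l)]]
    gSkip <- array(0, sdim)
    dh <- sdim[1] - dim(gSkipCrop)[1]; dw <- sdim[2] - dim(gSkipCrop)[2]
    r0 <- dh %/% 2L; c0 <- dw %/% 2L
    gSkip[(r0 + 1):(r0 + dim(gSkipCrop)[1]),
          (c0 + 1):(c0 + dim(gSkipCrop)[2]), ] <- gSkipCrop
    gSkips[[l]] <- gSkip
    bw <- .upconv_bw(tape[[paste0(nm, ".x")]], P[[nm]]$W, gUp)
    grads[[nm]] <- list(W = bw$gW, b = as.numeric(bw$gb))
    g <- bw$gx
  }
  g <- reluBack("bottleneck_conv2", g)
  g <- convBack("bottleneck_conv2", g)
  g <- reluBack("bottleneck_conv1", g)
  g <- convBack("bottleneck_conv1", g)
  for (l in rev(seq_len(cfg$depth))) {
    g <- .maxpool_bw(g, tape[[sprintf("pool%d", l)]])
    g <- g + gSkips[[l]]
    g <- reluBack(sprintf("enc%d_conv2", l), g)
    g <- convBack(sprintf("enc%d_conv2", l), g)
    g <- reluBack(sprintf("enc%d_conv1", l), g)
    g <- convBack(sprintf("enc%d_conv1", l), g)
  }
  grads
}
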