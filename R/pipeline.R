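#' End-to-end pipeline configuration
#'
#' @param denoiseEnabled run the Wiener preprocessing stage (FALSE gives
#'   the texture+network ablation without denoising).
#' @param wiener a [wienerConfig()].
#' @param glcm a [glcmConfig()] in map mode for the initial texture stage;
#'   the default window 9 / stride 2 suits desk-scale (64 px) images, while
#'   512 px ROIs warrant window 17 / stride 8.
#' @param unetCheckpoint path to a [saveUNet()] checkpoint, or NULL when a
#'   model object is passed to [segmentLung()] directly.
#' @param maxIterations maximum U-Net refinement passes (>= 1, default 5).
#' @param convergenceDSC stop once Dice between consecutive masks reaches
#'   this value (in (0, 1], default 0.999). Dice rather than exact pixel
#'   equality operationalises "the contour is the same" robustly.
#' @param seed integer seed (texture-stage clustering).
#' @return a list of class "PipelineConfig".
#' @export
pipelineConfig <- function(denoiseEnabled = TRUE, wiener = wienerConfig(),
                           glcm = glcmMapConfig(window = 9L, stride = 2L),
                           unetCheckpoint = NULL,
                           maxIterations = 5L, convergenceDSC = 0.999,
                           seed = 7L) {
  maxIterations <- as.integer(maxIterations)
  if (maxIterations < 1L) stopDomain("maxIterations must be >= 1")
  if (!(convergenceDSC > 0 && convergenceDSC <= 1))
    stopDomain("convergenceDSC must be in (0, 1]")
  structure(list(denoiseEnabled = isTRUE(denoiseEnabled), wiener = wiener,
                 glcm = glcm, unetCheckpoint = unetCheckpoint,
                 maxIterations = maxIterations,
                 convergenceDSC = convergenceDSC, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Dice similarity coefficient
#'
#' DSC = 2 |M intersect A| / (|M| + |A|), in [0, 1]; symmetric; defined as
#' 1 when both masks are empty (two empty segmentations agree perfectly).
#'
#' @param M,A \code{BinaryMask}s (or 0/1 matrices) of equal shape.
#' @return scalar in [0, 1].
#' @export
#' @examples
#' m <- matrix(0, 2, 4); m[1, ] <- 1   # |M| = 4
#' a <- matrix(0, 2, 4); a[, 1:2] <- 1 # |A| = 4, overlap 2
#' dice(m, a)  # 0.5
dice <- function(M, A) {
  m <- if (is(M, "BinaryMask")) pixels(M) else M
  a <- if (is(A, "BinaryMask")) pixels(A) else A
  if (!identical(dim(m), dim(a)))
    stopDomain("mask shape mismatch: %s vs %s",
               paste(dim(m), collapse = "x"), paste(dim(a), collapse = "x"))
  sm <- sum(m); sa <- sum(a)
  if (sm + sa == 0) return(1)
  2 * sum(m * a) / (sm + sa)
}

#' Sensitivity (true-positive rate)
#'
#' SEN = TP / (TP + FN) with TP the lung pixels the prediction recovers
#' and FN those it misses; undefined (a domain error) for an empty ground
#' truth.
#'
#' @param truth ground-truth \code{BinaryMask} (nonempty).
#' @param pred predicted \code{BinaryMask} of equal shape.
#' @return scalar in [0, 1].
#' @export
sensitivity <- function(truth, pred) {
  m <- if (is(truth, "BinaryMask")) pixels(truth) else truth
  a <- if (is(pred, "BinaryMask")) pixels(pred) else pred
  if (!identical(dim(m), dim(a))) stopDomain("mask shape mismatch")
  tp <- sum(m * a); fn <- sum(m * (1 - a))
  if (tp + fn == 0) stopDomain("sensitivity undefined for empty ground truth")
  tp / (tp + fn)
}

#' Segment one image with the two-stage iterative pipeline
#'
#' Runs (1) optional Wiener denoising, (2) the texture stage once for the
#' initial mask, then (3) repeats the U-Net refinement on (denoised image,
#' current mask) until the Dice between consecutive masks reaches
#' \code{cfg$convergenceDSC} or \code{cfg$maxIterations} passes have run.
#' All masks (initial first) are recorded.
#'
#' @param image a \code{GrayImage}.
#' @param cfg a [pipelineConfig()].
#' @param model a "UNetModel"; if NULL, loaded from
#'   \code{cfg$unetCheckpoint}.
#' @return a \code{SegmentationResult}.
#' @export
segmentLung <- function(image, cfg = pipelineConfig(), model = NULL) {
  stopifnot(is(image, "GrayImage"), inherits(cfg, "PipelineConfig"))
  if (is.null(model)) {
    if (is.null(cfg$unetCheckpoint))
      stopDomain("no model given and no unetCheckpoint configured")
    model <- loadUNet(cfg$unetCheckpoint)
  }
  work <- if (cfg$denoiseEnabled) wienerDenoise(image, cfg$wiener) else image
  fmap <- textureFeatureMap(work, cfg$glcm)
  current <- initialTextureSegmentation(fmap, work, seed = cfg$seed)
  masks <- list(current)
  convergedFlag <- FALSE
  it <- 0L
  while (it < cfg$maxIterations) {
    it <- it + 1L
    refined <- predictMask(model, work, current)
    masks[[length(masks) + 1L]] <- refined
    if (dice(refined, current) >= cfg$convergenceDSC) {
      convergedFlag <- TRUE
      current <- refined
      break
    }
    current <- refined
  }
  new("SegmentationResult", finalMask = current, iterationMasks = masks,
      converged = convergedFlag, iterationsRun = it)
}

#' Run the desk-scale phantom study
#'
#' Generates a seeded phantom dataset, splits it, builds the texture-stage
#' initial masks, trains the compact U-Net on the training split, and
#' evaluates the full iterative pipeline on the held-out split. This is
#' the package's self-contained analogue of a real-data training run: 60
#' phantoms at 64 px, 40 train / 20 test, 30 epochs by default.
#'
#' @param n total number of phantoms.
#' @param trainFraction fraction used for training.
#' @param epochs training epochs.
#' @param seed master seed driving phantom generation, the split,
#'   clustering and training.
#' @param params template [phantomParams()].
#' @param cfg a [pipelineConfig()]; its checkpoint field is ignored.
#' @param train a [trainConfig()]; its epochs/seed are overridden by the
#'   arguments above.
#' @param dir where to write the dataset (default: a temp dir).
#' @return list with \code{record} (the test-set \code{EvalRecord}),
#'   \code{initialDSC} (mean texture-stage Dice on the test set),
#'   \code{model}, \code{lossHistory} and \code{split}.
#' @export
runDeskRecipe <- function(n = 60L, trainFraction = 2 / 3, epochs = 30L,
                          seed = 7L, params = phantomParams(),
                          cfg = pipelineConfig(seed = seed),
                          train = trainConfig(),
                          dir = tempfile("deskrecipe")) {
  ds <- generateDataset(n, params, seed = seed, dir = dir)
  split <- splitDataset(seq_len(n), trainFraction, seed = seed)
  dataset <- lapply(split$trainItems, function(i) {
    s <- ds$samples[[i]]
    work <- if (cfg$denoiseEnabled) wienerDenoise(s@image, cfg$wiener) else s@image
    fmap <- textureFeatureMap(work, cfg$glcm)
    init <- initialTextureSegmentation(fmap, work, seed = cfg$seed)
    list(stack = stackInputs(work, init), mask = s@mask)
  })
  train$epochs <- as.integer(epochs)
  train$seed <- as.integer(seed)
  model <- buildUNet(unetConfig(), seed = seed)
  fit <- trainUNet(model, dataset, train)

  rows <- list(); initDSC <- numeric(0)
  for (i in split$testItems) {
    s <- ds$samples[[i]]
    res <- segmentLung(s@image, cfg, fit$model)
    initDSC <- c(initDSC, dice(iterationMasks(res)[[1]], s@mask))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("phantom_%03d", i),
      dsc = dice(s@mask, finalMask(res)),
      sen = sensitivity(s@mask, finalMask(res)),
      iterations = iterationsRun(res),
      converged = converged(res))
  }
  tab <- do.call(rbind, rows)
  rec <- new("EvalRecord", table = tab, dsc = mean(tab$dsc),
             sen = mean(tab$sen), skipped = 0L)
  list(record = rec, initialDSC = mean(initDSC), model = fit$model,
       lossHistory = fit$lossHistory, split = split)
}

#' Evaluate the pipeline over a manifest
#'
#' Segments every image listed in the manifest, scores it against its
#' ground-truth mask, and aggregates per-sample means (not pooled pixels).
#' Entries whose image or mask file is missing are skipped and counted.
#'
#' @param manifest path to a manifest file, or a data.frame with columns
#'   \code{image}, \code{mask} (see [readManifest()]).
#' @param cfg a [pipelineConfig()].
#' @param model optional "UNetModel" (else loaded from the config).
#' @param reportPath optional CSV output (columns sample_id, dsc, sen,
#'   iterations, converged).
#' @return an \code{EvalRecord}.
#' @export
evaluatePipeline <- function(manifest, cfg = pipelineConfig(), model = NULL,
                             reportPath = NULL) {
  mf <- if (is.data.frame(manifest)) manifest else readManifest(manifest)
  if (is.null(model)) {
    if (is.null(cfg$unetCheckpoint))
      stopDomain("no model given and no unetCheckpoint configured")
    model <- loadUNet(cfg$unetCheckpoint)
  }
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(mf))) {
    if (!file.exists(mf$image[i]) || !file.exists(mf$mask[i])) {
      warning(sprintf("sample %d skipped: missing file", i), call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    img <- readGrayImage(mf$image[i])
    truth <- readMask(mf$mask[i])
    res <- segmentLung(img, cfg, model)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = basename(mf$image[i]),
      dsc = dice(truth, finalMask(res)),
      sen = sensitivity(truth, finalMask(res)),
      iterations = iterationsRun(res),
      converged = converged(res))
  }
  if (!length(rows)) stopDomain("no evaluable samples in manifest")
  tab <- do.call(rbind, rows)
  if (!is.null(reportPath)) write.csv(tab, reportPath, row.names = FALSE)
  new("EvalRecord", table = tab, dsc = mean(tab$dsc), sen = mean(tab$sen),
      skipped = skipped)
}
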