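#' @import methods
#' @importFrom stats kmeans rnorm runif sd var aggregate
#' @importFrom utils write.csv read.csv read.table packageVersion
#' @useDynLib ildseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Grayscale 2-D image
#'
#' Carrier for a single-channel slice: a rows x cols matrix of real
#' intensities together with the declared intensity scale (default 0-255,
#' i.e. 8-bit CT ROI dynamics). Pixel (1,1) is the top-left corner; the
#' first index is the row.
#'
#' @slot pixels numeric matrix of intensities (rows x cols).
#' @slot intensityRange numeric(2), declared \code{c(min, max)} scale.
#'
#' @aliases GrayImage-class
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", intensityRange = "numeric"),
  prototype(pixels = matrix(0, 1, 1), intensityRange = c(0, 255))
)

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1 x 1")
  if (!all(is.finite(p))) return("all pixel values must be finite")
  r <- object@intensityRange
  if (length(r) != 2L || !all(is.finite(r)) || r[2] <= r[1])
    return("intensityRange must be c(min, max) with min < max")
  TRUE
})

#' Binary segmentation mask
#'
#' Per-pixel lung/background labelling: a matrix containing exactly the
#' values 0 (background) and 1 (lung), with the same shape as its paired
#' image. The unit on which Dice and sensitivity are computed.
#'
#' @slot pixels numeric matrix with entries in \{0, 1\}.
#' @slot metadata list of optional provenance flags (e.g. \code{fallback}).
#'
#' @aliases BinaryMask-class
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", metadata = "list"),
  prototype(pixels = matrix(0, 1, 1), metadata = list())
)

setValidity("BinaryMask", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (!all(p %in% c(0, 1))) return("mask values must be exactly 0 or 1")
  TRUE
})

#' Gray-level co-occurrence matrix (raw counts)
#'
#' Q x Q matrix of pair counts q(i, j): the number of ordered pixel pairs at
#' displacement d along direction theta whose source gray level is i and
#' target gray level is j (levels 0..Q-1; matrix row/col k holds level k-1).
#'
#' @slot counts non-negative integer-valued Q x Q matrix.
#' @slot d integer pixel displacement (>= 1).
#' @slot theta direction in degrees, one of 0, 45, 90, 135.
#' @slot symmetric logical, TRUE after symmetrisation (counts + t(counts)).
#'
#' @aliases GLCM-class
#' @exportClass GLCM
setClass("GLCM",
  representation(counts = "matrix", d = "integer", theta = "numeric",
                 symmetric = "logical"),
  prototype(counts = matrix(0, 2, 2), d = 1L, theta = 0, symmetric = FALSE)
)

setValidity("GLCM", function(object) {
  q <- object@counts
  if (nrow(q) != ncol(q)) return("counts must be square (Q x Q)")
  if (any(q < 0)) return("counts must be non-negative")
  if (object@d < 1L) return("d must be >= 1")
  if (!object@theta %in% c(0, 45, 90, 135))
    return("theta must be one of 0, 45, 90, 135 degrees")
  if (isTRUE(object@symmetric) && !isTRUE(all.equal(q, t(q))))
    return("symmetric GLCM must equal its transpose")
  TRUE
})

#' Normalised gray-level co-occurrence matrix
#'
#' The GLCM turned into a joint probability distribution
#' p(i, j) = q(i, j) / sum(q); entries are non-negative and sum to one.
#' This is the input to the 14 Haralick texture features.
#'
#' @slot probs Q x Q matrix of probabilities.
#'
#' @aliases NGLCM-class
#' @exportClass NGLCM
setClass("NGLCM", representation(probs = "matrix"),
         prototype(probs = diag(2) / 2))

setValidity("NGLCM", function(object) {
  p <- object@probs
  if (nrow(p) != ncol(p)) return("probs must be square")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1 (within 1e-9)")
  TRUE
})

#' Sliding-window Haralick texture feature map
#'
#' One row per (window, displacement d, direction theta) triple holding the
#' 14 Haralick scalars plus the window geometry (1-based top-left row/col
#' and side), so every feature can be mapped back to its pixel box.
#'
#' @slot features data.frame with columns win, row, col, d, theta and the 14
#'   feature columns (see \code{haralickFeatureNames}).
#' @slot window integer window side in pixels.
#' @slot stride integer stride in pixels.
#' @slot imageDim integer(2) of the source image (rows, cols).
#' @slot Q integer number of gray levels used.
#'
#' @aliases TextureFeatureMap-class
#' @exportClass TextureFeatureMap
setClass("TextureFeatureMap",
  representation(features = "data.frame", window = "integer",
                 stride = "integer", imageDim = "integer", Q = "integer"))

#' Result of the iterative segmentation loop
#'
#' Records the full trajectory of the two-stage pipeline on one image: the
#' initial texture mask, every U-Net refinement, the convergence verdict
#' (Dice between consecutive masks reaching the configured threshold) and
#' the number of refinement passes run.
#'
#' @slot finalMask \code{BinaryMask}, the last mask produced.
#' @slot iterationMasks list of \code{BinaryMask}; element 1 is the initial
#'   texture mask, subsequent elements are U-Net refinements.
#' @slot converged logical.
#' @slot iterationsRun integer number of U-Net refinement passes.
#'
#' @aliases SegmentationResult-class
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(finalMask = "BinaryMask", iterationMasks = "list",
                 converged = "logical", iterationsRun = "integer"))

setValidity("SegmentationResult", function(object) {
  if (length(object@iterationMasks) < 1L) return("need at least one mask")
  last <- object@iterationMasks[[length(object@iterationMasks)]]
  if (!identical(pixels(last), pixels(object@finalMask)))
    return("finalMask must equal the last iteration mask")
  TRUE
})

#' Segmentation evaluation record
#'
#' Per-sample Dice and sensitivity for a test set plus their arithmetic
#' means (per-sample averaging, not pooled pixels).
#'
#' @slot table data.frame with columns sample_id, dsc, sen, iterations,
#'   converged.
#' @slot dsc numeric mean Dice over samples.
#' @slot sen numeric mean sensitivity over samples.
#' @slot skipped integer number of manifest entries skipped (missing files).
#'
#' @aliases EvalRecord-class
#' @exportClass EvalRecord
setClass("EvalRecord",
  representation(table = "data.frame", dsc = "numeric", sen = "numeric",
                 skipped = "integer"))

#' Synthetic phantom sample
#'
#' A generated lung phantom: image, exact ground-truth lung mask, and the
#' parameter record that produced them.
#'
#' @slot image \code{GrayImage}.
#' @slot mask \code{BinaryMask}.
#' @slot params the \code{phantomParams} list used.
#'
#' @aliases PhantomSample-class
#' @exportClass PhantomSample
setClass("PhantomSample",
  representation(image = "GrayImage", mask = "BinaryMask", params = "list"))
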