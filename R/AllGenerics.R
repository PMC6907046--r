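#' Accessors for image-like objects
#'
#' \code{pixels} returns the underlying numeric matrix; \code{imgHeight} and
#' \code{imgWidth} its dimensions; \code{intensityRange} the declared
#' intensity scale of a \code{GrayImage}.
#'
#' @param x a \code{GrayImage} or \code{BinaryMask}.
#' @return \code{pixels}: a matrix; the others: scalars / numeric(2).
#' @name accessors
#' @examples
#' img <- grayImage(matrix(0:3, 2, 2))
#' pixels(img); imgHeight(img); imgWidth(img); intensityRange(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))
#' @rdname accessors
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))
#' @rdname accessors
#' @export
setGeneric("intensityRange", function(x) standardGeneric("intensityRange"))

#' @rdname accessors
setMethod("pixels", "GrayImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "BinaryMask", function(x) x@pixels)
#' @rdname accessors
setMethod("imgHeight", "GrayImage", function(x) nrow(x@pixels))
#' @rdname accessors
setMethod("imgHeight", "BinaryMask", function(x) nrow(x@pixels))
#' @rdname accessors
setMethod("imgWidth", "GrayImage", function(x) ncol(x@pixels))
#' @rdname accessors
setMethod("imgWidth", "BinaryMask", function(x) ncol(x@pixels))
#' @rdname accessors
setMethod("intensityRange", "GrayImage", function(x) x@intensityRange)

#' GLCM accessors
#'
#' @param x a \code{GLCM} or \code{NGLCM}.
#' @return \code{glcmCounts}: integer-valued matrix of pair counts;
#'   \code{glcmProbs}: probability matrix summing to one.
#' @name glcm-accessors
NULL

#' @rdname glcm-accessors
#' @export
setGeneric("glcmCounts", function(x) standardGeneric("glcmCounts"))
#' @rdname glcm-accessors
#' @export
setGeneric("glcmProbs", function(x) standardGeneric("glcmProbs"))
#' @rdname glcm-accessors
setMethod("glcmCounts", "GLCM", function(x) x@counts)
#' @rdname glcm-accessors
setMethod("glcmProbs", "NGLCM", function(x) x@probs)

#' Segmentation result accessors
#'
#' @param x a \code{SegmentationResult} or \code{EvalRecord}.
#' @return \code{finalMask}: a \code{BinaryMask}; \code{iterationMasks}: a
#'   list of masks (initial texture mask first); \code{converged} /
#'   \code{iterationsRun}: scalars; \code{evalTable}: the per-sample
#'   data.frame.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("finalMask", function(x) standardGeneric("finalMask"))
#' @rdname result-accessors
#' @export
setGeneric("iterationMasks", function(x) standardGeneric("iterationMasks"))
#' @rdname result-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname result-accessors
#' @export
setGeneric("iterationsRun", function(x) standardGeneric("iterationsRun"))
#' @rdname result-accessors
#' @export
setGeneric("evalTable", function(x) standardGeneric("evalTable"))

#' @rdname result-accessors
setMethod("finalMask", "SegmentationResult", function(x) x@finalMask)
#' @rdname result-accessors
setMethod("iterationMasks", "SegmentationResult", function(x) x@iterationMasks)
#' @rdname result-accessors
setMethod("converged", "SegmentationResult", function(x) x@converged)
#' @rdname result-accessors
setMethod("iterationsRun", "SegmentationResult", function(x) x@iterationsRun)
#' @rdname result-accessors
setMethod("evalTable", "EvalRecord", function(x) x@table)

setMethod("show", "GrayImage", function(object) {
  r <- object@intensityRange
  cat(sprintf("GrayImage %d x %d, range [%g, %g], values in [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels), r[1], r[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, foreground %d px (%.1f%%)%s\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              100 * mean(object@pixels),
              if (isTRUE(object@metadata$fallback)) " [fallback]" else ""))
})

setMethod("show", "GLCM", function(object) {
  cat(sprintf("GLCM Q=%d, d=%d, theta=%g deg, total pairs %g%s\n",
              nrow(object@counts), object@d, object@theta,
              sum(object@counts),
              if (object@symmetric) ", symmetric" else ""))
})

setMethod("show", "NGLCM", function(object) {
  cat(sprintf("NGLCM Q=%d, sum=%.6f\n", nrow(object@probs), sum(object@probs)))
})

setMethod("show", "TextureFeatureMap", function(object) {
  cat(sprintf(
    "TextureFeatureMap: %d windows (side %d, stride %d), %d (d,theta) x 14 = %d scalars per window set\n",
    length(unique(object@features$win)), object@window, object@stride,
    nrow(object@features) / max(1L, length(unique(object@features$win))),
    14L * nrow(object@features) / max(1L, length(unique(object@features$win)))))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d refinement pass(es), %sconverged\n",
              object@iterationsRun, if (object@converged) "" else "NOT "))
})

setMethod("show", "EvalRecord", function(object) {
  cat(sprintf("EvalRecord: %d samples, mean DSC %.4f, mean SEN %.4f (%d skipped)\n",
              nrow(object@table), object@dsc, object@sen, object@skipped))
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample %dx%d, texture '%s', lung fraction %.3f, seed %d\n",
              imgHeight(object@image), imgWidth(object@image),
              object@params$textureKind, mean(pixels(object@mask)),
              object@params$seed))
})
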