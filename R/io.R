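#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale PNG (multi-channel PNGs are converted to
#' luminance with Rec.601 weights) or a single-frame uncompressed grayscale
#' DICOM, and returns a \code{GrayImage} on the declared 0-255 scale.
#' 16-bit PNG and DICOM pixel data are linearly rescaled to 0-255, since the
#' downstream texture stage assumes 8-bit dynamics (Q = 256 gray levels).
#'
#' @param path file to read.
#' @param kind "auto" (by extension), "png" or "dicom".
#' @param intensityRange declared output scale, default \code{c(0, 255)}.
#' @return a \code{GrayImage}.
#' @seealso [writeMask()], [writeGrayImage()]
#' @export
readGrayImage <- function(path, kind = c("auto", "png", "dicom"),
                          intensityRange = c(0, 255)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopDomain("file not found: %s", path)
  if (kind == "auto")
    kind <- if (grepl("\\.dcm$|\\.dicom$", path, ignore.case = TRUE)) "dicom" else "png"
  if (kind == "dicom") return(readDicomImage(path, intensityRange))
  a <- tryCatch(png::readPNG(path), error = function(e)
    stopDomain("cannot decode PNG '%s': %s", path, conditionMessage(e)))
  if (length(dim(a)) == 3L) {
    # luminance for RGB(A); ignore alpha
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  # readPNG normalises to [0,1] for both 8- and 16-bit depth
  px <- a * (intensityRange[2] - intensityRange[1]) + intensityRange[1]
  grayImage(px, intensityRange)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (1) is written as 255, background (0) as 0, so masks
#' round-trip exactly through [readGrayImage()] (read back as 0/255).
#'
#' @param mask a \code{BinaryMask}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  ok <- tryCatch({ png::writePNG(pixels(mask), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopDomain("cannot write mask to '%s'", path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Pixels above half intensity are foreground; exact inverse of
#' [writeMask()] for 0/255 files.
#'
#' @param path PNG file.
#' @return a \code{BinaryMask}.
#' @export
readMask <- function(path) {
  img <- readGrayImage(path, kind = "png")
  binaryMask(pixels(img) > (sum(intensityRange(img)) / 2))
}

#' Write a GrayImage as an 8-bit PNG
#'
#' Intensities are mapped from the declared range to 0-255 and rounded.
#'
#' @param image a \code{GrayImage}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGrayImage <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  r <- intensityRange(image)
  v <- round((pixels(image) - r[1]) / (r[2] - r[1]) * 255) / 255
  v <- pmin(pmax(v, 0), 1)
  ok <- tryCatch({ png::writePNG(v, path); TRUE }, error = function(e) FALSE)
  if (!ok) stopDomain("cannot write image to '%s'", path)
  invisible(path)
}

#' Crop a square region of interest
#'
#' Output pixel (r, c) equals input pixel (topLeft[1] + r - 1,
#' topLeft[2] + c - 1); the box must lie fully inside the image (no
#' implicit padding).
#'
#' @param image a \code{GrayImage}.
#' @param topLeft integer(2), 1-based (row, col) of the box corner.
#' @param size box side in pixels.
#' @return the \code{size} x \code{size} sub-image.
#' @export
cropROI <- function(image, topLeft, size) {
  stopifnot(is(image, "GrayImage"))
  r0 <- as.integer(topLeft[1]); c0 <- as.integer(topLeft[2]); s <- as.integer(size)
  if (s < 1L) stopDomain("crop size must be >= 1")
  if (r0 < 1L || c0 < 1L || r0 + s - 1L > imgHeight(image) ||
      c0 + s - 1L > imgWidth(image))
    stopDomain("crop box [%d:%d, %d:%d] exceeds image %d x %d",
               r0, r0 + s - 1L, c0, c0 + s - 1L, imgHeight(image), imgWidth(image))
  grayImage(pixels(image)[r0:(r0 + s - 1L), c0:(c0 + s - 1L), drop = FALSE],
            intensityRange(image))
}

#' Deterministic train/test split
#'
#' Shuffles the item ids under \code{seed} and assigns the first
#' round(n * trainFraction) to the training set (round-half-up, so 1946
#' items at fraction 0.8 give 1557 train / 389 test). Both lists preserve
#' the shuffle order. The caller's RNG stream is left untouched.
#'
#' @param itemIds character or integer vector of >= 2 unique ids.
#' @param trainFraction real in (0, 1).
#' @param seed integer seed.
#' @return a list of class "DatasetSplit": trainItems, testItems,
#'   trainFraction, seed.
#' @export
#' @examples
#' s <- splitDataset(sprintf("roi%04d", 1:1946), 0.8, seed = 1)
#' length(s$trainItems); length(s$testItems)
splitDataset <- function(itemIds, trainFraction, seed) {
  n <- length(itemIds)
  if (n < 2L) stopDomain("need at least 2 items to split, got %d", n)
  if (anyDuplicated(itemIds)) stopDomain("item ids must be unique")
  if (!(trainFraction > 0 && trainFraction < 1))
    stopDomain("trainFraction must be in (0, 1)")
  nTrain <- floor(n * trainFraction + 0.5)  # round half up
  perm <- withLocalSeed(seed, sample.int(n))
  testIdx <- if (nTrain < n) perm[(nTrain + 1L):n] else integer(0)
  structure(list(trainItems = itemIds[perm[seq_len(nTrain)]],
                 testItems  = itemIds[testIdx],
                 trainFraction = trainFraction, seed = as.integer(seed)),
            class = "DatasetSplit")
}

#' @export
print.DatasetSplit <- function(x, ...) {
  cat(sprintf("DatasetSplit: %d train / %d test (fraction %.3f, seed %d)\n",
              length(x$trainItems), length(x$testItems), x$trainFraction, x$seed))
  invisible(x)
}

#' Read / write a dataset manifest
#'
#' A manifest is a plain-text file with one \code{image_path<TAB>mask_path}
#' pair per line; relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file.
#' @return \code{readManifest}: a data.frame with columns \code{image},
#'   \code{mask}.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopDomain("manifest not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stopDomain("manifest lines must be 'image<TAB>mask'")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  data.frame(image = resolve(vapply(parts, `[`, "", 1L)),
             mask  = resolve(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' @rdname readManifest
#' @param images,masks path vectors of equal length (written as given).
#' @export
writeManifest <- function(images, masks, path) {
  stopifnot(length(images) == length(masks))
  writeLines(paste(images, masks, sep = "\t"), path)
  invisible(path)
}
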