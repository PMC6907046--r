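#' Construct a GrayImage
#'
#' @param pixels numeric matrix (rows x cols) of finite intensities.
#' @param intensityRange declared \code{c(min, max)} scale; default 0-255.
#' @return a \code{GrayImage}.
#' @export
#' @examples
#' grayImage(matrix(runif(16, 0, 255), 4, 4))
grayImage <- function(pixels, intensityRange = c(0, 255)) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, intensityRange = as.numeric(intensityRange))
}

#' Construct a BinaryMask
#'
#' @param pixels matrix (or logical matrix) of 0/1 values.
#' @param metadata optional list of provenance flags.
#' @return a \code{BinaryMask}.
#' @export
binaryMask <- function(pixels, metadata = list()) {
  if (is.logical(pixels)) pixels <- pixels * 1
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("BinaryMask", pixels = pixels, metadata = metadata)
}

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so package functions never perturb user RNG.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mix a base seed with an index into a derived 31-bit seed.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

# Sliding-window box mean with symmetric (edge-replicating mirror) padding.
# Two cumsum passes; exact, no FFT. `w` must be odd.
boxMean <- function(m, w) {
  r <- (w - 1L) %/% 2L
  p <- padSymmetric(m, r)
  cs <- apply(rbind(0, p), 2L, cumsum)
  v <- cs[(w + 1L):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
  cs2 <- t(apply(cbind(0, v), 1L, cumsum))
  out <- cs2[, (w + 1L):ncol(cs2), drop = FALSE] - cs2[, 1:(ncol(cs2) - w), drop = FALSE]
  out / (w * w)
}

padSymmetric <- function(m, r) {
  if (r == 0L) return(m)
  ri <- c(pmin(r:1, nrow(m)), seq_len(nrow(m)), nrow(m) - pmin(1:r, nrow(m)) + 1L)
  ci <- c(pmin(r:1, ncol(m)), seq_len(ncol(m)), ncol(m) - pmin(1:r, ncol(m)) + 1L)
  m[ri, ci, drop = FALSE]
}

clipTo <- function(m, range) pmin(pmax(m, range[1]), range[2])

stopDomain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
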