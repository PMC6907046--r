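#' GLCM configuration
#'
#' Controls gray-level quantisation and which co-occurrence matrices are
#' built. Two working modes share the configuration:
#' \itemize{
#'   \item whole-ROI mode (\code{window = NULL}): one matrix per
#'     (distance, direction) over the full image. The default 30 distances
#'     x 4 directions yields 120 NGLCMs and 120 x 14 = 1680 Haralick
#'     scalars per ROI.
#'   \item sliding-window map mode (\code{window} set): the chain is run in
#'     each window on a stride grid, producing a [TextureFeatureMap()]. At
#'     window scale 256 levels give unusably sparse matrices, so map mode
#'     conventionally uses a coarser Q (e.g. 32) and short distances.
#' }
#'
#' @param Q number of gray levels (>= 2), default 256.
#' @param distances integer displacements d >= 1, default 1:30.
#' @param directions subset of c(0, 45, 90, 135) degrees.
#' @param symmetric symmetrise each GLCM before normalising (default TRUE).
#' @param window odd window side for map mode, or NULL for whole-ROI mode.
#' @param stride stride in pixels for map mode, default 8.
#' @return a list of class "GLCMConfig".
#' @export
glcmConfig <- function(Q = 256L, distances = 1:30,
                       directions = c(0, 45, 90, 135),
                       symmetric = TRUE, window = NULL, stride = 8L) {
  Q <- as.integer(Q)
  if (Q < 2L) stopDomain("Q must be >= 2")
  distances <- as.integer(distances)
  if (length(distances) < 1L || any(distances < 1L))
    stopDomain("all distances must be >= 1")
  if (length(directions) < 1L || !all(directions %in% c(0, 45, 90, 135)))
    stopDomain("directions must be a nonempty subset of {0, 45, 90, 135}")
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window < 3L || window %% 2L == 0L)
      stopDomain("window must be an odd integer >= 3 (or NULL for whole-ROI mode)")
  }
  stride <- as.integer(stride)
  if (stride < 1L) stopDomain("stride must be >= 1")
  structure(list(Q = Q, distances = distances, directions = directions,
                 symmetric = isTRUE(symmetric), window = window,
                 stride = stride),
            class = "GLCMConfig")
}

# Default sliding-window map configuration for the initial texture stage.
#' @rdname glcmConfig
#' @export
glcmMapConfig <- function(Q = 32L, distances = c(1L, 2L),
                          directions = c(0, 45, 90, 135),
                          symmetric = TRUE, window = 17L, stride = 8L) {
  glcmConfig(Q = Q, distances = distances, directions = directions,
             symmetric = symmetric, window = window, stride = stride)
}

#' Quantise an image to Q gray levels
#'
#' level = floor((value - min) / rangeSize * Q), clamped to Q - 1, with
#' rangeSize = max - min + 1 of the declared (integer-valued) intensity
#' scale. For an 8-bit image and Q = 256 the levels equal the pixel
#' values; the mapping is monotone in the input value.
#'
#' @param image a \code{GrayImage}.
#' @param Q number of levels (>= 2).
#' @return a \code{GrayImage} whose pixels are integer levels 0..Q-1
#'   (intensityRange c(0, Q-1)).
#' @export
quantizeImage <- function(image, Q) {
  stopifnot(is(image, "GrayImage"))
  Q <- as.integer(Q)
  if (Q < 2L) stopDomain("Q must be >= 2")
  r <- intensityRange(image)
  size <- r[2] - r[1] + 1
  lev <- floor((pixels(image) - r[1]) / size * Q)
  lev <- pmin(pmax(lev, 0), Q - 1)
  grayImage(lev, c(0, Q - 1))
}

#' Direction offset for a GLCM angle
#'
#' Returns the (row, col) unit offset (x, y) of the displacement
#' convention: the co-occurring pixel of (k, l) is (k + x d, l + y d),
#' with row 0 at the top so 45 degrees points up-right.
#'
#' @param theta one of 0, 45, 90, 135 (degrees).
#' @return integer(2): c(x, y) = row and column offset multipliers, i.e.
#'   0 -> (0, 1), 45 -> (-1, 1), 90 -> (-1, 0), 135 -> (-1, -1).
#' @export
directionOffset <- function(theta) {
  switch(as.character(theta),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stopDomain("theta must be one of 0, 45, 90, 135 degrees (got %s)",
                    as.character(theta)))
}

#' Compute a gray-level co-occurrence matrix
#'
#' counts(i, j) is the number of ordered pixel pairs (k, l), (m, n) with
#' (m, n) = (k, l) + d * directionOffset(theta), source level i and target
#' level j; pairs with either pixel outside the image are skipped. A
#' displacement too large for the image yields an all-zero matrix (not an
#' error).
#'
#' @param image a quantised \code{GrayImage} (integer levels 0..Q-1).
#' @param d displacement in pixels (>= 1).
#' @param theta direction in degrees (0, 45, 90, 135).
#' @param Q number of gray levels.
#' @return a \code{GLCM}.
#' @export
#' @examples
#' img <- grayImage(matrix(2, 3, 3), c(0, 4))
#' glcmCounts(computeGLCM(img, 1, 0, 5))[3, 3]  # 6 horizontal pairs
computeGLCM <- function(image, d, theta, Q) {
  stopifnot(is(image, "GrayImage"))
  d <- as.integer(d); Q <- as.integer(Q)
  if (d < 1L) stopDomain("d must be >= 1")
  off <- directionOffset(theta)
  p <- pixels(image)
  if (any(p < 0 | p > Q - 1) || any(p != floor(p)))
    stopDomain("image must be quantised to integer levels 0..Q-1")
  dr <- off[1] * d; dc <- off[2] * d
  H <- nrow(p); W <- ncol(p)
  rs <- seq_len(H); rs <- rs[rs + dr >= 1L & rs + dr <= H]
  cs <- seq_len(W); cs <- cs[cs + dc >= 1L & cs + dc <= W]
  counts <- matrix(0, Q, Q)
  if (length(rs) && length(cs)) {
    i <- p[rs, cs, drop = FALSE]
    j <- p[rs + dr, cs + dc, drop = FALSE]
    counts <- matrix(tabulate(i + 1 + j * Q, nbins = Q * Q), Q, Q)
  }
  new("GLCM", counts = counts, d = d, theta = as.numeric(theta),
      symmetric = FALSE)
}

#' Symmetrise a GLCM
#'
#' counts' = counts + t(counts), so every pair is counted in both
#' orientations and the matrix equals its transpose; the total count
#' doubles exactly.
#'
#' @param glcm a \code{GLCM}.
#' @return the symmetric \code{GLCM}.
#' @export
symmetrizeGLCM <- function(glcm) {
  stopifnot(is(glcm, "GLCM"))
  new("GLCM", counts = glcm@counts + t(glcm@counts), d = glcm@d,
      theta = glcm@theta, symmetric = TRUE)
}

#' Normalise a GLCM to a probability matrix
#'
#' p(i, j) = q(i, j) / sum(q). An all-zero matrix has no defined
#' probabilities and is a domain error.
#'
#' @param glcm a \code{GLCM} with positive total count.
#' @return an \code{NGLCM}.
#' @export
normalizeGLCM <- function(glcm) {
  stopifnot(is(glcm, "GLCM"))
  tot <- sum(glcm@counts)
  if (tot <= 0) stopDomain("cannot normalise an all-zero GLCM")
  new("NGLCM", probs = glcm@counts / tot)
}

#' Names of the 14 Haralick texture features
#'
#' @return character(14), in canonical f1..f14 order.
#' @export
haralickFeatureNames <- function() c(
  "ASM", "Contrast", "Correlation", "Variance", "IDM",
  "SumAverage", "SumVariance", "SumEntropy", "Entropy",
  "DifferenceVariance", "DifferenceEntropy", "IMC1", "IMC2", "MCC")

#' The 14 Haralick texture features of an NGLCM
#'
#' Computes, with natural logarithms: f1 angular second moment, f2
#' contrast, f3 correlation, f4 sum of squares (variance about the row
#' marginal mean), f5 inverse difference moment, f6 sum average, f7 sum
#' variance (about the sum average), f8 sum entropy, f9 entropy, f10
#' difference variance, f11 difference entropy, f12/f13 information
#' measures of correlation, f14 maximal correlation coefficient (square
#' root of the second-largest eigenvalue of the conditional-transition
#' matrix).
#'
#' Degenerate-case conventions, chosen so constant regions yield finite
#' features: 0 log 0 = 0; correlation = 0 when either marginal standard
#' deviation is 0; IMC1 = 0 when max(HX, HY) = 0; the IMC2 radicand is
#' clamped at 0; MCC = 0 when fewer than two gray levels have positive
#' marginal mass.
#'
#' @param nglcm an \code{NGLCM}.
#' @return named numeric(14), see [haralickFeatureNames()].
#' @export
#' @examples
#' # single-cell distribution (constant image): ASM 1, Contrast 0, Entropy 0
#' g <- computeGLCM(grayImage(matrix(1, 4, 4), c(0, 3)), 1, 0, 4)
#' haralickFeatures(normalizeGLCM(symmetrizeGLCM(g)))[c("ASM", "Contrast", "Entropy")]
haralickFeatures <- function(nglcm) {
  stopifnot(is(nglcm, "NGLCM"))
  P <- nglcm@probs
  Q <- nrow(P)
  lev <- 0:(Q - 1)
  I <- matrix(lev, Q, Q)        # row index (source level)
  J <- t(I)                     # col index (target level)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

  f1 <- sum(P^2)
  f2 <- sum((I - J)^2 * P)
  f3 <- if (sdx > 0 && sdy > 0) (sum(I * J * P) - mux * muy) / (sdx * sdy) else 0
  f4 <- sum((I - mux)^2 * P)
  f5 <- sum(P / (1 + (I - J)^2))

  # p_{x+y}(k), k = 0..2Q-2 ; p_{x-y}(k), k = 0..Q-1 (diagonal-band sums)
  pv <- as.vector(P)
  pxy <- numeric(2 * Q - 1)
  bs <- rowsum(pv, group = as.vector(I + J), reorder = TRUE)
  pxy[as.integer(rownames(bs)) + 1L] <- bs[, 1]
  pxmy <- numeric(Q)
  bd <- rowsum(pv, group = abs(as.vector(I - J)), reorder = TRUE)
  pxmy[as.integer(rownames(bd)) + 1L] <- bd[, 1]
  ks <- 0:(2 * Q - 2); kd <- 0:(Q - 1)
  f6 <- sum(ks * pxy)
  f7 <- sum((ks - f6)^2 * pxy)
  f8 <- -sum(xlogx(pxy))
  f9 <- -sum(xlogx(P))
  mud <- sum(kd * pxmy)
  f10 <- sum((kd - mud)^2 * pxmy)
  f11 <- -sum(xlogx(pxmy))

  HXY <- f9
  PXY <- outer(px, py)
  HXY1 <- -sum(ifelse(PXY > 0, P * log(PXY), 0))
  HXY2 <- -sum(xlogx(PXY))
  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  f12 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  f13 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  f14 <- haralickMCC(P, px, py)

  out <- c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
  names(out) <- haralickFeatureNames()
  out
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# M(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), restricted to levels with
# positive marginal mass. 0 when the restriction has fewer than 2 levels.
haralickMCC <- function(P, px, py) {
  s <- which(px > 0 & py > 0)
  if (length(s) < 2L) return(0)
  Ps <- P[s, s, drop = FALSE]
  A <- Ps / px[s]
  B <- sweep(Ps, 2L, py[s], "/")
  M <- A %*% t(B)
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(ev[2], 0))
}

#' Sliding-window Haralick texture feature map
#'
#' Quantises the image once to cfg$Q levels, then for every window on the
#' stride grid and every (distance, direction) in cfg runs the
#' quantise -> GLCM -> symmetrise -> normalise -> Haralick chain. Each
#' window-set therefore carries |distances| x |directions| x 14 scalars;
#' whole-ROI mode (window = NULL) treats the full image as a single
#' window. Combinations whose displacement leaves no in-bounds pair are
#' skipped.
#'
#' @param image a \code{GrayImage}.
#' @param cfg a [glcmConfig()] / [glcmMapConfig()].
#' @return a \code{TextureFeatureMap}.
#' @export
textureFeatureMap <- function(image, cfg = glcmMapConfig()) {
  stopifnot(is(image, "GrayImage"), inherits(cfg, "GLCMConfig"))
  H <- imgHeight(image); W <- imgWidth(image)
  full <- is.null(cfg$window)
  win <- if (full) min(H, W) else cfg$window
  if (win > min(H, W))
    stopDomain("window %d exceeds image %d x %d", win, H, W)
  q <- quantizeImage(image, cfg$Q)
  qp <- pixels(q)
  storage.mode(qp) <- "integer"
  rows0 <- if (full) 1L else seq(1L, H - win + 1L, by = cfg$stride)
  cols0 <- if (full) 1L else seq(1L, W - win + 1L, by = cfg$stride)
  offs <- vapply(cfg$directions, directionOffset, integer(2))
  m <- .texture_map_cpp(qp, as.integer(rows0 - 1L), as.integer(cols0 - 1L),
                        if (full) -1L else win, cfg$distances, offs,
                        as.numeric(cfg$directions), cfg$Q, cfg$symmetric)
  if (nrow(m) == 1L && all(m[1, ] == 0))
    stopDomain("no in-bounds pixel pairs for any (d, theta)")
  feat <- as.data.frame(m)
  names(feat) <- c("win", "row", "col", "d", "theta", haralickFeatureNames())
  new("TextureFeatureMap", features = feat,
      window = if (full) min(H, W) else win,
      stride = cfg$stride, imageDim = c(H, W), Q = cfg$Q)
}

#' Initial texture-based lung segmentation
#'
#' The unsupervised first stage, in three steps.
#'
#' \emph{Window classification.} Per-window Haralick vectors are averaged
#' over all (distance, direction) pairs and augmented with the intensity
#' at the window centre (3x3 mean); all columns are standardised, with
#' the intensity column weighted so the intensity view carries the same
#' total weight as the 14-column texture view. Windows are clustered with
#' seeded k-means (10 restarts) into \code{clusters} groups, and a
#' cluster is marked lung-candidate when the median centre intensity of
#' its windows lies below the image's Otsu threshold (lung fields and
#' outside-body air are the dark classes; chest wall and wall-centred
#' boundary windows are bright).
#'
#' \emph{Painting.} Each window's label is assigned to its centre pixel
#' (the window is measurement support, not a paint box) and the label
#' field is filled to full resolution by nearest-centre lookup, so the
#' effective label resolution is the stride, not the window size.
#'
#' \emph{Anatomical cleanup.} A body mask is built from the bright side
#' of the Otsu threshold (closing with a disk of radius 3, largest
#' component, hole filling); the lung mask is the candidate label field
#' inside the body, closed (disk radius 3), keeping the at most 2 largest
#' components. Restricting to the filled body region removes
#' outside-body air, which is dark like lung but never enclosed by the
#' chest wall. Deterministic under \code{seed}.
#'
#' If the window features are degenerate (a single texture over the whole
#' image) or clustering yields no usable dark/bright split, the stage
#' falls back to the plain intensity route (Otsu dark side inside the
#' body, same cleanup) and flags the mask with
#' \code{metadata$fallback = TRUE}.
#'
#' @param fmap a [textureFeatureMap()] of \code{image} in map mode.
#' @param image the \code{GrayImage} the map was computed from.
#' @param seed integer seed for k-means.
#' @param clusters number of texture clusters (>= 2; default 4 - air,
#'   lung texture, chest wall and boundary windows tend to separate).
#' @return a \code{BinaryMask} (metadata flags: fallback).
#' @export
initialTextureSegmentation <- function(fmap, image, seed = 1L, clusters = 4L) {
  stopifnot(is(fmap, "TextureFeatureMap"), is(image, "GrayImage"))
  if (!identical(fmap@imageDim, c(imgHeight(image), imgWidth(image))))
    stopDomain("feature map geometry does not match the image")
  if (clusters < 2L) stopDomain("clusters must be >= 2")
  feat <- fmap@features
  fcols <- haralickFeatureNames()
  fm <- rowsum(as.matrix(feat[fcols]), group = feat$win, reorder = TRUE)
  fm <- fm / as.vector(table(feat$win)[rownames(fm)])
  geo <- unique(feat[c("win", "row", "col")])
  geo <- geo[match(as.integer(rownames(fm)), geo$win), ]

  p <- pixels(image)
  w <- fmap@window
  h <- (w - 1L) %/% 2L                  # centre offset
  ctrMean <- mapply(function(r0, c0) {
    r <- max(r0 + h - 1L, 1L):min(r0 + h + 1L, nrow(p))
    cc <- max(c0 + h - 1L, 1L):min(c0 + h + 1L, ncol(p))
    mean(p[r, cc])
  }, geo$row, geo$col)

  keep <- apply(fm, 2L, function(v) isTRUE(sd(v) > 1e-12))
  thr <- otsuThreshold(p, intensityRange(image))
  fallback <- sd(ctrMean) <= 1e-12 || nrow(fm) <= clusters
  dark <- NULL; km <- NULL
  if (!fallback) {
    X <- cbind(scale(fm[, keep, drop = FALSE]),
               sqrt(length(fcols)) * scale(ctrMean))
    km <- try(withLocalSeed(seed,
                kmeans(X, centers = clusters, nstart = 10L)),
              silent = TRUE)
    if (inherits(km, "try-error") || length(unique(km$cluster)) < 2L) {
      fallback <- TRUE
    } else {
      dark <- vapply(seq_len(max(km$cluster)), function(cl)
        stats::median(ctrMean[km$cluster == cl]) < thr, NA)
      if (!any(dark) || all(dark)) fallback <- TRUE
    }
  }

  lungLabel <- if (fallback) p < thr else {
    paintCenterLabels(km$cluster %in% which(dark), geo$row + h, geo$col + h,
                      nrow(p), ncol(p))
  }
  body <- bodyMask(p >= thr)
  mask <- lungLabel & body
  if (any(mask)) {
    mask <- closeMask(mask, radius = 3L)
    mask <- keepLargestComponents(mask, k = 2L)
  }
  binaryMask(mask, metadata = list(fallback = fallback))
}

# Nearest-centre fill of a per-window label vector to pixel resolution.
paintCenterLabels <- function(labels, ctrRow, ctrCol, H, W) {
  ur <- sort(unique(ctrRow)); uc <- sort(unique(ctrCol))
  lg <- matrix(FALSE, length(ur), length(uc))
  lg[cbind(match(ctrRow, ur), match(ctrCol, uc))] <- labels
  ri <- vapply(seq_len(H), function(i) which.min(abs(ur - i)), 1L)
  ci <- vapply(seq_len(W), function(j) which.min(abs(uc - j)), 1L)
  lg[ri, ci, drop = FALSE]
}

# Filled body region from a bright-tissue mask: close small gaps, keep the
# largest component (the thorax), fill its interior holes (the lungs).
bodyMask <- function(bright) {
  if (!any(bright)) return(!bright | TRUE)  # degenerate: allow everything
  b <- closeMask(bright, radius = 3L)
  b <- keepLargestComponents(b, k = 1L)
  filled <- EBImage::fillHull(EBImage::Image(b * 1))
  EBImage::imageData(filled) > 0.5
}

#' Built-in 5x5 five-level GLCM worked example
#'
#' A small synthetic image (levels 0-4) bundled with the package for
#' demonstrating co-occurrence counting by hand; constructed so the
#' ordered pair (0, 2) occurs exactly twice at d = 1, theta = 0.
#'
#' @return a quantised \code{GrayImage} with levels 0..4.
#' @export
#' @examples
#' g <- computeGLCM(glcmExampleImage(), d = 1, theta = 0, Q = 5)
#' glcmCounts(g)[1, 3]  # pair (0, 2): 2
glcmExampleImage <- function() {
  path <- system.file("extdata", "glcm-example-synthetic.txt",
                      package = "ildseg", mustWork = TRUE)
  m <- as.matrix(read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  grayImage(m, c(0, 4))
}

# Otsu threshold on the declared intensity scale (256-bin histogram).
otsuThreshold <- function(p, range) {
  v <- (p - range[1]) / (range[2] - range[1])
  thr <- EBImage::otsu(EBImage::Image(v), range = c(0, 1), levels = 256)
  thr * (range[2] - range[1]) + range[1]
}

# Morphological closing with a disk brush of the given radius.
closeMask <- function(mask, radius = 3L) {
  img <- EBImage::Image(mask * 1)
  out <- EBImage::closing(img, EBImage::makeBrush(2L * radius + 1L, "disc"))
  EBImage::imageData(out) > 0.5
}

# Keep at most the k largest connected components of a logical mask.
keepLargestComponents <- function(mask, k = 2L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) <= k) return(lab > 0)
  keep <- order(sizes, decreasing = TRUE)[seq_len(k)]
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
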