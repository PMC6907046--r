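#' Parameters for a synthetic lung phantom
#'
#' Describes a thorax-like test image: a bright elliptical thorax on a
#' dark air background enclosing two darker, mirrored lung ellipses
#' carrying an ILD-like procedural texture (reticular line lattice,
#' nodular seeded spots, or a ground-glass low-pass noise field), with
#' additive Gaussian noise on top. The ground-truth mask is exactly the
#' two lung ellipses, whose joint area is kept within 10-45% of the
#' frame. All geometry is jittered deterministically under \code{seed}.
#'
#' @param size image side in pixels (>= 32; 64 for desk-scale work, 512
#'   for full-scale runs).
#' @param thoraxIntensity chest-wall intensity (0-255 scale).
#' @param lungIntensity lung-field base intensity; must be darker than the
#'   thorax.
#' @param airIntensity background outside the thorax.
#' @param textureKind one of "reticular", "nodular", "ground_glass",
#'   "none".
#' @param textureAmplitude texture strength in intensity units (>= 0).
#' @param lungEccentricity height/width ratio of the lung ellipses.
#' @param noise a [noiseModel()]; its seed is ignored (the phantom seed
#'   drives all randomness).
#' @param seed integer seed.
#' @return a list of class "PhantomParams".
#' @export
phantomParams <- function(size = 64L, thoraxIntensity = 190,
                          lungIntensity = 70, airIntensity = 20,
                          textureKind = c("reticular", "nodular",
                                          "ground_glass", "none"),
                          textureAmplitude = 25, lungEccentricity = 2.1,
                          noise = noiseModel(mu = 0, sigma = 10), seed = 1L) {
  textureKind <- match.arg(textureKind)
  size <- as.integer(size)
  if (size < 32L) stopDomain("size must be >= 32")
  if (lungIntensity >= thoraxIntensity)
    stopDomain("lungIntensity must be < thoraxIntensity")
  if (textureAmplitude < 0) stopDomain("textureAmplitude must be >= 0")
  if (lungEccentricity <= 0) stopDomain("lungEccentricity must be > 0")
  structure(list(size = size, thoraxIntensity = thoraxIntensity,
                 lungIntensity = lungIntensity, airIntensity = airIntensity,
                 textureKind = textureKind,
                 textureAmplitude = textureAmplitude,
                 lungEccentricity = lungEccentricity, noise = noise,
                 seed = as.integer(seed)),
            class = "PhantomParams")
}

insideEllipse <- function(R, C, cr, cc, rr, rc) {
  ((R - cr) / rr)^2 + ((C - cc) / rc)^2 <= 1
}

#' Generate one lung phantom
#'
#' Fully reproducible under \code{params$seed}; with
#' \code{textureAmplitude = 0} and \code{sigma = 0} the image is
#' piecewise constant with exactly three intensities (air, lung, thorax).
#'
#' @param params a [phantomParams()].
#' @return a \code{PhantomSample}.
#' @export
generatePhantom <- function(params = phantomParams()) {
  stopifnot(inherits(params, "PhantomParams"))
  s <- params$size
  withLocalSeed(params$seed, {
    R <- matrix(seq_len(s), s, s)
    C <- t(R)
    mid <- (s + 1) / 2
    # thorax: wide ellipse filling most of the frame, slightly jittered
    thorax <- insideEllipse(R, C, mid * runif(1, 0.98, 1.02),
                            mid * runif(1, 0.98, 1.02),
                            0.42 * s * runif(1, 0.95, 1.05),
                            0.46 * s * runif(1, 0.95, 1.05))
    # two mirrored lung ellipses, geometry jittered but kept inside the
    # thorax and within the 10-45% area budget
    rc <- 0.125 * s * runif(1, 0.88, 1.10)        # column semi-axis per lung
    rr <- rc * params$lungEccentricity * runif(1, 0.92, 1.08)
    rr <- min(rr, 0.31 * s)
    crow <- mid + s * runif(1, -0.02, 0.04)
    gap <- 0.17 * s * runif(1, 0.95, 1.08)
    lungL <- insideEllipse(R, C, crow, mid - gap, rr, rc)
    lungR <- insideEllipse(R, C, crow, mid + gap, rr, rc)
    mask <- lungL | lungR

    img <- matrix(params$airIntensity, s, s)
    img[thorax] <- params$thoraxIntensity
    img[mask] <- params$lungIntensity
    if (params$textureKind != "none" && params$textureAmplitude > 0) {
      tex <- switch(params$textureKind,
        reticular = textureReticular(R, C, params$textureAmplitude),
        nodular = textureNodular(mask, params$textureAmplitude),
        ground_glass = textureGroundGlass(s, params$textureAmplitude))
      img[mask] <- img[mask] + tex[mask]
    }
    img <- clipTo(img, c(0, 255))
    image <- grayImage(img)
    if (params$noise$sigma > 0 || params$noise$mu != 0) {
      nm <- noiseModel(params$noise$mu, params$noise$sigma,
                       deriveSeed(params$seed, 7919L))
      image <- addGaussianNoise(image, nm)
    }
    frac <- mean(mask)
    if (frac < 0.10 || frac > 0.45)
      stopDomain("lung area fraction %.3f outside [0.10, 0.45]; adjust params", frac)
    new("PhantomSample", image = image, mask = binaryMask(mask),
        params = unclass(params))
  })
}

# Oriented bright line lattice: two families of lines a few pixels apart,
# the sharp-edged reticular pattern.
textureReticular <- function(R, C, amplitude) {
  phi <- runif(1, 0, pi)
  spacing <- sample(5:7, 1)
  u <- R * cos(phi) + C * sin(phi)
  v <- -R * sin(phi) + C * cos(phi)
  lines1 <- (floor(u) %% spacing) == 0
  lines2 <- (floor(v) %% (spacing + 1)) == 0
  (lines1 | lines2) * amplitude
}

# Seeded bright disk spots (nodules) of radius 1-2 px.
textureNodular <- function(mask, amplitude) {
  s <- nrow(mask)
  tex <- matrix(0, s, s)
  idx <- which(mask)
  if (!length(idx)) return(tex)
  nSpots <- max(3L, round(length(idx) / 60))
  centers <- sample(idx, min(nSpots, length(idx)))
  R <- matrix(seq_len(s), s, s); C <- t(R)
  for (ct in centers) {
    cr <- ((ct - 1) %% s) + 1; cc <- ((ct - 1) %/% s) + 1
    rad <- sample(1:2, 1)
    tex[(R - cr)^2 + (C - cc)^2 <= rad^2] <- amplitude
  }
  tex
}

# Low-pass-filtered white noise, rescaled to sd = amplitude / 2: smooth
# hazy increased attenuation.
textureGroundGlass <- function(s, amplitude) {
  w <- matrix(rnorm(s * s), s, s)
  sm <- boxMean(boxMean(w, 5L), 5L)
  sm <- sm / max(sd(sm), 1e-12)
  sm * amplitude / 2
}

#' Generate a phantom dataset on disk
#'
#' Writes n image/mask PNG pairs plus a manifest consumable by
#' [readManifest()]. Per-sample seeds are derived from \code{seed}, so the
#' whole dataset is reproducible and samples are pairwise distinct.
#'
#' @param n number of phantoms (>= 1).
#' @param params template [phantomParams()] (its seed is replaced
#'   per-sample).
#' @param seed base seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{samples} (list of
#'   \code{PhantomSample}) and \code{manifest} (path).
#' @export
generateDataset <- function(n, params = phantomParams(), seed = 1L,
                            dir = tempfile("phantoms")) {
  n <- as.integer(n)
  if (n < 1L) stopDomain("n must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- vector("list", n)
  imgs <- character(n); msks <- character(n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- deriveSeed(seed, i)
    samples[[i]] <- generatePhantom(p)
    imgs[i] <- file.path(dir, sprintf("img_%03d.png", i))
    msks[i] <- file.path(dir, sprintf("mask_%03d.png", i))
    writeGrayImage(samples[[i]]@image, imgs[i])
    writeMask(samples[[i]]@mask, msks[i])
  }
  manifest <- file.path(dir, "manifest.txt")
  writeManifest(basename(imgs), basename(msks), manifest)
  invisible(list(samples = samples, manifest = manifest, dir = dir))
}
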