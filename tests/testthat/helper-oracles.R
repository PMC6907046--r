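# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (double loops, literal formula transcriptions) and
# share no code with the implementation paths they check.

# Exhaustive ordered-pair counter for co-occurrence matrices: scans every
# pixel pair and checks the offset condition directly.
bruteGLCM <- function(levels, d, theta, Q) {
  off <- switch(as.character(theta),
                "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
                "135" = c(-1, -1))
  counts <- matrix(0, Q, Q)
  H <- nrow(levels); W <- ncol(levels)
  for (k in seq_len(H)) for (l in seq_len(W)) {
    m <- k + off[1] * d; n <- l + off[2] * d
    if (m >= 1 && m <= H && n >= 1 && n <= W)
      counts[levels[k, l] + 1, levels[m, n] + 1] <-
        counts[levels[k, l] + 1, levels[m, n] + 1] + 1
  }
  storage.mode(counts) <- "integer"
  counts
}

# Literal transcription of the 14 Haralick feature formulas (natural log),
# written as plain loops, independent of the package implementation.
bruteHaralick <- function(P) {
  Q <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((0:(Q - 1)) * px); muy <- sum((0:(Q - 1)) * py)
  sdx <- sqrt(sum(((0:(Q - 1)) - mux)^2 * px))
  sdy <- sqrt(sum(((0:(Q - 1)) - muy)^2 * py))
  f1 <- f2 <- f4 <- f5 <- f9 <- cor <- 0
  pxy <- numeric(2 * Q - 1); pxmy <- numeric(Q)
  for (i in 0:(Q - 1)) for (j in 0:(Q - 1)) {
    p <- P[i + 1, j + 1]
    f1 <- f1 + p^2
    f2 <- f2 + (i - j)^2 * p
    cor <- cor + i * j * p
    f4 <- f4 + (i - mux)^2 * p
    f5 <- f5 + p / (1 + (i - j)^2)
    if (p > 0) f9 <- f9 - p * log(p)
    pxy[i + j + 1] <- pxy[i + j + 1] + p
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + p
  }
  f3 <- if (sdx > 0 && sdy > 0) (cor - mux * muy) / (sdx * sdy) else 0
  f6 <- sum((0:(2 * Q - 2)) * pxy)
  f7 <- sum(((0:(2 * Q - 2)) - f6)^2 * pxy)
  f8 <- -sum(ifelse(pxy > 0, pxy * log(pxy), 0))
  mud <- sum((0:(Q - 1)) * pxmy)
  f10 <- sum(((0:(Q - 1)) - mud)^2 * pxmy)
  f11 <- -sum(ifelse(pxmy > 0, pxmy * log(pxmy), 0))
  HX <- -sum(ifelse(px > 0, px * log(px), 0))
  HY <- -sum(ifelse(py > 0, py * log(py), 0))
  HXY1 <- HXY2 <- 0
  for (i in 0:(Q - 1)) for (j in 0:(Q - 1)) {
    m <- px[i + 1] * py[j + 1]
    if (m > 0) {
      if (P[i + 1, j + 1] > 0) HXY1 <- HXY1 - P[i + 1, j + 1] * log(m)
      HXY2 <- HXY2 - m * log(m)
    }
  }
  f12 <- if (max(HX, HY) > 0) (f9 - HXY1) / max(HX, HY) else 0
  f13 <- sqrt(max(1 - exp(-2 * (HXY2 - f9)), 0))
  s <- which(px > 0 & py > 0)
  f14 <- 0
  if (length(s) >= 2) {
    M <- matrix(0, length(s), length(s))
    for (a in seq_along(s)) for (b in seq_along(s)) {
      acc <- 0
      for (k in seq_along(s))
        acc <- acc + P[s[a], s[k]] * P[s[b], s[k]] / (px[s[a]] * py[s[k]])
      M[a, b] <- acc
    }
    ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
    f14 <- sqrt(max(ev[2], 0))
  }
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
}

# Build a small single-frame DICOM file byte by byte (explicit VR little
# endian by default). Synthetic fixture; pixel values given as an integer
# matrix written row-major.
writeTestDicom <- function(path, pix, bits = 16L, photometric = "MONOCHROME2",
                           transferSyntax = "1.2.840.10008.1.2.1") {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  el <- function(grp, ele, vr, value) {
    u16(grp); u16(ele)
    if (vr %in% c("OB", "OW")) {
      writeChar(vr, con, 2, eos = NULL); u16(0); u32(length(value))
      writeBin(value, con)
    } else if (vr == "raw2") {       # short-form binary payload
      writeChar("US", con, 2, eos = NULL); u16(2); u16(value)
    } else {
      if (nchar(value) %% 2 == 1) value <- paste0(value, " ")
      writeChar(vr, con, 2, eos = NULL); u16(nchar(value))
      writeChar(value, con, nchar(value), eos = NULL)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, 4, eos = NULL)
  el(0x0002, 0x0010, "UI", transferSyntax)
  explicit <- transferSyntax == "1.2.840.10008.1.2.1"
  elBody <- function(grp, ele, vr, value, payload = NULL) {
    u16(grp); u16(ele)
    if (!is.null(payload)) {
      if (explicit) { writeChar("OW", con, 2, eos = NULL); u16(0); u32(length(payload)) }
      else u32(length(payload))
      writeBin(payload, con)
    } else if (vr == "US") {
      if (explicit) { writeChar("US", con, 2, eos = NULL); u16(2) } else u32(2)
      u16(value)
    } else {
      if (nchar(value) %% 2 == 1) value <- paste0(value, " ")
      if (explicit) { writeChar(vr, con, 2, eos = NULL); u16(nchar(value)) }
      else u32(nchar(value))
      writeChar(value, con, nchar(value), eos = NULL)
    }
  }
  elBody(0x0028, 0x0002, "US", 1L)
  elBody(0x0028, 0x0004, "CS", photometric)
  elBody(0x0028, 0x0010, "US", nrow(pix))
  elBody(0x0028, 0x0011, "US", ncol(pix))
  elBody(0x0028, 0x0100, "US", bits)
  elBody(0x0028, 0x0103, "US", 0L)
  v <- as.integer(t(pix))              # row-major
  payload <- if (bits == 8L) as.raw(v) else
    writeBin(v, raw(), size = 2, endian = "little")
  elBody(0x7fe0, 0x0010, "OW", payload = payload)
  invisible(path)
}

# Depth-3 same-padding U-Net whose prediction copies the mask input
# channel: all weights zero except a centre-tap path
# enc1_conv1(ch2) -> enc1_conv2 -> skip -> dec1_conv1(skip ch) ->
# dec1_conv2 -> head(class 2).
makeIdentityUNet <- function() {
  model <- buildUNet(unetConfig(), seed = 1L)
  for (nm in names(model$params)) {
    model$params[[nm]]$W[] <- 0
    model$params[[nm]]$b[] <- 0
  }
  model$params$enc1_conv1$W[5 + 9 * 1, 1] <- 1   # centre tap, input channel 2
  model$params$enc1_conv2$W[5, 1] <- 1
  model$params$dec1_conv1$W[5 + 9 * 16, 1] <- 1  # skip block, channel 1
  model$params$dec1_conv2$W[5, 1] <- 1
  model$params$head$W[1, 2] <- 1
  model
}

# One denoised phantom plus its texture-stage initial mask, shared by the
# network tests.
phantomTrainingCase <- function(seed = 7L) {
  ph <- generatePhantom(phantomParams(seed = seed))
  den <- wienerDenoise(ph@image)
  fmap <- textureFeatureMap(den, glcmMapConfig(window = 9L, stride = 2L))
  init <- initialTextureSegmentation(fmap, den, seed = seed)
  list(phantom = ph, denoised = den, init = init,
       stack = stackInputs(den, init))
}

# Minimal 16-bit grayscale PNG writer (IHDR/IDAT/IEND with zlib via
# memCompress and a table-driven CRC32), used only to build read fixtures.
writePNG16 <- function(pix, path) {
  crcTable <- local({
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L)) bitwXor(-306674912L, bitwShiftR(c, 1)) else
          bitwShiftR(c, 1)
      tab[n + 1] <- c
    }
    tab
  })
  crc32 <- function(bytes) {
    c <- -1L
    for (b in as.integer(bytes))
      c <- bitwXor(crcTable[bitwAnd(bitwXor(c, b), 255L) + 1L],
                   bitwShiftR(bitwAnd(c, -256L), 8))
    bitwXor(c, -1L)
  }
  u32 <- function(x) {
    x <- as.numeric(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(crc32(body)))
  }
  H <- nrow(pix); W <- ncol(pix)
  ihdr <- c(u32(W), u32(H), as.raw(c(16, 0, 0, 0, 0)))  # depth 16, gray
  scan <- raw(0)
  for (r in seq_len(H)) {
    v <- as.integer(pix[r, ])
    scan <- c(scan, as.raw(0),
              as.raw(rbind(v %/% 256, v %% 256)))      # filter 0 + big endian
  }
  idat <- memCompress(scan, type = "gzip")             # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
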