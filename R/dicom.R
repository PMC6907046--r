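# Minimal single-frame grayscale DICOM reader.
#
# Supports Part-10 files (128-byte preamble + "DICM") in implicit or
# explicit VR little endian, uncompressed, MONOCHROME1/2, one sample per
# pixel, 8 or 16 bits allocated. The method itself operates on 8-bit PNG
# ROIs; this path exists as a convenience for raw scanner exports, so the
# parser is deliberately narrow and errors loudly on anything else.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

readDicomImage <- function(path, intensityRange = c(0, 255)) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stopDomain("'%s' is not a DICOM part-10 file (missing DICM marker)", path)
  meta <- dicomParse(raw, 133L, explicit = TRUE, stopGroup = 2L)
  ts <- dicomString(meta$elements[["0002,0010"]])
  if (!is.null(ts) && !ts %in% c(UID_IMPLICIT_LE, UID_EXPLICIT_LE))
    stopDomain("unsupported DICOM transfer syntax '%s' (only uncompressed little endian)", ts)
  explicit <- is.null(ts) || ts == UID_EXPLICIT_LE
  body <- dicomParse(raw, meta$pos, explicit = explicit, stopGroup = NA)
  el <- body$elements

  photometric <- dicomString(el[["0028,0004"]])
  if (is.null(photometric) || !photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stopDomain("unsupported photometric interpretation '%s'",
               if (is.null(photometric)) "<absent>" else photometric)
  samples <- dicomUint(el[["0028,0002"]], 1L)
  if (samples != 1L) stopDomain("only single-sample (grayscale) DICOM supported")
  rows <- dicomUint(el[["0028,0010"]]); cols <- dicomUint(el[["0028,0011"]])
  bits <- dicomUint(el[["0028,0100"]])
  signed <- dicomUint(el[["0028,0103"]], 0L) == 1L
  frames <- dicomUint0(dicomString(el[["0028,0008"]]), 1L)
  if (frames != 1L) stopDomain("multi-frame DICOM not supported")
  pd <- el[["7fe0,0010"]]
  if (is.null(pd) || is.null(rows) || is.null(cols) || is.null(bits))
    stopDomain("DICOM missing Rows/Columns/BitsAllocated/PixelData")

  if (bits == 8L) {
    v <- as.integer(pd)[seq_len(rows * cols)]
  } else if (bits == 16L) {
    v <- readBin(pd, "integer", n = rows * cols, size = 2L,
                 signed = signed, endian = "little")
  } else stopDomain("unsupported BitsAllocated = %d", bits)
  slope <- dicomUint0(dicomString(el[["0028,1053"]]), 1)
  icept <- dicomUint0(dicomString(el[["0028,1052"]]), 0)
  v <- v * slope + icept
  # pixel data is stored row-major (left-to-right, top-to-bottom)
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  if (photometric == "MONOCHROME1") m <- max(m) - m  # invert: low = bright
  lo <- min(m); hi <- max(m)
  px <- if (hi > lo) (m - lo) / (hi - lo) * (intensityRange[2] - intensityRange[1]) +
          intensityRange[1] else matrix(intensityRange[1], rows, cols)
  grayImage(px, intensityRange)
}

# Walk data elements from byte offset `pos` (1-based); returns the element
# table (named "gggg,eeee" -> raw value) and the offset after the last one.
dicomParse <- function(raw, pos, explicit, stopGroup) {
  n <- length(raw)
  elements <- list()
  longVRs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  while (pos + 7L <= n + 1L && pos <= n) {
    grp <- dicomU16(raw, pos); ele <- dicomU16(raw, pos + 2L)
    if (!is.na(stopGroup) && grp != stopGroup) break
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% longVRs) {
        len <- dicomU32(raw, pos + 4L); pos <- pos + 8L
      } else {
        len <- dicomU16(raw, pos + 2L); pos <- pos + 4L
      }
    } else {
      vr <- NA_character_
      len <- dicomU32(raw, pos); pos <- pos + 4L
    }
    if (len == 4294967295) stopDomain("undefined-length DICOM element (encapsulated?) not supported")
    if (pos + len - 1L > n) stopDomain("truncated DICOM element")
    key <- sprintf("%04x,%04x", grp, ele)
    elements[[key]] <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    if (key == "7fe0,0010") break
  }
  list(elements = elements, pos = pos)
}

dicomU16 <- function(raw, pos)
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
dicomU32 <- function(raw, pos)
  as.numeric(dicomU16(raw, pos)) + 65536 * as.numeric(dicomU16(raw, pos + 2L))
dicomString <- function(v) if (is.null(v)) NULL else trimws(rawToChar(v[v != as.raw(0)]))
dicomUint <- function(v, default = NULL) {
  if (is.null(v) || length(v) < 2L) return(default)
  dicomU16(v, 1L)
}
dicomUint0 <- function(s, default) {
  if (is.null(s) || !nzchar(s)) return(default)
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) default else x
}
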