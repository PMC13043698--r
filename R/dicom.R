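# Minimal DICOM support: uncompressed little-endian, single-frame,
# monochrome. This covers the de-identified exports the pipeline accepts
# (Explicit/Implicit VR Little Endian); compressed transfer syntaxes,
# colour images and cine loops are rejected.

UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding carries a 4-byte length after 2 reserved bytes
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

uint16_at <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

uint32_at <- function(bytes, pos) {
  as.double(bytes[pos]) + 256 * as.double(bytes[pos + 1L]) +
    65536 * as.double(bytes[pos + 2L]) + 16777216 * as.double(bytes[pos + 3L])
}

ascii_value <- function(raw) {
  trimws(rawToChar(raw[raw != as.raw(0)]))
}

# Parse one element; returns list(tag, value_raw, next_pos) or NULL at EOF.
parse_element <- function(bytes, pos, explicit) {
  n <- length(bytes)
  if (pos + 7L > n) return(NULL)
  group <- uint16_at(bytes, pos)
  elem <- uint16_at(bytes, pos + 2L)
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% LONG_VRS) {
      len <- uint32_at(bytes, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- uint16_at(bytes, pos + 6L)
      data_pos <- pos + 8L
    }
  } else {
    vr <- NA_character_
    len <- uint32_at(bytes, pos + 4L)
    data_pos <- pos + 8L
  }
  if (len == 4294967295) {
    qlus_stop("DICOM element with undefined length is not supported",
              "qlus_format_error")
  }
  if (data_pos + len - 1 > n) {
    qlus_stop("truncated DICOM element", "qlus_io_error")
  }
  value <- if (len > 0) bytes[data_pos:(data_pos + len - 1)] else raw(0)
  list(tag = sprintf("%04x,%04x", group, elem), group = group,
       vr = vr, value = value, next_pos = data_pos + len)
}

#' Read an uncompressed monochrome DICOM file
#'
#' Parses Explicit or Implicit VR Little Endian datasets and returns the raw
#' stored pixel grid (not yet reduced to 8-bit) plus the geometry tags the
#' pipeline needs. Compressed transfer syntaxes, colour images and
#' multi-frame objects raise a format error.
#'
#' @param path Path to a `.dcm` file.
#' @return List with `pixels` (integer matrix, stored values), `bits_stored`,
#'   `bits_allocated`, and `pixel_spacing_mm` (or `NULL`).
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 ||
      rawToChar(bytes[129:132]) != "DICM") {
    qlus_stop(sprintf("'%s' is not a DICOM part-10 file", path),
              "qlus_io_error")
  }
  pos <- 133L
  # file meta group (0002,xxxx) is always Explicit VR Little Endian
  transfer_syntax <- NULL
  repeat {
    if (pos + 7L > length(bytes)) break
    if (uint16_at(bytes, pos) != 2L) break
    el <- parse_element(bytes, pos, explicit = TRUE)
    if (el$tag == "0002,0010") transfer_syntax <- ascii_value(el$value)
    pos <- el$next_pos
  }
  if (is.null(transfer_syntax)) {
    qlus_stop("DICOM file meta header lacks a transfer syntax UID",
              "qlus_format_error")
  }
  if (!transfer_syntax %in% c(UID_IMPLICIT_LE, UID_EXPLICIT_LE)) {
    qlus_stop(sprintf("unsupported transfer syntax '%s' (only uncompressed little endian)",
                      transfer_syntax),
              "qlus_format_error")
  }
  explicit <- transfer_syntax == UID_EXPLICIT_LE
  tags <- new.env(parent = emptyenv())
  repeat {
    el <- parse_element(bytes, pos, explicit)
    if (is.null(el)) break
    assign(el$tag, el$value, envir = tags)
    pos <- el$next_pos
    if (el$tag == "7fe0,0010") break
  }
  get_tag <- function(tag) if (exists(tag, envir = tags)) get(tag, envir = tags) else NULL
  need_u16 <- function(tag, what) {
    v <- get_tag(tag)
    if (is.null(v) || length(v) < 2) {
      qlus_stop(sprintf("DICOM is missing required tag %s (%s)", tag, what),
                "qlus_format_error")
    }
    uint16_at(v, 1L)
  }
  samples <- get_tag("0028,0002")
  if (!is.null(samples) && uint16_at(samples, 1L) != 1L) {
    qlus_stop("colour DICOM (SamplesPerPixel != 1) is not supported",
              "qlus_format_error")
  }
  photometric <- get_tag("0028,0004")
  if (!is.null(photometric) &&
      !startsWith(ascii_value(photometric), "MONOCHROME")) {
    qlus_stop("only monochrome photometric interpretations are supported",
              "qlus_format_error")
  }
  n_frames <- get_tag("0028,0008")
  if (!is.null(n_frames) && ascii_value(n_frames) != "" &&
      as.integer(ascii_value(n_frames)) != 1L) {
    qlus_stop("multi-frame DICOM (cine loop) is not supported",
              "qlus_format_error")
  }
  rows <- need_u16("0028,0010", "Rows")
  cols <- need_u16("0028,0011", "Columns")
  bits_alloc <- need_u16("0028,0100", "BitsAllocated")
  bits_stored_raw <- get_tag("0028,0101")
  bits_stored <- if (is.null(bits_stored_raw)) bits_alloc else uint16_at(bits_stored_raw, 1L)
  if (!bits_alloc %in% c(8L, 16L)) {
    qlus_stop("only 8- or 16-bit allocated DICOM pixel data is supported",
              "qlus_format_error")
  }
  pix_rep <- get_tag("0028,0103")
  if (!is.null(pix_rep) && uint16_at(pix_rep, 1L) != 0L) {
    qlus_stop("signed DICOM pixel data is not supported", "qlus_format_error")
  }
  pixel_raw <- get_tag("7fe0,0010")
  if (is.null(pixel_raw)) {
    qlus_stop("DICOM has no PixelData element", "qlus_format_error")
  }
  n_px <- rows * cols
  if (bits_alloc == 8L) {
    if (length(pixel_raw) < n_px) {
      qlus_stop("PixelData shorter than Rows*Columns", "qlus_io_error")
    }
    values <- as.integer(pixel_raw[seq_len(n_px)])
  } else {
    if (length(pixel_raw) < 2L * n_px) {
      qlus_stop("PixelData shorter than Rows*Columns", "qlus_io_error")
    }
    values <- readBin(pixel_raw, "integer", n = n_px, size = 2L,
                      signed = FALSE, endian = "little")
  }
  spacing <- get_tag("0028,0030")
  pixel_spacing_mm <- if (!is.null(spacing)) {
    as.numeric(strsplit(ascii_value(spacing), "\\\\")[[1]])[1]
  } else {
    NULL
  }
  list(pixels = matrix(values, nrow = rows, ncol = cols, byrow = TRUE),
       bits_stored = bits_stored, bits_allocated = bits_alloc,
       pixel_spacing_mm = pixel_spacing_mm)
}

encode_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                   size = 2L, endian = "little")
  if (vr %in% LONG_VRS) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

enc_us <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

#' Write an uncompressed monochrome DICOM file
#'
#' Writes a part-10 Explicit VR Little Endian file holding one monochrome
#' frame. Intended for round-trip tests and synthetic exports; stored values
#' may use 8 or 16 bits.
#'
#' @param pixels Integer matrix of stored values.
#' @param path Output path.
#' @param bits_stored 8 or 16.
#' @param pixel_spacing_mm Optional pixel spacing written to (0028,0030).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, bits_stored = 8L,
                        pixel_spacing_mm = NULL) {
  stopifnot(is.matrix(pixels))
  bits_stored <- as.integer(bits_stored)
  if (!bits_stored %in% c(8L, 16L)) {
    qlus_stop("`bits_stored` must be 8 or 16", "qlus_value_error")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 2^bits_stored - 1)) {
    qlus_stop("pixel values out of range for the stated bit depth",
              "qlus_value_error")
  }
  values <- as.integer(t(pixels))  # DICOM stores row-major
  pixel_raw <- if (bits_stored == 8L) {
    as.raw(values)
  } else {
    writeBin(values, raw(), size = 2L, endian = "little")
  }
  sop_class <- "1.2.840.10008.5.1.4.1.1.6.1"  # ultrasound image storage
  meta <- c(
    encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    encode_element(0x0002, 0x0002, "UI", charToRaw(sop_class)),
    encode_element(0x0002, 0x0003, "UI", charToRaw("1.2.826.0.1.3680043.2.0.1")),
    encode_element(0x0002, 0x0010, "UI", charToRaw(UID_EXPLICIT_LE))
  )
  meta <- c(encode_element(0x0002, 0x0000, "UL",
                           writeBin(length(meta), raw(), size = 4L,
                                    endian = "little")),
            meta)
  body <- c(
    encode_element(0x0008, 0x0016, "UI", charToRaw(sop_class)),
    encode_element(0x0028, 0x0002, "US", enc_us(1L)),
    encode_element(0x0028, 0x0004, "CS", charToRaw("MONOCHROME2")),
    encode_element(0x0028, 0x0010, "US", enc_us(nrow(pixels))),
    encode_element(0x0028, 0x0011, "US", enc_us(ncol(pixels)))
  )
  if (!is.null(pixel_spacing_mm)) {
    body <- c(body, encode_element(
      0x0028, 0x0030, "DS",
      charToRaw(sprintf("%g\\%g", pixel_spacing_mm, pixel_spacing_mm))))
  }
  body <- c(
    body,
    encode_element(0x0028, 0x0100, "US", enc_us(bits_stored)),
    encode_element(0x0028, 0x0101, "US", enc_us(bits_stored)),
    encode_element(0x0028, 0x0102, "US", enc_us(bits_stored - 1L)),
    encode_element(0x0028, 0x0103, "US", enc_us(0L)),
    encode_element(0x7fe0, 0x0010, "OW", pixel_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
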