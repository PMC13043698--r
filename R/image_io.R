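#' Admissible lung zone labels
#'
#' The eight imaging sections used for quantitative lung ultrasound:
#' left/right x anterior/lateral x upper/lower. Labels are bit-exact strings,
#' e.g. `"LAL"` = left anterior lower, `"RLU"` = right lateral upper.
#'
#' @export
QLUS_ZONES <- c("LAL", "LAU", "LLL", "LLU", "RAL", "RAU", "RLL", "RLU")

#' Construct an ultrasound frame
#'
#' An `ultrasound_frame` is one single-frame monochrome image quantised to
#' the 256-level greyscale range (0-255), together with the acquisition
#' metadata the cohort pipeline needs: subject, zone, and ultrasound machine.
#'
#' @param pixels Integer matrix (rows x columns) of grey levels in 0-255.
#' @param subject_id Opaque subject identifier.
#' @param zone One of the eight zone labels in [QLUS_ZONES].
#' @param machine_id Free-form ultrasound machine label (e.g. `"venue50"`).
#' @param pixel_spacing_mm Optional physical size of one pixel in mm.
#' @return An object of class `ultrasound_frame`.
#' @export
ultrasound_frame <- function(pixels, subject_id, zone, machine_id,
                             pixel_spacing_mm = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    qlus_stop("`pixels` must be a non-empty matrix", "qlus_value_error")
  }
  if (anyNA(pixels) || any(pixels != floor(pixels)) ||
      any(pixels < 0) || any(pixels > 255)) {
    qlus_stop("pixel intensities must be integers in [0, 255]",
              "qlus_value_error")
  }
  if (!is.character(zone) || length(zone) != 1L || !(zone %in% QLUS_ZONES)) {
    qlus_stop(sprintf("`zone` must be one of: %s",
                      paste(QLUS_ZONES, collapse = ", ")),
              "qlus_value_error")
  }
  if (!is.null(pixel_spacing_mm)) {
    assert_scalar_number(pixel_spacing_mm, "pixel_spacing_mm")
    if (pixel_spacing_mm <= 0) {
      qlus_stop("`pixel_spacing_mm` must be positive", "qlus_value_error")
    }
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels,
         height = nrow(pixels), width = ncol(pixels),
         pixel_spacing_mm = pixel_spacing_mm,
         subject_id = as.character(subject_id),
         zone = zone,
         machine_id = as.character(machine_id)),
    class = "ultrasound_frame"
  )
}

#' @export
print.ultrasound_frame <- function(x, ...) {
  cat(sprintf("<ultrasound_frame> %dx%d px, subject=%s zone=%s machine=%s\n",
              x$height, x$width, x$subject_id, x$zone, x$machine_id))
  invisible(x)
}

#' Reduce raw intensities to the 8-bit greyscale range
#'
#' Maps raw non-negative intensities onto grey levels 0-255 by floor scaling:
#' `floor(raw * 255 / source_max)`. The mapping is monotone non-decreasing,
#' hits 0 and 255 at the endpoints, and is the identity on 8-bit input with
#' `source_max = 255`. A rounding variant is available for parity with
#' viewers that round instead of truncating.
#'
#' @param raw Numeric matrix/vector of non-negative integers.
#' @param source_max Largest representable raw value (e.g. 65535 for 16-bit).
#' @param rounding `"floor"` (default) or `"round"` (half-up).
#' @return Integer grey levels in 0-255, same shape as `raw`.
#' @export
to_8bit <- function(raw, source_max, rounding = c("floor", "round")) {
  rounding <- match.arg(rounding)
  assert_scalar_number(source_max, "source_max")
  if (source_max < 1) {
    qlus_stop("`source_max` must be >= 1", "qlus_value_error")
  }
  if (anyNA(raw) || any(raw < 0)) {
    qlus_stop("raw intensities must be non-negative", "qlus_value_error")
  }
  if (any(raw > source_max)) {
    qlus_stop("raw intensity exceeds `source_max`", "qlus_range_error")
  }
  scaled <- (raw * 255.0) / source_max  # exact for raw <= 2^46 / 255
  out <- if (rounding == "floor") floor(scaled) else round_half_up(scaled)
  out[out > 255] <- 255L
  storage.mode(out) <- "integer"
  out
}

read_sidecar <- function(path) {
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sidecar)) return(list())
  jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
}

#' Read one ultrasound frame from disk
#'
#' Supports 8-bit greyscale PNG and uncompressed little-endian single-frame
#' monochrome DICOM. DICOM data deeper than 8 bits is reduced with [to_8bit]
#' using `source_max = 2^BitsStored - 1`. Subject/zone/machine metadata is
#' taken from a JSON sidecar (`<file>.json` with keys `subject_id`, `zone`,
#' `machine_id`, `pixel_spacing_mm`); entries in `metadata_overrides` win
#' over the sidecar, and the sidecar wins over file-internal tags.
#'
#' @param path Path to a `.png` or `.dcm` file.
#' @param metadata_overrides Optional named list overriding metadata fields.
#' @param rounding Bit-depth reduction mode, see [to_8bit].
#' @return An [ultrasound_frame].
#' @export
read_frame <- function(path, metadata_overrides = list(),
                       rounding = c("floor", "round")) {
  rounding <- match.arg(rounding)
  if (!file.exists(path)) {
    qlus_stop(sprintf("cannot read '%s': no such file", path),
              "qlus_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  meta <- list()
  if (ext == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) qlus_stop(
                      sprintf("failed to decode PNG '%s': %s",
                              path, conditionMessage(e)),
                      "qlus_io_error"))
    if (length(dim(img)) == 3L) {
      qlus_stop("colour or multi-channel PNG is not supported; expected 8-bit greyscale",
                "qlus_format_error")
    }
    scaled <- img * 255
    if (max(abs(scaled - round(scaled))) > 1e-6) {
      qlus_stop("PNG does not hold 8-bit grey levels", "qlus_format_error")
    }
    pixels <- round(scaled)
    storage.mode(pixels) <- "integer"
  } else if (ext %in% c("dcm", "dicom")) {
    dcm <- read_dicom(path)
    if (dcm$bits_stored > 8L) {
      pixels <- to_8bit(dcm$pixels, 2^dcm$bits_stored - 1, rounding = rounding)
    } else {
      pixels <- dcm$pixels
      storage.mode(pixels) <- "integer"
    }
    meta$pixel_spacing_mm <- dcm$pixel_spacing_mm
  } else {
    qlus_stop(sprintf("unsupported image extension '%s'", ext),
              "qlus_format_error")
  }
  sidecar <- read_sidecar(path)
  for (field in c("subject_id", "zone", "machine_id", "pixel_spacing_mm")) {
    if (!is.null(metadata_overrides[[field]])) {
      meta[[field]] <- metadata_overrides[[field]]
    } else if (!is.null(sidecar[[field]]) && is.null(meta[[field]])) {
      meta[[field]] <- sidecar[[field]]
    }
  }
  for (field in c("subject_id", "zone", "machine_id")) {
    if (is.null(meta[[field]])) {
      qlus_stop(sprintf("frame metadata field '%s' missing: supply a sidecar JSON or an override",
                        field),
                "qlus_metadata_error")
    }
  }
  ultrasound_frame(pixels, meta$subject_id, meta$zone, meta$machine_id,
                   pixel_spacing_mm = meta$pixel_spacing_mm)
}

#' Write a frame as an 8-bit greyscale PNG (plus metadata sidecar)
#'
#' @param frame An [ultrasound_frame].
#' @param path Output `.png` path.
#' @param sidecar Write the metadata sidecar JSON next to the image?
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path, sidecar = TRUE) {
  stopifnot(inherits(frame, "ultrasound_frame"))
  png::writePNG(frame$pixels / 255, target = path)
  if (sidecar) {
    meta <- list(subject_id = frame$subject_id, zone = frame$zone,
                 machine_id = frame$machine_id)
    if (!is.null(frame$pixel_spacing_mm)) {
      meta$pixel_spacing_mm <- frame$pixel_spacing_mm
    }
    jsonlite::write_json(meta,
                         paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
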