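#' Pleural region-of-interest specification
#'
#' The ROI follows the convention used for pleural/subpleural greyscale
#' analysis: the superior boundary is the pleural line (included), the
#' lateral boundaries are the rib shadows flanking the intercostal window,
#' and the inferior boundary is a fixed depth below the pleural line
#' (default 50 pixels, approximately 1 mm at typical neonatal linear-probe
#' settings).
#'
#' Coordinates are 0-based `(column, row)` with rows increasing downward,
#' matching the on-disk JSON representation.
#'
#' @param pleural_polyline Two-column matrix (or list of `c(col, row)`
#'   pairs) tracing the pleural surface left to right; columns must be
#'   strictly increasing.
#' @param lateral_bounds Half-open column interval `c(col_min, col_max)`;
#'   pixels with `col_min <= col < col_max` are eligible.
#' @param depth_px Band depth in pixels below (and including) the pleural
#'   row.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(pleural_polyline, lateral_bounds, depth_px = 50L) {
  if (is.list(pleural_polyline)) {
    pleural_polyline <- do.call(rbind, pleural_polyline)
  }
  pleural_polyline <- as.matrix(pleural_polyline)
  if (ncol(pleural_polyline) != 2L || nrow(pleural_polyline) < 2L) {
    qlus_stop("`pleural_polyline` needs >= 2 (column, row) vertices",
              "qlus_spec_error")
  }
  cols <- pleural_polyline[, 1]
  if (any(diff(cols) <= 0)) {
    qlus_stop("polyline columns must be strictly increasing",
              "qlus_spec_error")
  }
  if (length(lateral_bounds) != 2L || anyNA(lateral_bounds)) {
    qlus_stop("`lateral_bounds` must be c(col_min, col_max)",
              "qlus_spec_error")
  }
  col_min <- lateral_bounds[1]
  col_max <- lateral_bounds[2]
  if (col_min >= col_max) {
    qlus_stop("lateral interval [col_min, col_max) is empty",
              "qlus_spec_error")
  }
  if (col_min < cols[1] || col_max - 1 > cols[length(cols)]) {
    qlus_stop("lateral bounds fall outside the polyline's column span",
              "qlus_spec_error")
  }
  depth_px <- as.integer(depth_px)
  if (is.na(depth_px) || depth_px < 1L) {
    qlus_stop("`depth_px` must be >= 1", "qlus_spec_error")
  }
  structure(list(pleural_polyline = pleural_polyline,
                 lateral_bounds = c(col_min, col_max),
                 depth_px = depth_px),
            class = "roi_spec")
}

# Interpolated pleural row (0-based) at each 0-based column in `cols0`;
# ties round half-up so the rasterisation is deterministic.
pleural_row_at <- function(spec, cols0) {
  v <- spec$pleural_polyline
  xs <- v[, 1]; ys <- v[, 2]
  if (any(cols0 < xs[1]) || any(cols0 > xs[length(xs)])) {
    qlus_stop("column outside the polyline's span", "qlus_spec_error")
  }
  seg <- findInterval(cols0, xs, rightmost.closed = TRUE)
  frac <- (cols0 - xs[seg]) / (xs[seg + 1L] - xs[seg])
  y <- ys[seg] + frac * (ys[seg + 1L] - ys[seg])
  as.integer(round_half_up(y))
}

#' Rasterise an ROI specification to a pixel mask
#'
#' Includes exactly the pixels `(c, r)` with
#' `col_min <= c < col_max` and `pleural_row(c) <= r < pleural_row(c) +
#' depth_px`, where `pleural_row(c)` is the polyline linearly interpolated
#' at column `c` and rounded half-up. A band that would extend past the
#' bottom of the frame is an error, not a silent clip: clipping changes the
#' pixel count and biases every downstream feature.
#'
#' @param spec An [roi_spec].
#' @param height,width Frame dimensions in pixels.
#' @param min_pixels Minimum admissible mask size (guards degenerate ROIs).
#' @return An object of class `roi_mask`: list with `mask` (logical
#'   height x width matrix), `n_pixels`, and `pleural_rows`.
#' @export
rasterize_roi <- function(spec, height, width, min_pixels = 100L) {
  stopifnot(inherits(spec, "roi_spec"))
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) {
    qlus_stop("frame dimensions must be positive", "qlus_value_error")
  }
  col_min <- spec$lateral_bounds[1]
  col_max <- spec$lateral_bounds[2]
  if (col_min < 0 || col_max > width) {
    qlus_stop("lateral bounds fall outside the frame", "qlus_spec_error")
  }
  cols0 <- seq.int(col_min, col_max - 1L)
  prows <- pleural_row_at(spec, cols0)
  if (anyNA(prows) || any(prows < 0L)) {
    qlus_stop("pleural polyline leaves the frame", "qlus_spec_error")
  }
  if (any(prows + spec$depth_px - 1L > height - 1L)) {
    qlus_stop(sprintf("ROI band of depth %d extends past the bottom row",
                      spec$depth_px),
              "qlus_out_of_frame_error")
  }
  depth <- spec$depth_px
  # vectorised fill: for each eligible column, rows prow..prow+depth-1
  rr <- rep(prows, each = depth) + rep.int(seq_len(depth) - 1L, length(cols0))
  cc <- rep(cols0, each = depth)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  mask[cbind(rr + 1L, cc + 1L)] <- TRUE
  n_pixels <- sum(mask)
  if (n_pixels < min_pixels) {
    qlus_stop(sprintf("ROI has %d pixels, below the minimum of %d",
                      n_pixels, min_pixels),
              "qlus_degenerate_roi_error")
  }
  structure(list(mask = mask, n_pixels = n_pixels, pleural_rows = prows,
                 lateral_bounds = spec$lateral_bounds,
                 depth_px = depth),
            class = "roi_mask")
}

#' Convert a physical depth to pixels
#'
#' @param target_mm Desired band depth in mm.
#' @param pixel_spacing_mm Physical size of one pixel in mm.
#' @return Depth in pixels, `round(target_mm / pixel_spacing_mm)`, at least 1.
#' @export
depth_from_mm <- function(target_mm, pixel_spacing_mm) {
  assert_scalar_number(target_mm, "target_mm")
  assert_scalar_number(pixel_spacing_mm, "pixel_spacing_mm")
  if (target_mm <= 0 || pixel_spacing_mm <= 0) {
    qlus_stop("depth and pixel spacing must both be positive",
              "qlus_value_error")
  }
  max(1L, as.integer(round_half_up(target_mm / pixel_spacing_mm)))
}

#' Read / write an ROI specification as JSON
#'
#' On-disk schema: `{"pleural_polyline": [[c, r], ...],
#' "lateral_bounds": [c0, c1], "depth_px": 50}` with 0-based
#' `(column, row)` coordinates, row increasing downward.
#'
#' @param path JSON file path.
#' @return [roi_spec] (for `read_roi_spec`); `path` invisibly (for
#'   `write_roi_spec`).
#' @export
read_roi_spec <- function(path) {
  if (!file.exists(path)) {
    qlus_stop(sprintf("cannot read ROI spec '%s'", path), "qlus_io_error")
  }
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  roi_spec(js$pleural_polyline, js$lateral_bounds,
           depth_px = js$depth_px %||% 50L)
}

#' @param spec An [roi_spec].
#' @rdname read_roi_spec
#' @export
write_roi_spec <- function(spec, path) {
  stopifnot(inherits(spec, "roi_spec"))
  jsonlite::write_json(
    list(pleural_polyline = unname(spec$pleural_polyline),
         lateral_bounds = spec$lateral_bounds,
         depth_px = spec$depth_px),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
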