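#' Mean grey value within a masked region
#'
#' First-order echogenicity measure: the arithmetic mean pixel intensity
#' over the ROI. Higher values indicate a brighter pleural/subpleural
#' region.
#'
#' @param frame An [ultrasound_frame].
#' @param mask An [roi_mask] (or a logical matrix congruent with the frame).
#' @return Mean grey value in `[0, 255]`.
#' @export
mean_grey_value <- function(frame, mask) {
  stopifnot(inherits(frame, "ultrasound_frame"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dim(frame$pixels))) {
    qlus_stop("mask must be a logical matrix congruent with the frame",
              "qlus_shape_error")
  }
  if (!any(m)) {
    qlus_stop("mask selects no pixels", "qlus_degenerate_roi_error")
  }
  mean(frame$pixels[m])
}

#' Build a masked grey-level co-occurrence matrix
#'
#' Counts ordered pixel pairs `(p, q)` with `q` displaced from `p` by
#' `offset = c(d_row, d_col)` where BOTH endpoints lie inside the mask —
#' pairs straddling a rib shadow or the band edge never contribute. The
#' default offset `c(0, 1)` pairs each pixel with its right-hand neighbour
#' (0 degrees, distance 1); with `symmetric = TRUE` each pair also counts
#' in the transposed cell, so `p(i, j) = p(j, i)` exactly. Counts are
#' normalised to probabilities.
#'
#' With `levels < 256` intensities are re-binned by `floor(g * levels/256)`.
#'
#' @param frame An [ultrasound_frame].
#' @param mask An [roi_mask] or logical matrix.
#' @param offset Integer displacement `c(d_row, d_col)`, nonzero.
#' @param symmetric Symmetrise the matrix? Default `TRUE`.
#' @param levels Number of grey levels (default 256; no re-binning).
#' @return Object of class `glcm`: list with probability matrix `p`
#'   (`levels` x `levels`), `levels`, `offset`, `symmetric`, `n_pairs`.
#' @export
build_glcm <- function(frame, mask, offset = c(0L, 1L), symmetric = TRUE,
                       levels = 256L) {
  stopifnot(inherits(frame, "ultrasound_frame"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!is.logical(m) || !identical(dim(m), dim(frame$pixels))) {
    qlus_stop("mask must be a logical matrix congruent with the frame",
              "qlus_shape_error")
  }
  if (!any(m)) {
    qlus_stop("mask selects no pixels", "qlus_degenerate_roi_error")
  }
  offset <- as.integer(offset)
  if (length(offset) != 2L || anyNA(offset) || all(offset == 0L)) {
    qlus_stop("`offset` must be a nonzero integer displacement c(d_row, d_col)",
              "qlus_value_error")
  }
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) {
    qlus_stop("`levels` must be >= 2", "qlus_value_error")
  }
  px <- frame$pixels
  if (levels < 256L) {
    px <- floor(px * (levels / 256))
    storage.mode(px) <- "integer"
    dim(px) <- dim(frame$pixels)
  }
  res <- glcm_pair_counts(px, m, offset[1], offset[2], levels,
                          isTRUE(symmetric))
  n_pairs <- res$n_pairs
  if (n_pairs == 0) {
    qlus_stop("no pixel pair has both endpoints inside the mask",
              "qlus_no_pairs_error")
  }
  p <- res$counts / (if (isTRUE(symmetric)) 2 * n_pairs else n_pairs)
  dim(p) <- c(levels, levels)
  structure(list(p = p, levels = levels, offset = offset,
                 symmetric = isTRUE(symmetric), n_pairs = n_pairs),
            class = "glcm", by_construction = TRUE)
}

validate_glcm <- function(g, sums) {
  if (abs(sums$total - 1) > 1e-12 || isTRUE(sums$any_neg)) {
    qlus_stop("GLCM probabilities must be non-negative and sum to 1",
              "qlus_contract_error")
  }
  # objects straight out of build_glcm are symmetric by construction;
  # hand-assembled ones get the full check
  if (!isTRUE(attr(g, "by_construction")) && isTRUE(g$symmetric) &&
      !isTRUE(all.equal(g$p, t(g$p), tolerance = 0))) {
    qlus_stop("GLCM flagged symmetric but p != t(p)", "qlus_contract_error")
  }
  invisible(g)
}

#' Haralick texture features of a GLCM
#'
#' Computes the five second-order features used for pleural/subpleural
#' texture quantification, with grey levels `i, j` in `0..levels-1`:
#' \itemize{
#'   \item angular second moment `asm = sum p(i,j)^2` — image uniformity;
#'   \item `contrast = sum (i-j)^2 p(i,j)` — local intensity variation;
#'   \item `correlation = (sum i*j*p(i,j) - mu_x*mu_y) / (sigma_x*sigma_y)`
#'     with marginal means/SDs `mu_x, sigma_x` of `p_x(i) = sum_j p(i,j)` —
#'     linear dependency of neighbouring grey levels; `NA` when either
#'     marginal has zero variance (a constant region), never imputed;
#'   \item inverse difference moment `idm = sum p(i,j) / (1 + (i-j)^2)` —
#'     local homogeneity;
#'   \item `entropy = -sum p(i,j) log p(i,j)` (0 log 0 = 0) — texture
#'     randomness; natural log by default.
#' }
#'
#' @param g A [build_glcm] result.
#' @param entropy_base Logarithm base for entropy (default `exp(1)`).
#' @return Named list: `asm`, `contrast`, `correlation`, `idm`, `entropy`.
#' @export
haralick_features <- function(g, entropy_base = exp(1)) {
  if (!inherits(g, "glcm") || !is.matrix(g$p) || !is.double(g$p)) {
    qlus_stop("not a glcm object", "qlus_contract_error")
  }
  s <- glcm_feature_sums(g$p, g$levels)
  validate_glcm(g, s)
  denom <- sqrt(max(s$var_x, 0)) * sqrt(max(s$var_y, 0))
  correlation <- if (denom < .Machine$double.eps) {
    NA_real_  # undefined on a zero-variance (constant) region
  } else {
    (s$sum_ij - s$mu_x * s$mu_y) / denom
  }
  list(asm = s$asm, contrast = s$contrast, correlation = correlation,
       idm = s$idm, entropy = s$entropy_nats / log(entropy_base))
}

#' Analyse one frame: rasterise the ROI and compute all Q-LUS features
#'
#' Composition of [rasterize_roi], [mean_grey_value], [build_glcm] and
#' [haralick_features] under one configuration. Returns one tidy row per
#' frame, ready to be bound into the per-frame feature table.
#'
#' @param frame An [ultrasound_frame].
#' @param spec An [roi_spec].
#' @param config A [qlus_config] list (GLCM and ROI settings).
#' @return One-row [tibble::tibble]: subject_id, zone, machine_id,
#'   n_roi_pixels, n_pairs, mgv, asm, contrast, correlation, idm, entropy.
#' @export
analyze_frame <- function(frame, spec, config = qlus_config()) {
  mask <- rasterize_roi(spec, frame$height, frame$width,
                        min_pixels = config$min_roi_pixels)
  g <- build_glcm(frame, mask, offset = config$offset,
                  symmetric = config$symmetric, levels = config$levels)
  feats <- haralick_features(g, entropy_base = config$entropy_base)
  tibble::new_tibble(list(
    subject_id = frame$subject_id, zone = frame$zone,
    machine_id = frame$machine_id,
    n_roi_pixels = mask$n_pixels, n_pairs = g$n_pairs,
    mgv = mean_grey_value(frame, mask),
    asm = feats$asm, contrast = feats$contrast,
    correlation = feats$correlation, idm = feats$idm,
    entropy = feats$entropy), nrow = 1L)
}
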