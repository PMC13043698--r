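#' Respiratory support modes
#'
#' Modes under which mean airway pressure (MAP) is measured or set — CPAP,
#' conventional mechanical ventilation, high-frequency oscillatory
#' ventilation — versus modes with no measured MAP (no support, nasal
#' high flow). For CPAP the set pressure is taken as MAP.
#'
#' @export
SUPPORT_MODES <- c("none", "high_flow", "cpap", "cmv", "hfov")

#' @rdname SUPPORT_MODES
#' @export
MAP_MODES <- c("cpap", "cmv", "hfov")

#' Oxygen saturation index (OSI)
#'
#' `OSI = MAP * FiO2 / SpO2` with FiO2 and SpO2 on a common percentage
#' scale, the standard clinical convention: `MAP * (FiO2 * 100) / SpO2[%]`.
#' So `OSI(10, 1.0, 100) = 10`. Higher OSI means worse oxygenation; OSI is
#' strictly increasing in MAP and FiO2 and strictly decreasing in SpO2.
#' Set `fio2_scale = "fraction"` to leave FiO2 as a raw fraction.
#'
#' @param map_cmH2O Mean airway pressure, cmH2O (positive).
#' @param fio2 Fraction of inspired oxygen, 0.21-1.0.
#' @param spo2 Peripheral oxygen saturation, percent, (0, 100].
#' @param fio2_scale `"percent"` (default) or `"fraction"`.
#' @return OSI (unitless). Vectorised over its arguments.
#' @export
oxygen_saturation_index <- function(map_cmH2O, fio2, spo2,
                                    fio2_scale = c("percent", "fraction")) {
  fio2_scale <- match.arg(fio2_scale)
  check_fio2_spo2(fio2, spo2)
  if (anyNA(map_cmH2O) || any(map_cmH2O <= 0)) {
    qlus_stop("`map_cmH2O` must be positive", "qlus_value_error")
  }
  scale <- if (fio2_scale == "percent") 100 else 1
  map_cmH2O * (fio2 * scale) / spo2
}

check_fio2_spo2 <- function(fio2, spo2) {
  if (anyNA(fio2) || any(fio2 < 0.21) || any(fio2 > 1)) {
    qlus_stop("`fio2` must lie in [0.21, 1.0]", "qlus_value_error")
  }
  if (anyNA(spo2) || any(spo2 <= 0) || any(spo2 > 100)) {
    qlus_stop("`spo2` must lie in (0, 100]", "qlus_value_error")
  }
  invisible(TRUE)
}

#' SpO2/FiO2 (S/F) ratio
#'
#' `spo2 / fio2` with SpO2 in percent and FiO2 as a fraction. Higher is
#' better oxygenation; the ratio is decreasing in FiO2.
#'
#' @inheritParams oxygen_saturation_index
#' @return S/F ratio (unitless). Vectorised.
#' @export
sf_ratio <- function(spo2, fio2) {
  check_fio2_spo2(fio2, spo2)
  spo2 / fio2
}

#' Validate one clinical record
#'
#' A record carries subject_id, support_mode, map_cmH2O (optional), fio2,
#' spo2 and machine_id. MAP may be present only under a pressure-delivering
#' mode (CPAP set pressure counts as MAP) and must be present under
#' CMV/HFOV/CPAP.
#'
#' @param rec Named list or one-row data frame.
#' @return The record as a named list, invisibly validated.
#' @export
validate_clinical_record <- function(rec) {
  rec <- as.list(rec)
  for (f in c("subject_id", "support_mode", "fio2", "spo2", "machine_id")) {
    if (is.null(rec[[f]]) || is.na(rec[[f]])) {
      qlus_stop(sprintf("clinical record missing field '%s'", f),
                "qlus_validation_error")
    }
  }
  if (!rec$support_mode %in% SUPPORT_MODES) {
    qlus_stop(sprintf("unknown support_mode '%s'", rec$support_mode),
              "qlus_validation_error")
  }
  check_fio2_spo2(rec$fio2, rec$spo2)
  has_map <- !is.null(rec$map_cmH2O) && !is.na(rec$map_cmH2O)
  if (has_map) {
    if (rec$map_cmH2O <= 0) {
      qlus_stop("map_cmH2O must be positive when present",
                "qlus_validation_error")
    }
    if (!rec$support_mode %in% MAP_MODES) {
      qlus_stop("MAP recorded under a mode that does not deliver airway pressure",
                "qlus_validation_error")
    }
  } else if (rec$support_mode %in% MAP_MODES) {
    qlus_stop(sprintf("support_mode '%s' requires map_cmH2O",
                      rec$support_mode),
              "qlus_validation_error")
  }
  rec
}

#' Oxygenation indices for one clinical record
#'
#' The S/F ratio is computed for every record; OSI only when MAP is
#' available (for CPAP the set pressure is the MAP). Infants on no support
#' or nasal high flow have no MAP, so their oxygenation is quantified by
#' S/F alone.
#'
#' @param rec Named list or one-row data frame (see
#'   [validate_clinical_record]).
#' @param fio2_scale See [oxygen_saturation_index].
#' @return List with `osi` (or `NA` when MAP unavailable) and `sf_ratio`.
#' @export
compute_indices <- function(rec, fio2_scale = "percent") {
  rec <- validate_clinical_record(rec)
  has_map <- !is.null(rec$map_cmH2O) && !is.na(rec$map_cmH2O)
  list(
    osi = if (has_map) {
      oxygen_saturation_index(rec$map_cmH2O, rec$fio2, rec$spo2,
                              fio2_scale = fio2_scale)
    } else {
      NA_real_
    },
    sf_ratio = sf_ratio(rec$spo2, rec$fio2))
}

QLUS_FEATURES <- c("mgv", "asm", "contrast", "correlation", "idm", "entropy")

#' Aggregate zone-level features into one Q-LUS value per infant
#'
#' Each subject's Q-LUS value for a feature is the arithmetic mean of that
#' feature over the imaged zones. An undefined zone-level correlation
#' (constant ROI) is excluded from the correlation mean — with a warning —
#' rather than imputed, and the number of zones actually used is recorded.
#' Under the strict policy (default) all 8 zones must be present; the
#' lenient policy accepts `min_zones` or more (default 6) with a warning.
#'
#' @param features_by_zone Data frame of per-frame feature rows for ONE
#'   subject (as produced by [analyze_frame]), one row per zone.
#' @param policy `"strict"` (exactly 8 zones) or `"lenient"`.
#' @param min_zones Minimum zones under the lenient policy.
#' @return One-row [tibble::tibble]: subject_id, machine_id, n_zones_used,
#'   and the six zone-mean features.
#' @export
aggregate_subject <- function(features_by_zone,
                              policy = c("strict", "lenient"),
                              min_zones = 6L) {
  policy <- match.arg(policy)
  fz <- as.data.frame(features_by_zone)
  if (nrow(fz) < 1L) {
    qlus_stop("no zone-level features supplied", "qlus_incomplete_subject_error")
  }
  if (length(unique(fz$subject_id)) != 1L) {
    qlus_stop("features_by_zone must describe a single subject",
              "qlus_validation_error")
  }
  if (anyDuplicated(fz$zone) || !all(fz$zone %in% QLUS_ZONES)) {
    qlus_stop("zones must be distinct admissible labels",
              "qlus_validation_error")
  }
  n_zones <- nrow(fz)
  if (policy == "strict" && n_zones < 8L) {
    qlus_stop(sprintf("strict aggregation needs all 8 zones, got %d", n_zones),
              "qlus_incomplete_subject_error")
  }
  if (policy == "lenient") {
    if (n_zones < min_zones) {
      qlus_stop(sprintf("lenient aggregation needs >= %d zones, got %d",
                        min_zones, n_zones),
                "qlus_incomplete_subject_error")
    }
    if (n_zones < 8L) {
      qlus_warn(sprintf("subject %s aggregated from %d of 8 zones",
                        fz$subject_id[1], n_zones),
                "qlus_incomplete_subject_warning")
    }
  }
  if (anyNA(fz$correlation)) {
    qlus_warn(sprintf(
      "subject %s: %d zone(s) with undefined GLCM correlation excluded from its mean",
      fz$subject_id[1], sum(is.na(fz$correlation))),
      "qlus_undefined_feature_warning")
  }
  means <- lapply(QLUS_FEATURES, function(f) {
    v <- fz[[f]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(means) <- QLUS_FEATURES
  tibble::tibble(
    subject_id = fz$subject_id[1],
    machine_id = fz$machine_id[1],
    n_zones_used = n_zones,
    !!!means)
}

#' Build the subject-level table: Q-LUS means joined with oxygenation
#'
#' Aggregates a per-frame feature table over subjects and joins each
#' subject's oxygenation indices computed from the clinical table.
#'
#' @param features Per-frame feature table ([analyze_frame] rows).
#' @param clinical Clinical table with columns subject_id, support_mode,
#'   map_cmH2O, fio2, spo2, machine_id.
#' @param policy,min_zones Passed to [aggregate_subject].
#' @param fio2_scale Passed to [compute_indices].
#' @return [tibble::tibble] with one row per subject: Q-LUS means plus
#'   `osi` and `sf_ratio`.
#' @export
subject_table <- function(features, clinical, policy = "strict",
                          min_zones = 6L, fio2_scale = "percent") {
  features <- as.data.frame(features)
  clinical <- as.data.frame(clinical)
  missing_clin <- setdiff(unique(features$subject_id), clinical$subject_id)
  if (length(missing_clin) > 0) {
    qlus_stop(sprintf("no clinical record for subject(s): %s",
                      paste(missing_clin, collapse = ", ")),
              "qlus_validation_error")
  }
  rows <- lapply(split(features, features$subject_id), aggregate_subject,
                 policy = policy, min_zones = min_zones)
  agg <- do.call(rbind, rows)
  idx <- lapply(agg$subject_id, function(sid) {
    compute_indices(clinical[match(sid, clinical$subject_id), ],
                    fio2_scale = fio2_scale)
  })
  agg$osi <- vapply(idx, `[[`, numeric(1), "osi")
  agg$sf_ratio <- vapply(idx, `[[`, numeric(1), "sf_ratio")
  tibble::as_tibble(agg[order(agg$subject_id), ])
}
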