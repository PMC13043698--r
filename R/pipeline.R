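#' Pipeline configuration
#'
#' Central configuration for the whole analysis. Every default is the
#' study-faithful choice: 256 grey levels with no re-binning, GLCM offset
#' `c(0, 1)` (0 degrees, distance 1), symmetric normalised GLCM, natural-log
#' entropy, 50-pixel ROI depth with a 100-pixel minimum, strict 8-zone
#' aggregation, percentage-scale OSI, bootstrap CIs, p < 0.05 significance
#' and no multiple-testing correction.
#'
#' @param levels GLCM grey levels.
#' @param offset GLCM displacement `c(d_row, d_col)`.
#' @param symmetric Symmetrise the GLCM?
#' @param entropy_base Entropy log base (`exp(1)`, 2, or 10).
#' @param depth_px ROI band depth in pixels.
#' @param min_roi_pixels Minimum mask size.
#' @param aggregation `"strict"` or `"lenient"`.
#' @param min_zones Minimum zones under the lenient policy.
#' @param fio2_scale OSI FiO2 scale, `"percent"` or `"fraction"`.
#' @param rounding Bit-depth reduction mode for [to_8bit].
#' @param ci_method `"bootstrap"` or `"fisher"`.
#' @param n_boot Bootstrap resamples.
#' @param p_method Spearman p-value method.
#' @param adjust Multiple-testing adjustment (`"none"` or a
#'   [stats::p.adjust] method).
#' @param alpha Significance threshold.
#' @param seed Base seed for all stochastic steps.
#' @return Named list of class `qlus_config`.
#' @export
qlus_config <- function(levels = 256L, offset = c(0L, 1L), symmetric = TRUE,
                        entropy_base = exp(1), depth_px = 50L,
                        min_roi_pixels = 100L, aggregation = "strict",
                        min_zones = 6L, fio2_scale = "percent",
                        rounding = "floor", ci_method = "bootstrap",
                        n_boot = 2000L, p_method = "auto", adjust = "none",
                        alpha = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "qlus_config")
}

#' Write / read a pipeline configuration (JSON)
#'
#' A config written to file and read back reproduces identical pipeline
#' output.
#'
#' @param config [qlus_config].
#' @param path JSON path.
#' @return `path` invisibly / the restored `qlus_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "qlus_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  js$offset <- as.integer(js$offset)
  do.call(qlus_config, js)
}

frame_stem <- function(frame) paste0(frame$subject_id, "_", frame$zone)

#' Write a simulated cohort to a directory tree
#'
#' Produces the on-disk layout the analysis steps consume: `frames/` with
#' one 8-bit PNG + metadata sidecar per frame, `roi/` with one ROI-spec
#' JSON per frame, `clinical.csv`, `truth.csv`, and a `manifest.json`
#' recording parameters and seed.
#'
#' @param dir Output directory (created if needed).
#' @param n_subjects,params,seed Passed to [simulate_cohort].
#' @param write_dicom_frames Also export each frame as uncompressed DICOM?
#' @return The cohort object, invisibly.
#' @export
qlus_simulate_to_dir <- function(dir, n_subjects = 70L,
                                 params = sim_params(), seed = 1L,
                                 write_dicom_frames = FALSE) {
  cohort <- simulate_cohort(n_subjects, params = params, seed = seed)
  frames_dir <- file.path(dir, "frames")
  roi_dir <- file.path(dir, "roi")
  dir.create(frames_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(roi_dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cohort$frames)) {
    stem <- frame_stem(cohort$frames[[k]])
    write_frame_png(cohort$frames[[k]],
                    file.path(frames_dir, paste0(stem, ".png")))
    if (write_dicom_frames) {
      write_dicom(cohort$frames[[k]]$pixels,
                  file.path(frames_dir, paste0(stem, ".dcm")))
    }
    write_roi_spec(cohort$roi_specs[[k]],
                   file.path(roi_dir, paste0(stem, ".json")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_subjects = n_subjects, seed = seed, params = unclass(params)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Analyse a directory of frames against matching ROI specs
#'
#' Pairs every image in `frames_dir` (PNG or DICOM) with the ROI spec JSON
#' of the same stem in `roi_dir` and runs [analyze_frame] on each pair.
#' Output rows are sorted by subject then zone, so a rerun on the same
#' inputs is byte-identical. In strict mode an image without a matching
#' spec is an error; otherwise it is skipped with a warning.
#'
#' @param frames_dir Directory of `.png`/`.dcm` frames (metadata sidecars
#'   alongside).
#' @param roi_dir Directory of ROI spec JSONs.
#' @param config [qlus_config].
#' @param out_csv Optional path; when given, the table is also written as
#'   CSV.
#' @param strict Unmatched frame handling (error vs skip).
#' @return Per-frame feature [tibble::tibble].
#' @export
qlus_analyze_dir <- function(frames_dir, roi_dir, config = qlus_config(),
                             out_csv = NULL, strict = TRUE) {
  paths <- sort(list.files(frames_dir, pattern = "\\.(png|dcm|dicom)$",
                           full.names = TRUE))
  if (length(paths) == 0) {
    qlus_stop(sprintf("no frames found under '%s'", frames_dir),
              "qlus_io_error")
  }
  rows <- list()
  for (path in paths) {
    stem <- tools::file_path_sans_ext(basename(path))
    spec_path <- file.path(roi_dir, paste0(stem, ".json"))
    if (!file.exists(spec_path)) {
      if (strict) {
        qlus_stop(sprintf("frame '%s' has no ROI spec in '%s'",
                          basename(path), roi_dir),
                  "qlus_io_error")
      }
      qlus_warn(sprintf("skipping '%s': no matching ROI spec",
                        basename(path)))
      next
    }
    frame <- read_frame(path, rounding = config$rounding)
    spec <- read_roi_spec(spec_path)
    rows[[length(rows) + 1L]] <- analyze_frame(frame, spec, config = config)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$zone), ]
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE, na = "")
  }
  out
}

#' Correlate per-frame features with the clinical table and write reports
#'
#' Aggregates the per-frame feature table to subject level, joins
#' oxygenation indices, computes the long correlation table (overall and
#' per machine) and its wide study-style rendering with `"NS"` for
#' non-significant cells, and optionally draws one scatter plot per
#' (feature, index) with machine-coded points plus OSI / S/F histograms.
#'
#' @param features Per-frame feature table or path to its CSV.
#' @param clinical Clinical table or path to its CSV.
#' @param config [qlus_config].
#' @param out_dir Optional output directory for `subjects.csv`,
#'   `correlations_long.csv`, `correlations_wide.csv` and (with
#'   `make_plots`) `plots/`.
#' @param make_plots Draw scatter plots and histograms?
#' @return List: `subjects`, `long`, `wide`.
#' @export
qlus_correlate_files <- function(features, clinical,
                                 config = qlus_config(), out_dir = NULL,
                                 make_plots = FALSE) {
  if (is.character(features)) {
    features <- utils::read.csv(features, stringsAsFactors = FALSE)
  }
  if (is.character(clinical)) {
    clinical <- utils::read.csv(clinical, stringsAsFactors = FALSE)
  }
  unmatched <- setdiff(unique(features$subject_id), clinical$subject_id)
  if (length(unmatched) > 0) {
    qlus_stop(sprintf("feature rows with no clinical record: %s",
                      paste(unmatched, collapse = ", ")),
              "qlus_validation_error")
  }
  subjects <- subject_table(features, clinical,
                            policy = config$aggregation,
                            min_zones = config$min_zones,
                            fio2_scale = config$fio2_scale)
  long <- correlation_table(subjects, group_by_machine = TRUE,
                            ci_method = config$ci_method,
                            n_boot = config$n_boot,
                            p_method = config$p_method,
                            seed = config$seed, adjust = config$adjust,
                            alpha = config$alpha)
  wide <- render_wide_table(long)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(subjects, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(long, file.path(out_dir, "correlations_long.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(wide, file.path(out_dir, "correlations_wide.csv"),
                     row.names = FALSE, na = "")
    if (make_plots) {
      plot_dir <- file.path(out_dir, "plots")
      dir.create(plot_dir, showWarnings = FALSE)
      for (feat in QLUS_FEATURES) {
        for (index in c("osi", "sf_ratio")) {
          gg <- plot_feature_scatter(subjects, feat, index)
          if (!is.null(gg)) {
            ggplot2::ggsave(
              file.path(plot_dir, sprintf("scatter_%s_%s.png", feat, index)),
              gg, width = 5, height = 4, dpi = 120)
          }
        }
      }
      ggplot2::ggsave(file.path(plot_dir, "index_histograms.png"),
                      plot_index_histograms(subjects),
                      width = 7, height = 3.5, dpi = 120)
    }
  }
  list(subjects = subjects, long = long, wide = wide)
}

#' Scatter plot of one Q-LUS feature against one oxygenation index
#'
#' Points are machine-coded; each dot is one infant.
#'
#' @param subjects Subject-level table.
#' @param feature One of mgv, asm, contrast, correlation, idm, entropy.
#' @param index `"osi"` or `"sf_ratio"`.
#' @return A ggplot, or `NULL` when no complete pairs exist.
#' @export
plot_feature_scatter <- function(subjects, feature, index) {
  d <- as.data.frame(subjects)
  d <- d[!is.na(d[[feature]]) & !is.na(d[[index]]), ]
  if (nrow(d) == 0) return(NULL)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[index]], y = .data[[feature]],
    colour = .data[["machine_id"]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = toupper(sub("sf_ratio", "S/F ratio", index)),
                  y = paste("Q-LUS", feature),
                  colour = "machine") +
    ggplot2::theme_minimal()
}

#' Histograms of the two oxygenation indices
#'
#' @param subjects Subject-level table.
#' @return A ggplot with one facet per index.
#' @export
plot_index_histograms <- function(subjects) {
  d <- as.data.frame(subjects)
  long <- rbind(
    data.frame(index = "OSI", value = d$osi[!is.na(d$osi)]),
    data.frame(index = "S/F ratio", value = d$sf_ratio[!is.na(d$sf_ratio)]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[["value"]])) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40") +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = NULL, y = "infants") +
    ggplot2::theme_minimal()
}
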