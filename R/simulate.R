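#' Parameters of the synthetic lung-ultrasound simulator
#'
#' The generator draws a latent per-infant aeration level `a` in `[0, 1]`
#' and lets it drive both sides of the study: the imaging side (pleural
#' line brightness rises with aeration; B-line count falls with aeration;
#' Rayleigh speckle everywhere; dark rib shadows at the lateral edges) and
#' the clinical side (SpO2 rises and FiO2 falls with aeration, so OSI
#' falls and S/F rises). Defaults are chosen so the simulated OSI and S/F
#' spans resemble a preterm cohort on noninvasive support; they are module
#' defaults, not estimates from any clinical dataset.
#'
#' @param height,width Frame size in pixels.
#' @param pleural_row Nominal 0-based row of the pleural line.
#' @param pleural_jitter Max vertical deviation of polyline vertices (px).
#' @param pleural_band Vertical extent of the bright pleural band (px).
#' @param rib_width Width of each lateral rib shadow (px).
#' @param rib_atten Multiplicative attenuation inside rib shadows.
#' @param speckle_sigma Rayleigh scale of the background speckle.
#' @param b0,b1 Pleural band brightness: `b0 + b1 * aeration`.
#' @param bline_max,bline_width,bline_gain B-line streaks: count is
#'   `round((1 - aeration) * bline_max)`, each `bline_width` columns wide,
#'   adding `bline_gain` below the pleural line.
#' @param depth_px ROI band depth below (and including) the pleural line.
#' @param s0,s1,sd_spo2 SpO2 link: `clip(s0 + s1*a + N(0, sd_spo2), 80, 100)`.
#' @param f0,f1,sd_fio2 FiO2 link: `clip(f0 + f1*(1-a) + N(0, sd_fio2),
#'   0.21, 1)`.
#' @param map_mean,map_sd,map_min,map_max MAP draw, cmH2O, clipped normal.
#' @param sigma_z Zone-to-zone aeration spread around the subject level.
#' @param machine_mix Fraction of subjects imaged on the first machine.
#' @param machine_ids Labels of the two machine subgroups.
#' @param machine_gain,machine_offset Per-machine global grey remapping
#'   `clip(gain * g + offset)`, emulating vendor post-processing.
#' @param map_fraction Fraction of subjects on a MAP-delivering mode.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(height = 80L, width = 96L,
                       pleural_row = 18L, pleural_jitter = 2L,
                       pleural_band = 6L,
                       rib_width = 10L, rib_atten = 0.15,
                       speckle_sigma = 28,
                       b0 = 80, b1 = 100,
                       bline_max = 6L, bline_width = 2L, bline_gain = 45,
                       depth_px = 50L,
                       s0 = 88, s1 = 10, sd_spo2 = 2,
                       f0 = 0.21, f1 = 0.5, sd_fio2 = 0.05,
                       map_mean = 9, map_sd = 1.5, map_min = 5, map_max = 16,
                       sigma_z = 0.1,
                       machine_mix = 0.8,
                       machine_ids = c("venue50", "venuego"),
                       machine_gain = c(1.0, 1.12),
                       machine_offset = c(0, -8),
                       map_fraction = 0.6) {
  p <- as.list(environment())
  if (p$b1 <= 0 || p$f1 <= 0 || p$s1 <= 0) {
    # the construction requires aeration to improve echogenicity and
    # oxygenation; zeroed links are only admissible via null_params()
    qlus_stop("b1, s1 and f1 must be positive (use null_params() for the no-link generator)",
              "qlus_value_error")
  }
  if (p$b0 < 0 || p$b0 + p$b1 > 255) {
    qlus_stop("pleural brightness b0 + b1 must stay within [0, 255]",
              "qlus_value_error")
  }
  if (p$pleural_row + p$pleural_jitter + p$depth_px > p$height) {
    qlus_stop("geometry too small: pleural band plus ROI depth exceeds the frame",
              "qlus_geometry_error")
  }
  if (2 * p$rib_width + 8 >= p$width) {
    qlus_stop("geometry too small: rib shadows leave no intercostal window",
              "qlus_geometry_error")
  }
  structure(p, class = "sim_params")
}

#' No-link variant of the simulator parameters
#'
#' Zeroes the aeration-to-oxygenation link (`s1 = f1 = 0`), so SpO2 and
#' FiO2 become pure noise around their baselines and any correlation
#' between image features and oxygenation is spurious. Used for null
#' calibration of the sign-recovery experiment.
#'
#' @param ... Overrides forwarded to [sim_params].
#' @return `sim_params` list with a severed link.
#' @export
null_params <- function(...) {
  p <- sim_params(...)
  p$s1 <- 0
  p$f1 <- 0
  p$b1 <- 0
  p$s0 <- 92   # recentre baselines so clipping stays mild
  p$f0 <- 0.35
  p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate one lung-ultrasound frame with ground-truth ROI
#'
#' Rayleigh speckle background; a bright pleural band of mean brightness
#' `b0 + b1 * aeration` following a gently jittered pleural polyline;
#' `round((1 - aeration) * bline_max)` vertical B-line streaks from the
#' pleural line to the bottom of the frame; dark rib-shadow columns at the
#' lateral edges; an optional machine-specific grey remapping. The
#' returned `roi_spec` traces the simulated pleural line between the rib
#' shadows with the configured depth. Identical `(aeration, params, seed)`
#' give a bit-identical frame.
#'
#' @param aeration Latent aeration in `[0, 1]` (1 = well aerated).
#' @param params [sim_params].
#' @param seed Integer seed.
#' @param subject_id,zone,machine_id Frame metadata.
#' @return List with `frame` ([ultrasound_frame]) and `spec` ([roi_spec]).
#' @export
simulate_frame <- function(aeration, params = sim_params(), seed = 1L,
                           subject_id = "S001", zone = "LAL",
                           machine_id = params$machine_ids[1]) {
  if (!is.numeric(aeration) || length(aeration) != 1L ||
      aeration < 0 || aeration > 1) {
    qlus_stop("`aeration` must be a single value in [0, 1]",
              "qlus_value_error")
  }
  p <- params
  with_seed(seed, {
    h <- p$height; w <- p$width
    # Rayleigh speckle envelope
    img <- p$speckle_sigma * sqrt(-2 * log(stats::runif(h * w)))
    dim(img) <- c(h, w)

    # pleural polyline: vertices spanning the full width, jittered rows
    n_vert <- 5L
    vcols <- round(seq(0, w - 1L, length.out = n_vert))
    vrows <- p$pleural_row +
      round(stats::runif(n_vert, -p$pleural_jitter, p$pleural_jitter))
    spec <- roi_spec(cbind(vcols, vrows),
                     lateral_bounds = c(p$rib_width + 2L,
                                        w - p$rib_width - 2L),
                     depth_px = p$depth_px)
    prow_all <- pleural_row_at(spec, 0:(w - 1L))

    # bright pleural band following the polyline (vectorised fill)
    band_mu <- p$b0 + p$b1 * aeration
    band <- p$pleural_band
    rr <- rep(prow_all + 1L, each = band) + rep.int(0:(band - 1L), w)
    cc <- rep(seq_len(w), each = band)
    img[cbind(rr, cc)] <- band_mu + stats::rnorm(band * w, 0, 8)

    # vertical B-line streaks below the pleural line
    n_b <- round((1 - aeration) * p$bline_max)
    if (n_b > 0) {
      lo <- p$rib_width + 2L
      hi <- w - p$rib_width - 2L - p$bline_width
      starts <- sort(sample(lo:hi, n_b, replace = FALSE))
      for (s in starts) {
        cc <- (s + 1L):(s + p$bline_width)
        for (c1 in cc) {
          rr <- (prow_all[c1] + 1L):h
          img[rr, c1] <- img[rr, c1] + p$bline_gain
        }
      }
    }

    # rib shadows at both lateral edges
    img[, 1:p$rib_width] <- img[, 1:p$rib_width] * p$rib_atten
    img[, (w - p$rib_width + 1L):w] <-
      img[, (w - p$rib_width + 1L):w] * p$rib_atten

    px <- remap_u8(img, 1, 0)

    # machine-specific global remapping (vendor post-processing)
    mi <- match(machine_id, p$machine_ids)
    if (!is.na(mi) && (p$machine_gain[mi] != 1 || p$machine_offset[mi] != 0)) {
      storage.mode(px) <- "double"
      px <- remap_u8(px, p$machine_gain[mi], p$machine_offset[mi])
    }
    list(frame = ultrasound_frame(px, subject_id, zone, machine_id),
         spec = spec, n_blines = n_b)
  })
}

#' Simulate a full study cohort
#'
#' Each subject gets a latent aeration `a ~ Beta(2, 2)`, eight zone-level
#' aerations `clip(a + N(0, sigma_z), 0, 1)` and eight frames (one per
#' zone label), a machine assignment (`machine_mix` fraction on the first
#' machine), a support mode (a `map_fraction` share on CPAP/CMV/HFOV with
#' a drawn MAP; the rest on no support or high flow, without MAP), and
#' SpO2/FiO2 from the aeration link. Fully reproducible from the seed.
#'
#' @param n_subjects Number of infants (the study's own scale is 70).
#' @param params [sim_params].
#' @param seed Integer seed.
#' @return List of class `qlus_cohort`: `frames` (list of
#'   [ultrasound_frame]), `roi_specs` (parallel list), `clinical`
#'   (clinical table), `truth` (per-zone latent aeration).
#' @export
simulate_cohort <- function(n_subjects = 70L, params = sim_params(),
                            seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) {
    qlus_stop("`n_subjects` must be >= 1", "qlus_value_error")
  }
  p <- params
  draws <- with_seed(seed, {
    a <- stats::rbeta(n_subjects, 2, 2)
    zone_a <- clip(a + matrix(stats::rnorm(8L * n_subjects, 0, p$sigma_z),
                              nrow = n_subjects), 0, 1)
    spo2 <- clip(p$s0 + p$s1 * a + stats::rnorm(n_subjects, 0, p$sd_spo2),
                 80, 100)
    fio2 <- clip(p$f0 + p$f1 * (1 - a) + stats::rnorm(n_subjects, 0, p$sd_fio2),
                 0.21, 1.0)
    map <- clip(stats::rnorm(n_subjects, p$map_mean, p$map_sd),
                p$map_min, p$map_max)
    # random subset of exact size, so MAP availability is not confounded
    # with the block-wise machine assignment
    on_map <- seq_len(n_subjects) %in%
      sample.int(n_subjects, round(p$map_fraction * n_subjects))
    mode <- ifelse(on_map,
                   sample(MAP_MODES, n_subjects, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1)),
                   sample(c("none", "high_flow"), n_subjects, replace = TRUE))
    machine <- rep(p$machine_ids[2], n_subjects)
    machine[seq_len(round(p$machine_mix * n_subjects))] <- p$machine_ids[1]
    list(a = a, zone_a = zone_a, spo2 = spo2, fio2 = fio2, map = map,
         mode = mode, machine = machine)
  })
  sid <- sprintf("S%03d", seq_len(n_subjects))
  frames <- vector("list", 8L * n_subjects)
  specs <- vector("list", 8L * n_subjects)
  truth_rows <- vector("list", n_subjects)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (z in seq_along(QLUS_ZONES)) {
      k <- k + 1L
      fs <- simulate_frame(draws$zone_a[i, z], params = p,
                           seed = derive_seed(seed, 1000L + k),
                           subject_id = sid[i], zone = QLUS_ZONES[z],
                           machine_id = draws$machine[i])
      frames[[k]] <- fs$frame
      specs[[k]] <- fs$spec
    }
    truth_rows[[i]] <- tibble::tibble(
      subject_id = sid[i], aeration = draws$a[i],
      zone = QLUS_ZONES, zone_aeration = draws$zone_a[i, ])
  }
  clinical <- tibble::tibble(
    subject_id = sid,
    support_mode = draws$mode,
    map_cmH2O = ifelse(draws$mode %in% MAP_MODES, draws$map, NA_real_),
    fio2 = draws$fio2,
    spo2 = draws$spo2,
    machine_id = draws$machine)
  structure(list(frames = frames, roi_specs = specs, clinical = clinical,
                 truth = do.call(rbind, truth_rows), seed = seed,
                 params = p),
            class = "qlus_cohort")
}

#' Per-frame feature table for a simulated cohort
#'
#' Runs [analyze_frame] over every frame/spec pair of a cohort.
#'
#' @param cohort [simulate_cohort] output.
#' @param config [qlus_config].
#' @return Per-frame feature [tibble::tibble].
#' @export
analyze_cohort <- function(cohort, config = qlus_config()) {
  stopifnot(inherits(cohort, "qlus_cohort"))
  rows <- mapply(analyze_frame, cohort$frames, cohort$roi_specs,
                 MoreArgs = list(config = config), SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

#' Sign-recovery experiment: does the pipeline recover the known link?
#'
#' Monte-Carlo check of the pipeline's headline directional finding:
#' brighter pleural/subpleural regions (higher MGV) should accompany
#' better oxygenation (lower OSI, higher S/F). Each rep simulates a
#' cohort, runs ROI + texture analysis on all frames, aggregates to
#' subject level, and computes `rho(MGV, OSI)` and `rho(MGV, S/F)`; a rep
#' is a success when `rho(MGV, OSI) < 0` AND `rho(MGV, S/F) > 0`.
#'
#' @param n_subjects Subjects per rep.
#' @param n_reps Monte-Carlo repetitions.
#' @param params [sim_params] (or [null_params] for the no-link null).
#' @param seed Master seed; rep `r` uses a seed derived from it.
#' @param config [qlus_config].
#' @return Joint-sign recovery rate in `[0, 1]`, with attribute `"signs"`
#'   (a two-column matrix of the per-rep rhos).
#' @export
sign_recovery_experiment <- function(n_subjects = 70L, n_reps = 200L,
                                     params = sim_params(), seed = 1L,
                                     config = qlus_config()) {
  if (n_reps < 1L) {
    qlus_stop("`n_reps` must be >= 1", "qlus_value_error")
  }
  rhos <- matrix(NA_real_, nrow = n_reps, ncol = 2,
                 dimnames = list(NULL, c("rho_mgv_osi", "rho_mgv_sf")))
  for (r in seq_len(n_reps)) {
    cohort <- simulate_cohort(n_subjects, params = params,
                              seed = derive_seed(seed, r))
    features <- analyze_cohort(cohort, config = config)
    subj <- subject_table(features, cohort$clinical)
    ok_osi <- !is.na(subj$osi)
    rhos[r, 1] <- spearman_rho(subj$mgv[ok_osi], subj$osi[ok_osi])
    rhos[r, 2] <- spearman_rho(subj$mgv, subj$sf_ratio)
  }
  rate <- mean(rhos[, 1] < 0 & rhos[, 2] > 0)
  attr(rate, "signs") <- rhos
  rate
}
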