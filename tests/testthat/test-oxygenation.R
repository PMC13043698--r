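test_that("OSI follows the percentage-scale definition", {
  # both percentages cancel: OSI equals MAP
  expect_equal(oxygen_saturation_index(10, 1.0, 100), 10)
  expect_equal(oxygen_saturation_index(10, 0.30, 90), 10 * 30 / 90)
  # raw-fraction variant
  expect_equal(oxygen_saturation_index(10, 0.30, 90, fio2_scale = "fraction"),
               10 * 0.30 / 90)
  expect_qlus_error(oxygen_saturation_index(0, 0.3, 90), "qlus_value_error")
  expect_qlus_error(oxygen_saturation_index(10, 0.15, 90), "qlus_value_error")
  expect_qlus_error(oxygen_saturation_index(10, 0.3, 0), "qlus_value_error")
})

test_that("OSI is strictly monotone in each argument on a grid", {
  maps <- seq(5, 16, length.out = 10)
  fio2 <- seq(0.21, 1, length.out = 10)
  spo2 <- seq(80, 100, length.out = 10)
  for (f in fio2) for (s in spo2) {
    expect_true(all(diff(oxygen_saturation_index(maps, f, s)) > 0))
  }
  for (m in maps) for (s in spo2) {
    expect_true(all(diff(oxygen_saturation_index(m, fio2, s)) > 0))
  }
  for (m in maps) for (f in fio2) {
    expect_true(all(diff(oxygen_saturation_index(m, f, spo2)) < 0))
  }
})

test_that("S/F ratio definition and opposite movement to OSI", {
  expect_equal(sf_ratio(100, 1.0), 100)
  expect_equal(sf_ratio(95, 0.21), 95 / 0.21)
  expect_qlus_error(sf_ratio(95, 0.15), "qlus_value_error")
  # improving SpO2 raises S/F and lowers OSI
  s <- seq(85, 99, by = 2)
  expect_true(all(diff(sf_ratio(s, 0.4)) > 0))
  expect_true(all(diff(oxygen_saturation_index(8, 0.4, s)) < 0))
})

test_that("index availability follows the support mode rules", {
  # no support, no MAP: S/F only
  r1 <- compute_indices(list(subject_id = "a", support_mode = "none",
                             map_cmH2O = NA, fio2 = 0.3, spo2 = 95,
                             machine_id = "m"))
  expect_true(is.na(r1$osi))
  expect_equal(r1$sf_ratio, 95 / 0.3)
  # CPAP: the set pressure is the MAP, and S/F is still reported
  r2 <- compute_indices(list(subject_id = "b", support_mode = "cpap",
                             map_cmH2O = 7, fio2 = 0.25, spo2 = 92,
                             machine_id = "m"))
  expect_equal(r2$osi, oxygen_saturation_index(7, 0.25, 92))
  expect_equal(r2$sf_ratio, 92 / 0.25)
  # ventilated without a recorded MAP is invalid
  expect_qlus_error(
    compute_indices(list(subject_id = "c", support_mode = "cmv",
                         map_cmH2O = NA, fio2 = 0.4, spo2 = 90,
                         machine_id = "m")),
    "qlus_validation_error")
  # MAP under a non-pressure mode is invalid
  expect_qlus_error(
    compute_indices(list(subject_id = "d", support_mode = "high_flow",
                         map_cmH2O = 8, fio2 = 0.3, spo2 = 95,
                         machine_id = "m")),
    "qlus_validation_error")
})

make_zone_rows <- function(sid = "S1", zones = QLUS_ZONES, mgv = 50,
                           correlation = 0.5) {
  n <- length(zones)
  tibble::tibble(
    subject_id = sid, zone = zones, machine_id = "venue50",
    n_roi_pixels = 500L, n_pairs = 450,
    mgv = rep_len(mgv, n), asm = 0.1, contrast = 10,
    correlation = rep_len(correlation, n), idm = 0.5, entropy = 2)
}

test_that("zone aggregation averages each feature across the 8 zones", {
  rows <- make_zone_rows(mgv = 1:8)
  agg <- aggregate_subject(rows)
  expect_equal(agg$mgv, 4.5)
  expect_equal(agg$n_zones_used, 8L)
  const <- aggregate_subject(make_zone_rows(mgv = 7))
  expect_equal(const$mgv, 7)
  # permutation invariance and min/max bounds
  shuffled <- rows[sample(8), ]
  expect_equal(aggregate_subject(shuffled)$mgv, agg$mgv)
  expect_true(agg$mgv >= min(rows$mgv) && agg$mgv <= max(rows$mgv))
})

test_that("aggregation policies gate incomplete subjects", {
  seven <- make_zone_rows(zones = QLUS_ZONES[1:7])
  expect_qlus_error(aggregate_subject(seven),
                    "qlus_incomplete_subject_error")
  expect_warning(agg <- aggregate_subject(seven, policy = "lenient"),
                 class = "qlus_incomplete_subject_warning")
  expect_equal(agg$n_zones_used, 7L)
  expect_qlus_error(
    aggregate_subject(make_zone_rows(zones = QLUS_ZONES[1:5]),
                      policy = "lenient"),
    "qlus_incomplete_subject_error")
})

test_that("undefined zone correlations are excluded from the mean, not imputed", {
  rows <- make_zone_rows(correlation = c(NA, NA, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4))
  expect_warning(agg <- aggregate_subject(rows),
                 class = "qlus_undefined_feature_warning")
  expect_equal(agg$correlation, 0.4)
  # all-undefined collapses to NA
  rows2 <- make_zone_rows(correlation = rep(NA_real_, 8))
  expect_warning(agg2 <- aggregate_subject(rows2),
                 class = "qlus_undefined_feature_warning")
  expect_true(is.na(agg2$correlation))
})

test_that("subject table joins Q-LUS means with oxygenation indices", {
  feats <- rbind(make_zone_rows("S1", mgv = 40),
                 make_zone_rows("S2", mgv = 60))
  clin <- tibble::tibble(
    subject_id = c("S1", "S2"),
    support_mode = c("none", "cpap"),
    map_cmH2O = c(NA, 8), fio2 = c(0.3, 0.5), spo2 = c(95, 90),
    machine_id = "venue50")
  tab <- subject_table(feats, clin)
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$osi[tab$subject_id == "S1"]))
  expect_equal(tab$osi[tab$subject_id == "S2"],
               oxygen_saturation_index(8, 0.5, 90))
  expect_equal(tab$sf_ratio, c(95 / 0.3, 90 / 0.5))
  expect_qlus_error(subject_table(feats, clin[1, ]),
                    "qlus_validation_error")
})
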