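full_mask <- function(fr) matrix(TRUE, fr$height, fr$width)

test_that("mean grey value equals the masked arithmetic mean", {
  fr <- ultrasound_frame(matrix(37L, 8, 8), "s", "LAL", "m")
  expect_equal(mean_grey_value(fr, full_mask(fr)), 37)
  two <- ultrasound_frame(rbind(c(0L, 255L), c(9L, 9L)), "s", "LAL", "m")
  m <- rbind(c(TRUE, TRUE), c(FALSE, FALSE))
  expect_equal(mean_grey_value(two, m), 127.5)
  set.seed(21)
  fr <- random_frame()
  m <- random_mask()
  expect_equal(mean_grey_value(fr, m), sum(fr$pixels[m]) / sum(m))
  expect_qlus_error(mean_grey_value(fr, matrix(FALSE, 16, 16)),
                    "qlus_degenerate_roi_error")
  expect_qlus_error(mean_grey_value(fr, matrix(TRUE, 4, 4)),
                    "qlus_shape_error")
})

test_that("hand-enumerated 2x2 co-occurrence probabilities are reproduced", {
  fr <- ultrasound_frame(rbind(c(0L, 0L), c(1L, 1L)), "s", "LAL", "m")
  g <- build_glcm(fr, full_mask(fr))
  # two horizontal pairs: (0,0) and (1,1)
  expect_equal(g$p[1, 1], 0.5)
  expect_equal(g$p[2, 2], 0.5)
  expect_equal(sum(g$p), 1)
  expect_identical(g$n_pairs, 2)
  # constant image: all mass in one diagonal cell
  k <- 77L
  cg <- build_glcm(ultrasound_frame(matrix(k, 4, 4), "s", "LAL", "m"),
                   matrix(TRUE, 4, 4))
  expect_equal(cg$p[k + 1, k + 1], 1)
})

test_that("pair construction honours mask, offset and symmetry contracts", {
  fr <- random_frame(8, 8)
  # one-column mask has no horizontal pair
  m <- matrix(FALSE, 8, 8); m[, 3] <- TRUE
  expect_qlus_error(build_glcm(fr, m), "qlus_no_pairs_error")
  # but a vertical offset finds pairs in the same mask
  g <- build_glcm(fr, m, offset = c(1L, 0L))
  expect_gt(g$n_pairs, 0)
  expect_qlus_error(build_glcm(fr, full_mask(fr), offset = c(0L, 0L)),
                    "qlus_value_error")
  expect_qlus_error(build_glcm(fr, matrix(TRUE, 3, 3)), "qlus_shape_error")
  expect_qlus_error(build_glcm(fr, matrix(FALSE, 8, 8)),
                    "qlus_degenerate_roi_error")
  # symmetric matrix is exactly its transpose
  gs <- build_glcm(fr, random_mask(8, 8))
  expect_identical(gs$p, t(gs$p))
})

test_that("features of closed-form matrices match hand computation", {
  # single-cell GLCM
  p1 <- matrix(0, 2, 2); p1[2, 2] <- 1
  f1 <- haralick_features(manual_glcm(p1))
  expect_equal(f1$asm, 1)
  expect_equal(f1$contrast, 0)
  expect_equal(f1$idm, 1)
  expect_equal(f1$entropy, 0)
  expect_true(is.na(f1$correlation))
  # two-cell diagonal: cov = 0.25, var = 0.25
  p2 <- diag(c(0.5, 0.5))
  f2 <- haralick_features(manual_glcm(p2))
  expect_equal(f2$asm, 0.5)
  expect_equal(f2$contrast, 0)
  expect_equal(f2$idm, 1)
  expect_equal(f2$entropy, log(2))
  expect_equal(f2$correlation, 1)
  # two-cell anti-diagonal: cov = -0.25
  p3 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f3 <- haralick_features(manual_glcm(p3))
  expect_equal(f3$asm, 0.5)
  expect_equal(f3$contrast, 1)
  expect_equal(f3$idm, 0.5)
  expect_equal(f3$entropy, log(2))
  expect_equal(f3$correlation, -1)
  # an unnormalised matrix violates the contract
  expect_qlus_error(haralick_features(manual_glcm(matrix(0.3, 2, 2))),
                    "qlus_contract_error")
})

test_that("all six features match the brute-force oracle on random frames", {
  set.seed(301)
  for (k in 1:40) {
    fr <- random_frame(16, 16)
    m <- random_mask(16, 16)
    symmetric <- k %% 2 == 0
    offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(0, 1))[k %% 4 + 1, ]
    g <- build_glcm(fr, m, offset = offs, symmetric = symmetric)
    o <- oracle_glcm(fr$pixels, m, offs[1], offs[2], symmetric = symmetric)
    expect_equal(g$p, o$p, tolerance = 1e-14, ignore_attr = TRUE)
    expect_equal(g$n_pairs, o$n_pairs)
    f <- haralick_features(g)
    fo <- oracle_features(o$p)
    for (nm in names(fo)) expect_equal(f[[nm]], fo[[nm]], tolerance = 1e-10)
    expect_equal(mean_grey_value(fr, m), mean(fr$pixels[m]))
  }
})

test_that("feature bounds hold on random inputs", {
  set.seed(302)
  for (k in 1:25) {
    fr <- random_frame(12, 12)
    g <- build_glcm(fr, random_mask(12, 12))
    f <- haralick_features(g)
    expect_true(f$asm > 0 && f$asm <= 1)
    expect_true(f$idm > 0 && f$idm <= 1)
    expect_gte(f$contrast, 0)
    expect_gte(f$entropy, 0)
    expect_lte(f$entropy, log(256^2))
    if (!is.na(f$correlation)) {
      expect_true(abs(f$correlation) <= 1 + 1e-9)
    }
  }
})

test_that("adding a constant moves MGV by that constant and nothing else", {
  set.seed(303)
  fr <- random_frame(16, 16, max_level = 200L)
  m <- random_mask(16, 16)
  k <- 40L
  shifted <- ultrasound_frame(fr$pixels + k, "T001", "LAL", "venue50")
  f0 <- haralick_features(build_glcm(fr, m))
  f1 <- haralick_features(build_glcm(shifted, m))
  expect_equal(mean_grey_value(shifted, m), mean_grey_value(fr, m) + k)
  for (nm in c("asm", "contrast", "correlation", "idm", "entropy")) {
    expect_equal(f1[[nm]], f0[[nm]], tolerance = 1e-10)
  }
})

test_that("diagonal concentration ties contrast, idm and entropy together", {
  fr <- ultrasound_frame(matrix(5L, 6, 6), "s", "LAL", "m")
  f <- haralick_features(build_glcm(fr, matrix(TRUE, 6, 6)))
  expect_equal(f$asm, 1)
  expect_equal(f$contrast, 0)
  expect_equal(f$idm, 1)
  expect_equal(f$entropy, 0)
})

test_that("marginals of a symmetric GLCM coincide", {
  set.seed(304)
  fr <- random_frame(10, 10)
  g <- build_glcm(fr, random_mask(10, 10), symmetric = TRUE)
  px_marg <- rowSums(g$p); py_marg <- colSums(g$p)
  l <- 0:255
  expect_equal(sum(l * px_marg), sum(l * py_marg), tolerance = 1e-12)
  expect_equal(sum((l - sum(l * px_marg))^2 * px_marg),
               sum((l - sum(l * py_marg))^2 * py_marg), tolerance = 1e-12)
})

test_that("config options: coarser levels, asymmetric mode, entropy base", {
  set.seed(305)
  fr <- random_frame(12, 12)
  m <- random_mask(12, 12)
  # re-binned levels against an oracle on the re-binned image
  g8 <- build_glcm(fr, m, levels = 8L)
  o8 <- oracle_glcm(matrix(as.integer(fr$pixels %/% 32L), 12, 12), m,
                    0, 1, levels = 8L)
  expect_equal(g8$p, o8$p, tolerance = 1e-14, ignore_attr = TRUE)
  # asymmetric GLCM
  ga <- build_glcm(fr, m, symmetric = FALSE)
  oa <- oracle_glcm(fr$pixels, m, 0, 1, symmetric = FALSE)
  expect_equal(ga$p, oa$p, tolerance = 1e-14, ignore_attr = TRUE)
  # entropy base conversion
  g <- build_glcm(fr, m)
  expect_equal(haralick_features(g, entropy_base = 2)$entropy,
               haralick_features(g)$entropy / log(2), tolerance = 1e-12)
})

test_that("analyze_frame equals the composition of its parts", {
  fs <- simulate_frame(0.5, seed = 31)
  cfg <- qlus_config()
  row <- analyze_frame(fs$frame, fs$spec, cfg)
  mask <- rasterize_roi(fs$spec, fs$frame$height, fs$frame$width,
                        min_pixels = cfg$min_roi_pixels)
  g <- build_glcm(fs$frame, mask, offset = cfg$offset,
                  symmetric = cfg$symmetric, levels = cfg$levels)
  f <- haralick_features(g, entropy_base = cfg$entropy_base)
  expect_equal(row$mgv, mean_grey_value(fs$frame, mask))
  expect_equal(row$n_roi_pixels, mask$n_pixels)
  expect_equal(row$n_pairs, g$n_pairs)
  for (nm in c("asm", "contrast", "correlation", "idm", "entropy")) {
    expect_equal(row[[nm]], f[[nm]])
  }
  # constant frame through the full composition
  flat <- ultrasound_frame(matrix(42L, 80, 96), "s", "LAL", "m")
  row2 <- analyze_frame(flat, fs$spec, cfg)
  expect_equal(row2$mgv, 42)
  expect_equal(row2$asm, 1)
  expect_true(is.na(row2$correlation))
})
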