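test_that("rho reproduces monotone extremes and the tied-rank oracle", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(8, 6, 4, 2)), -1)
  # ties: against explicit rank-then-Pearson and against stats::cor
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 2)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"))
  set.seed(501)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    a <- sample(1:10, n, replace = TRUE)  # plenty of ties
    b <- sample(1:10, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_rho(a, b), stats::cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("rho is invariant under increasing transforms and antisymmetric", {
  set.seed(502)
  for (k in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r)
    expect_equal(spearman_rho(x, y^3 + 2 * y), r)
    expect_equal(spearman_rho(x, -y), -r)
  }
})

test_that("degenerate correlation inputs raise typed errors", {
  expect_qlus_error(spearman_rho(1:5, rep(3, 5)),
                    "qlus_degenerate_input_error")
  expect_qlus_error(spearman_rho(1:2, 1:2), "qlus_degenerate_input_error")
  expect_qlus_error(spearman_rho(1:4, 1:5), "qlus_shape_error")
  expect_qlus_error(spearman_p(0.5, 2), "qlus_degenerate_input_error")
  expect_qlus_error(rho_ci(1:3, 1:3), "qlus_degenerate_input_error")
})

test_that("p-values: null centre, exact tails, and method agreement", {
  expect_equal(spearman_p(0, 20, method = "t"), 1)
  expect_equal(spearman_p(0, 5, method = "exact"), 1)
  # perfect monotone ranks at n = 5: 2 of 120 permutations are as extreme
  expect_equal(spearman_p(1, 5, method = "exact"), 2 / 120)
  expect_message(p1 <- spearman_p(1, 30, method = "t"), "limiting")
  expect_equal(p1, 0)
  # t vs exact across whole small-n rank spaces: worst-case gaps are
  # 0.077 (n=5), 0.048 (n=6), 0.027 (n=7)
  bounds <- c(`5` = 0.08, `6` = 0.05, `7` = 0.05)
  for (n in 5:7) {
    perms <- qlus:::all_permutations(n)
    rhos <- unique(apply(perms, 1, function(p) spearman_rho(seq_len(n), p)))
    gap <- max(abs(vapply(rhos, function(r) {
      suppressMessages(spearman_p(r, n, "t") - spearman_p(r, n, "exact"))
    }, numeric(1))))
    expect_lte(gap, bounds[[as.character(n)]])
  }
})

test_that("exact permutation p agrees with an in-test enumeration oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(4, 1, 2, 3, 5)
  r <- spearman_rho(x, y)
  # oracle: enumerate all 120 permutations independently
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perm_all(1:5), function(p) stats::cor(1:5, p), numeric(1))
  p_oracle <- mean(abs(rhos) >= abs(r) - 1e-12)
  expect_equal(spearman_p(r, 5, method = "exact"), p_oracle)
})

test_that("Fisher-z intervals stay in [-1,1] and cover at the nominal rate", {
  set.seed(503)
  for (k in 1:10) {
    x <- rnorm(12); y <- x + rnorm(12, 0, 0.3)
    ci <- rho_ci(x, y, method = "fisher")
    expect_true(all(ci >= -1 & ci <= 1))
    expect_lte(ci[1], spearman_rho(x, y))
    expect_gte(ci[2], spearman_rho(x, y))
  }
  # coverage of zero under independence, n = 100, 500 replicates
  set.seed(504)
  cover <- mean(vapply(1:500, function(k) {
    x <- rnorm(100); y <- rnorm(100)
    ci <- rho_ci(x, y, method = "fisher")
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1)))
  expect_gte(cover, 0.92)
})

test_that("bootstrap interval collapses on perfectly monotone data and is seeded", {
  x <- 1:8; y <- (1:8)^2
  ci <- rho_ci(x, y, method = "bootstrap", n_boot = 200, seed = 7)
  expect_equal(ci, c(1, 1))
  set.seed(505)
  a <- rnorm(30); b <- a + rnorm(30)
  ci1 <- rho_ci(a, b, n_boot = 500, seed = 42)
  ci2 <- rho_ci(a, b, n_boot = 500, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] < spearman_rho(a, b) && spearman_rho(a, b) < ci1[2])
})

test_that("strength labels follow the threshold table on |rho|", {
  expect_identical(classify_strength(0.38), "fair")
  expect_identical(classify_strength(-0.54), "moderate")
  expect_identical(classify_strength(0), "weak")
  expect_identical(classify_strength(0.2999), "weak")
  expect_identical(classify_strength(0.30), "fair")
  expect_identical(classify_strength(0.50), "moderate")
  expect_identical(classify_strength(0.70), "strong")
  expect_identical(classify_strength(-1), "strong")
  expect_identical(classify_strength(-0.38), classify_strength(0.38))
  expect_qlus_error(classify_strength(1.2), "qlus_value_error")
})

make_subjects <- function(n = 8, seed = 1) {
  set.seed(seed)
  mgv <- seq(40, 60, length.out = n)
  tibble::tibble(
    subject_id = sprintf("S%02d", 1:n), machine_id = "venue50",
    n_zones_used = 8L,
    mgv = mgv, asm = runif(n, 0, 1e-3), contrast = runif(n, 500, 900),
    correlation = runif(n, 0.3, 0.9), idm = runif(n, 0, 0.2),
    entropy = runif(n, 7, 9),
    osi = 12 - 0.1 * mgv,          # exactly antitone in mgv
    sf_ratio = 5 * mgv)            # exactly monotone in mgv
}

test_that("a noise-free monotone link yields rho = -1 / +1, significant", {
  subj <- make_subjects(8)
  tab <- correlation_table(subj, group_by_machine = FALSE, n_boot = 200)
  cell <- tab[tab$feature == "mgv" & tab$index == "osi", ]
  expect_equal(cell$rho, -1)
  expect_true(cell$significant)
  expect_identical(cell$strength, "strong")
  cell2 <- tab[tab$feature == "mgv" & tab$index == "sf_ratio", ]
  expect_equal(cell2$rho, 1)
  expect_true(cell2$significant)
})

test_that("degenerate and undersized cells are surfaced, not silently dropped", {
  subj <- make_subjects(8)
  subj$entropy <- 5  # constant feature -> degenerate cell
  w <- capture_warnings(tab <- correlation_table(subj,
                                                 group_by_machine = FALSE,
                                                 n_boot = 100))
  expect_true(any(grepl("degenerate", w)))
  cell <- tab[tab$feature == "entropy" & tab$index == "osi", ]
  expect_true(is.na(cell$rho))
  expect_identical(cell$note, "degenerate")
  # machine subgroup with too few subjects is omitted with a warning
  subj2 <- make_subjects(8)
  subj2$machine_id <- c(rep("venue50", 6), rep("venuego", 2))
  w2 <- capture_warnings(tab2 <- correlation_table(subj2, n_boot = 100))
  expect_true(any(grepl("omitted", w2)))
  expect_false(any(tab2$subgroup == "venuego"))
  expect_true(any(tab2$subgroup == "venue50"))
})

test_that("significance flag matches p < 0.05 and BH adjustment is optional", {
  subj <- make_subjects(12, seed = 9)
  tab <- suppressMessages(
    correlation_table(subj, group_by_machine = FALSE, n_boot = 100))
  expect_equal(tab$significant, tab$p_value < 0.05)
  tab_bh <- suppressMessages(
    correlation_table(subj, group_by_machine = FALSE, n_boot = 100,
                      adjust = "BH"))
  expect_true(all(tab_bh$p_value >= tab$p_value - 1e-12))
})

test_that("the wide rendering marks non-significant cells NS", {
  subj <- make_subjects(10, seed = 3)
  subj$asm <- rev(subj$asm)  # scramble any accidental monotonicity
  tab <- suppressMessages(
    correlation_table(subj, group_by_machine = FALSE, n_boot = 100))
  wide <- render_wide_table(tab)
  expect_identical(wide$feature, c("mgv", "asm", "contrast", "correlation",
                                   "idm", "entropy"))
  mgv_cell <- wide[wide$feature == "mgv", 2][[1]]
  expect_match(mgv_cell, "^-1\\.00")
  ns <- tab[!tab$significant, ]
  if (nrow(ns) > 0) {
    col <- paste("overall", ifelse(ns$index[1] == "osi", "OSI", "S/F"))
    expect_identical(wide[wide$feature == ns$feature[1], col][[1]], "NS")
  }
})
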