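#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of average ranks; ties receive their mean rank. The
#' explicit product-moment form is used rather than the tie-free
#' sum-of-squared-rank-differences shortcut, so tied data are handled
#' exactly.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with at least
#'   two distinct values.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    qlus_stop("`x` and `y` must have equal length", "qlus_shape_error")
  }
  if (anyNA(x) || anyNA(y)) {
    qlus_stop("inputs must not contain NA (drop incomplete pairs first)",
              "qlus_value_error")
  }
  n <- length(x)
  if (n < 3L) {
    qlus_stop("need n >= 3 observations", "qlus_degenerate_input_error")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    qlus_stop("constant vector: Spearman correlation undefined",
              "qlus_degenerate_input_error")
  }
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# All permutations of 1..n as an n! x n matrix (n <= 8 kept small on purpose)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, 1L] <- k
    rest <- seq_len(n)[-k]
    block[, -1L] <- matrix(rest[sub], nrow(sub))
    out[[k]] <- block
  }
  do.call(rbind, out)
}

#' Two-sided p-value for a Spearman correlation
#'
#' Default (`method = "auto"`): the exact permutation distribution of rho
#' over all `n!` rank permutations when `n <= 8`, otherwise the
#' t-approximation `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees
#' of freedom. `|rho| = 1` under the t-method returns the limiting p = 0
#' with a message. The exact method enumerates tie-free rank permutations.
#'
#' @param rho Observed Spearman coefficient.
#' @param n Sample size (`>= 3`).
#' @param method `"auto"`, `"t"`, or `"exact"`.
#' @return Two-sided p-value.
#' @export
spearman_p <- function(rho, n, method = c("auto", "t", "exact")) {
  method <- match.arg(method)
  assert_scalar_number(rho, "rho")
  assert_scalar_number(n, "n")
  if (n < 3) {
    qlus_stop("need n >= 3", "qlus_degenerate_input_error")
  }
  if (abs(rho) > 1 + 1e-9) {
    qlus_stop("`rho` must lie in [-1, 1]", "qlus_value_error")
  }
  rho <- max(-1, min(1, rho))
  if (method == "auto") method <- if (n <= 8) "exact" else "t"
  if (method == "exact") {
    if (n > 8) {
      qlus_stop("exact permutation p-value limited to n <= 8",
                "qlus_value_error")
    }
    perms <- all_permutations(as.integer(n))
    ref <- seq_len(n)
    d <- ref - mean(ref)
    ss <- sum(d^2)
    # rho for identity ranks vs each permutation
    rhos <- as.vector((perms %*% d) - mean(ref) * sum(d)) / ss
    return(mean(abs(rhos) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) {
    message("|rho| = 1: t-approximation returns the limiting p-value of 0")
    return(0)
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Confidence interval for a Spearman correlation
#'
#' Default method: seeded bootstrap percentile interval over pair resamples
#' (2000 by default). Alternative: Fisher-z normal approximation
#' `tanh(atanh(rho) +/- z * 1/sqrt(n-3))`, whose bounds always lie in
#' `[-1, 1]`.
#'
#' @param x,y Numeric vectors, `n >= 4`.
#' @param level Confidence level (default 0.95).
#' @param method `"bootstrap"` or `"fisher"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap (ignored by `"fisher"`).
#' @return `c(ci_low, ci_high)`.
#' @export
rho_ci <- function(x, y, level = 0.95, method = c("bootstrap", "fisher"),
                   n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(x)
  if (n != length(y) || n < 4L) {
    qlus_stop("need paired vectors with n >= 4", "qlus_degenerate_input_error")
  }
  alpha <- (1 - level) / 2
  if (method == "fisher") {
    rho <- spearman_rho(x, y)
    if (abs(rho) >= 1) return(c(rho, rho))
    z <- atanh(rho)
    half <- stats::qnorm(1 - alpha) / sqrt(n - 3)
    return(tanh(c(z - half, z + half)))
  }
  rhos <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (length(unique(xb)) < 2L || length(unique(yb)) < 2L) {
        return(NA_real_)
      }
      spearman_rho(xb, yb)
    }, numeric(1))
  })
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) < 2L) {
    qlus_stop("bootstrap produced no usable resamples",
              "qlus_degenerate_input_error")
  }
  unname(stats::quantile(rhos, c(alpha, 1 - alpha)))
}

#' Classify correlation strength
#'
#' Labels by `|rho|` with half-open intervals: weak `< 0.30 <=` fair
#' `< 0.50 <=` moderate `< 0.70 <=` strong.
#'
#' @param rho Spearman coefficient in `[-1, 1]`.
#' @return One of `"weak"`, `"fair"`, `"moderate"`, `"strong"`.
#' @export
classify_strength <- function(rho) {
  assert_scalar_number(rho, "rho")
  if (abs(rho) > 1 + 1e-9) {
    qlus_stop("`rho` must lie in [-1, 1]", "qlus_value_error")
  }
  a <- abs(rho)
  if (a < 0.30) "weak" else if (a < 0.50) "fair" else if (a < 0.70) "moderate" else "strong"
}

#' Correlation table: every Q-LUS feature against every oxygenation index
#'
#' The engine behind the study-style results table: for each feature
#' (mgv, asm, contrast, correlation, idm, entropy), each index (osi,
#' sf_ratio) and each subgroup (overall plus one per ultrasound machine
#' when `group_by_machine`), computes Spearman's rho, a 95% CI, a two-sided
#' p-value, a strength label and a significance flag (p < 0.05). Subjects
#' missing an index (no MAP, so no OSI) or a feature mean are dropped
#' pairwise per cell. Cells with fewer than `min_n` subjects are omitted
#' with a warning; degenerate cells (constant inputs) are kept with `NA`
#' statistics and a note.
#'
#' @param subjects Subject-level table ([subject_table] output).
#' @param group_by_machine Also emit per-machine subgroups?
#' @param ci_method,n_boot Passed to [rho_ci].
#' @param p_method Passed to [spearman_p].
#' @param seed Base seed; each cell's bootstrap uses a seed derived from it.
#' @param min_n Minimum subjects per cell (default 4).
#' @param adjust P-value adjustment across cells: `"none"` (default) or any
#'   [stats::p.adjust] method such as `"BH"`.
#' @param alpha Significance threshold (default 0.05).
#' @return Long-format [tibble::tibble]: feature, index, subgroup, n, rho,
#'   ci_low, ci_high, p_value, strength, significant, note.
#' @export
correlation_table <- function(subjects, group_by_machine = TRUE,
                              ci_method = "bootstrap", n_boot = 2000L,
                              p_method = "auto", seed = 1L, min_n = 4L,
                              adjust = "none", alpha = 0.05) {
  subjects <- as.data.frame(subjects)
  groups <- list(overall = subjects)
  if (group_by_machine) {
    for (mc in sort(unique(subjects$machine_id))) {
      groups[[mc]] <- subjects[subjects$machine_id == mc, ]
    }
  }
  rows <- list()
  cell <- 0L
  for (gname in names(groups)) {
    gd <- groups[[gname]]
    for (feat in QLUS_FEATURES) {
      for (index in c("osi", "sf_ratio")) {
        cell <- cell + 1L
        ok <- !is.na(gd[[feat]]) & !is.na(gd[[index]])
        x <- gd[[feat]][ok]; y <- gd[[index]][ok]
        n <- length(x)
        if (n < min_n) {
          qlus_warn(sprintf(
            "cell %s/%s/%s omitted: %d subject(s), below the minimum of %d",
            feat, index, gname, n, min_n), "qlus_cell_omitted_warning")
          next
        }
        res <- tryCatch({
          rho <- spearman_rho(x, y)
          ci <- rho_ci(x, y, method = ci_method, n_boot = n_boot,
                       seed = derive_seed(seed, cell))
          p <- spearman_p(rho, n, method = p_method)
          list(rho = rho, ci = ci, p = p,
               strength = classify_strength(rho), note = NA_character_)
        }, qlus_degenerate_input_error = function(e) {
          qlus_warn(sprintf("cell %s/%s/%s degenerate: %s",
                            feat, index, gname, conditionMessage(e)),
                    "qlus_degenerate_cell_warning")
          list(rho = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
               strength = NA_character_, note = "degenerate")
        })
        rows[[length(rows) + 1L]] <- tibble::tibble(
          feature = feat, index = index, subgroup = gname, n = n,
          rho = res$rho, ci_low = res$ci[1], ci_high = res$ci[2],
          p_value = res$p, strength = res$strength,
          significant = if (is.na(res$p)) NA else res$p < alpha,
          note = res$note)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none") && nrow(out) > 0) {
    out$p_value <- stats::p.adjust(out$p_value, method = adjust)
    out$significant <- ifelse(is.na(out$p_value), NA, out$p_value < alpha)
  }
  out
}

#' Render the long correlation table in the wide study style
#'
#' One row per feature, one column per (subgroup x index); significant
#' cells show `"rho (ci_low, ci_high)"`, non-significant cells show
#' `"NS"`, omitted or degenerate cells show `""`.
#'
#' @param results [correlation_table] output.
#' @param digits Decimals for rho and CI bounds.
#' @return [tibble::tibble] with a `feature` column plus one column per
#'   subgroup/index combination.
#' @export
render_wide_table <- function(results, digits = 2) {
  results <- as.data.frame(results)
  subgroups <- unique(results$subgroup)
  fmt <- function(r) {
    if (is.na(r$rho) || is.na(r$significant)) return("")
    if (!r$significant) return("NS")
    sprintf(paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)"),
            r$rho, r$ci_low, r$ci_high)
  }
  out <- tibble::tibble(feature = QLUS_FEATURES)
  for (sg in subgroups) {
    for (index in c("osi", "sf_ratio")) {
      colname <- paste(sg, toupper(sub("sf_ratio", "S/F", index)), sep = " ")
      colname <- sub("OSI", "OSI", colname)
      vals <- vapply(QLUS_FEATURES, function(f) {
        row <- results[results$feature == f & results$index == index &
                         results$subgroup == sg, , drop = FALSE]
        if (nrow(row) == 0) "" else fmt(row[1, ])
      }, character(1))
      out[[colname]] <- unname(vals)
    }
  }
  out
}
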