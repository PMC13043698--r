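# Independent brute-force oracles. These deliberately share no code with
# the package: the GLCM oracle enumerates pixel pairs with explicit loops,
# the ROI oracle evaluates the membership predicate per pixel with
# stats::approx interpolation, and the Spearman oracle goes through
# rank-then-Pearson by hand.

oracle_glcm <- function(px, mask, dr, dc, levels = 256L, symmetric = TRUE) {
  h <- nrow(px); w <- ncol(px)
  P <- matrix(0, levels, levels)
  n_pairs <- 0L
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
          mask[r, c] && mask[r2, c2]) {
        i <- px[r, c] + 1L; j <- px[r2, c2] + 1L
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
        n_pairs <- n_pairs + 1L
      }
    }
  }
  list(p = P / sum(P), n_pairs = n_pairs)
}

oracle_features <- function(P, entropy_base = exp(1)) {
  lev <- nrow(P)
  l <- 0:(lev - 1L)
  D2 <- outer(l, l, function(i, j) (i - j)^2)
  IJ <- outer(l, l)
  px_marg <- rowSums(P); py_marg <- colSums(P)
  mu_x <- sum(l * px_marg); mu_y <- sum(l * py_marg)
  sd_x <- sqrt(sum((l - mu_x)^2 * px_marg))
  sd_y <- sqrt(sum((l - mu_y)^2 * py_marg))
  corr <- if (sd_x * sd_y < .Machine$double.eps) NA_real_ else
    (sum(IJ * P) - mu_x * mu_y) / (sd_x * sd_y)
  list(asm = sum(P^2),
       contrast = sum(D2 * P),
       correlation = corr,
       idm = sum(P / (1 + D2)),
       entropy = -sum(ifelse(P > 0, P * log(P, base = entropy_base), 0)))
}

oracle_roi_mask <- function(spec, height, width) {
  m <- matrix(FALSE, height, width)
  v <- spec$pleural_polyline
  for (c0 in 0:(width - 1L)) {
    if (c0 < spec$lateral_bounds[1] || c0 >= spec$lateral_bounds[2]) next
    pr <- floor(stats::approx(v[, 1], v[, 2], xout = c0)$y + 0.5)
    for (r0 in 0:(height - 1L)) {
      if (r0 >= pr && r0 < pr + spec$depth_px) m[r0 + 1L, c0 + 1L] <- TRUE
    }
  }
  m
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# random test fixtures -------------------------------------------------------

random_frame <- function(h = 16L, w = 16L, max_level = 255L,
                         zone = "LAL") {
  px <- matrix(sample(0:max_level, h * w, replace = TRUE), h, w)
  ultrasound_frame(px, "T001", zone, "venue50")
}

# mask with a guaranteed horizontal pair
random_mask <- function(h = 16L, w = 16L, p_on = 0.6) {
  m <- matrix(stats::runif(h * w) < p_on, h, w)
  m[1, 1:2] <- TRUE
  m
}

random_roi_spec <- function(height, width) {
  depth <- sample(5:15, 1)
  n_vert <- sample(2:5, 1)
  vcols <- sort(sample(0:(width - 1L), n_vert))
  vcols[1] <- 0L; vcols[n_vert] <- width - 1L
  vcols <- unique(vcols)
  if (length(vcols) < 2) vcols <- c(0L, width - 1L)
  vrows <- sample(0:(height - depth - 1L), length(vcols), replace = TRUE)
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 v
  c0 <- pick(0:(width - 2L))
  c1 <- pick((c0 + 1L):width)
  roi_spec(cbind(vcols, vrows), c(c0, c1), depth_px = depth)
}

# minimal hand-assembled GLCM object for closed-form feature checks
manual_glcm <- function(p, symmetric = TRUE) {
  structure(list(p = p, levels = nrow(p), offset = c(0L, 1L),
                 symmetric = symmetric, n_pairs = 1),
            class = "glcm")
}

expect_qlus_error <- function(expr, class) {
  expect_error(expr, class = class)
}
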