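# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (pixel enumeration, direct sums) so they
# stay independent of the implementation they check.

# Rasterize a filled disc / rectangle / ellipse into a label matrix.
raster_disc <- function(r, pad = 3L, label = 1L) {
  n <- 2L * (r + pad) + 1L
  cx <- r + pad + 1L
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - cx)^2 + (j - cx)^2 <= r^2) m[i, j] <- label
    }
  }
  m
}

raster_rect <- function(w, h, pad = 3L, label = 1L) {
  m <- matrix(0L, h + 2L * pad, w + 2L * pad)
  m[(pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- label
  m
}

raster_ellipse <- function(a, b, theta = 0, pad = 3L, label = 1L) {
  n <- 2L * (ceiling(a) + pad) + 1L
  c0 <- ceiling(a) + pad + 1L
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- j - c0; y <- i - c0
      u <- x * cos(theta) + y * sin(theta)
      v <- -x * sin(theta) + y * cos(theta)
      if ((u / a)^2 + (v / b)^2 <= 1) m[i, j] <- label
    }
  }
  m
}

# A nucleus mask concentric with a single-object cell mask: keep pixels
# whose distance to the object's centroid is below a fraction of its radius.
shrink_mask <- function(mask, frac = 0.5) {
  px <- which(mask > 0, arr.ind = TRUE)
  ctr <- colMeans(px)
  d <- sqrt((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2)
  keep <- px[d <= stats::quantile(d, frac), , drop = FALSE]
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[keep] <- mask[keep]
  out
}

# Pixel-enumeration oracles.
oracle_area <- function(mask, label = 1L) sum(mask == label)
oracle_centroid <- function(mask, label = 1L) {
  px <- which(mask == label, arr.ind = TRUE)
  c(x = mean(px[, 2]), y = mean(px[, 1]))
}
oracle_bbox <- function(mask, label = 1L) {
  px <- which(mask == label, arr.ind = TRUE)
  c(w = diff(range(px[, 2])) + 1L, h = diff(range(px[, 1])) + 1L)
}
oracle_extent <- function(mask, label = 1L) {
  bb <- oracle_bbox(mask, label)
  oracle_area(mask, label) / (bb[["w"]] * bb[["h"]])
}
# Second-moment axis lengths by direct enumeration (with the 1/12 pixel term).
oracle_axes <- function(mask, label = 1L) {
  px <- which(mask == label, arr.ind = TRUE)
  x <- px[, 2]; y <- px[, 1]; n <- length(x)
  vxx <- sum((x - mean(x))^2) / n + 1 / 12
  vyy <- sum((y - mean(y))^2) / n + 1 / 12
  vxy <- sum((x - mean(x)) * (y - mean(y))) / n
  ev <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2, 2),
              symmetric = TRUE, only.values = TRUE)$values
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}
# Direct-sum Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Adjusted Rand index by direct contingency-table computation.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

extract_single <- function(cell_mask, nucleus_mask, ...) {
  suppressMessages(extract_features(cell_mask, nucleus_mask, ...))
}

# Small feature table fixture reused by clustering/profile tests.
small_fixture <- function(n = 600, seed = 42) {
  generate_population(n_cells = n, seed = seed)
}
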