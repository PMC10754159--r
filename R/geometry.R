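# Internal planar-geometry helpers. Polygons are n x 2 matrices (x, y),
# implicitly closed (last vertex connects back to the first).

poly_close_cross <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  list(x = x, y = y, x2 = x2, y2 = y2, cross = x * y2 - x2 * y)
}

poly_signed_area <- function(poly) sum(poly_close_cross(poly)$cross) / 2

poly_area <- function(poly) abs(poly_signed_area(poly))

poly_perimeter <- function(poly) {
  p <- poly_close_cross(poly)
  sum(sqrt((p$x2 - p$x)^2 + (p$y2 - p$y)^2))
}

poly_centroid <- function(poly) {
  p <- poly_close_cross(poly)
  a <- sum(p$cross) / 2
  c(sum((p$x + p$x2) * p$cross), sum((p$y + p$y2) * p$cross)) / (6 * a)
}

# Covariance of the uniform lamina over the polygon interior (2 x 2),
# via Green's-theorem second moments.
poly_cov <- function(poly) {
  if (poly_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  p <- poly_close_cross(poly)
  a <- sum(p$cross) / 2
  cx <- sum((p$x + p$x2) * p$cross) / (6 * a)
  cy <- sum((p$y + p$y2) * p$cross) / (6 * a)
  ixx <- sum(p$cross * (p$y^2 + p$y * p$y2 + p$y2^2)) / 12   # integral of y^2
  iyy <- sum(p$cross * (p$x^2 + p$x * p$x2 + p$x2^2)) / 12   # integral of x^2
  ixy <- sum(p$cross * (p$x * p$y2 + 2 * p$x * p$y + 2 * p$x2 * p$y2 + p$x2 * p$y)) / 24
  vxx <- iyy / a - cx^2
  vyy <- ixx / a - cy^2
  vxy <- ixy / a - cx * cy
  matrix(c(vxx, vxy, vxy, vyy), 2, 2)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

convex_hull <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[idx, , drop = FALSE]
}

# Maximum caliper (Feret) diameter: the hull diameter.
feret_max <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(0)
  d2 <- as.matrix(stats::dist(hull))
  max(d2)
}

# Minimum caliper width: min over hull edges of the farthest vertex distance
# to the edge's supporting line (rotating-calipers width).
feret_min <- function(hull) {
  n <- nrow(hull)
  if (n <= 1) return(0)
  if (n == 2) return(0)
  widths <- vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    max(abs((hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]))
  }, numeric(1))
  min(widths)
}

# Second-moment axis lengths (skimage/CellProfiler convention: the axis
# lengths of the ellipse with matching normalized second moments).
axis_lengths_from_cov <- function(v) {
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

eccentricity_from_cov <- function(v) {
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# The 14 per-compartment shape parameters from a simple polygon.
# Bounding box for `extent` is the axis-aligned box of the vertices.
shape_features_polygon <- function(poly) {
  a <- poly_area(poly)
  p <- poly_perimeter(poly)
  hull <- convex_hull(poly)
  ca <- poly_area(hull)
  v <- poly_cov(poly)
  ax <- axis_lengths_from_cov(v)
  bbox <- (max(poly[, 1]) - min(poly[, 1])) * (max(poly[, 2]) - min(poly[, 2]))
  fmax <- feret_max(hull)
  fmin <- feret_min(hull)
  c(
    area = a,
    perimeter = p,
    form_factor = 4 * pi * a / p^2,
    eccentricity = eccentricity_from_cov(v),
    solidity = min(1, a / ca),
    extent = min(1, a / bbox),
    major_axis_length = ax[["major"]],
    minor_axis_length = ax[["minor"]],
    aspect_ratio = ax[["major"]] / ax[["minor"]],
    equivalent_diameter = 2 * sqrt(a / pi),
    max_feret = fmax,
    min_feret = fmin,
    compactness = p^2 / (4 * pi * a),
    convex_area = ca
  )
}

# Parametric cell outline: an ellipse of given area and aspect ratio whose
# boundary radius is modulated by one low-order radial harmonic
# (1 + delta * cos(m t + phase)); delta > 0 lowers solidity. The polygon is
# rescaled so its area matches `area` exactly, then rotated and translated.
ellipse_harmonic_polygon <- function(area, aspect_ratio, delta = 0, m = 5L,
                                     phase = 0, theta = 0, center = c(0, 0),
                                     n_vertices = 96L) {
  a <- sqrt(area * aspect_ratio / pi)
  b <- sqrt(area / (pi * aspect_ratio))
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  mod <- 1 + delta * cos(m * t + phase)
  x <- a * cos(t) * mod
  y <- b * sin(t) * mod
  poly <- cbind(x, y)
  s <- sqrt(area / poly_area(poly))
  poly <- poly * s
  if (theta != 0) {
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    poly <- poly %*% t(rot)
  }
  poly[, 1] <- poly[, 1] + center[1]
  poly[, 2] <- poly[, 2] + center[2]
  poly
}

# Solidity of the harmonic shape as a function of delta, for calibration.
harmonic_solidity <- function(delta, aspect_ratio, m = 5L, n_vertices = 256L) {
  poly <- ellipse_harmonic_polygon(1000, aspect_ratio, delta = delta, m = m,
                                   n_vertices = n_vertices)
  poly_area(poly) / poly_area(convex_hull(poly))
}

# Monotone map from target solidity to harmonic amplitude, via a calibration
# grid computed once per (aspect ratio, m).
delta_for_solidity <- function(target, aspect_ratio, m = 5L,
                               delta_max = 0.2) {
  grid <- seq(0, delta_max, length.out = 21L)
  sol <- vapply(grid, harmonic_solidity, numeric(1),
                aspect_ratio = aspect_ratio, m = m)
  # sol decreases with delta; clamp outside the attainable range
  out <- stats::approx(x = rev(sol), y = rev(grid), xout = target,
                       yleft = delta_max, yright = 0, ties = "ordered")$y
  out
}
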