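#' Names of the 33 morphology parameters
#'
#' Fourteen size/shape parameters per compartment (cell, nucleus): area,
#' perimeter, form factor (4*pi*A/P^2), eccentricity, solidity, extent,
#' major/minor axis length, aspect ratio, equivalent diameter, max/min Feret
#' diameter, compactness (P^2/(4*pi*A)), convex area; plus five
#' cross-compartment parameters: nucleus/cell area and perimeter ratios,
#' centroid displacement, normalized centroid displacement, and cytoplasm
#' area. Orientation is deliberately excluded: every parameter is positive
#' (or a bounded ratio), which the downstream log normalization requires.
#'
#' @return Character vector of length 33.
#' @export
morph_feature_names <- function() {
  per <- c("area", "perimeter", "form_factor", "eccentricity", "solidity",
           "extent", "major_axis_length", "minor_axis_length", "aspect_ratio",
           "equivalent_diameter", "max_feret", "min_feret", "compactness",
           "convex_area")
  c(paste0("cell_", per), paste0("nucleus_", per),
    "nucleus_cell_area_ratio", "nucleus_cell_perimeter_ratio",
    "centroid_displacement", "normalized_centroid_displacement",
    "cytoplasm_area")
}

# Outer-contour perimeter: the ordered boundary-pixel path is smoothed with
# a 3-point moving average (removes staircase anisotropy), its polyline
# length taken, plus 2*pi*0.5 for the half-pixel offset between pixel
# centers and the outer crack boundary. Falls back to calibrated chain-code
# weights (Vossepoel-Smeulders) for contours too short to smooth.
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(4 * 0.948)  # single pixel: its crack boundary
  if (n < 8) {
    nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
    step2 <- rowSums((nxt - contour)^2)
    return(sum(ifelse(step2 > 1.5, 1.340, 0.948) * (step2 > 0)))
  }
  w <- 1L
  sm <- vapply(1:2, function(j) {
    x <- contour[, j]
    stats::filter(c(x[(n - w + 1):n], x, x[1:w]),
                  rep(1 / (2 * w + 1), 2 * w + 1))[(w + 1):(n + w)]
  }, numeric(n))
  d <- sqrt(rowSums((sm - rbind(sm[-1, , drop = FALSE], sm[1, , drop = FALSE]))^2))
  sum(d) + pi
}

# Shape parameters for one labelled region given its pixel coordinates
# (x = column, y = row, pixel centers). Boundary ordering comes from
# EBImage::ocontour on the cropped binary patch.
raster_shape_features <- function(px, py) {
  n <- length(px)
  x0 <- min(px); y0 <- min(py)
  w <- max(px) - x0 + 1L; h <- max(py) - y0 + 1L
  patch <- matrix(0L, w, h)  # EBImage images are [x, y]
  patch[cbind(px - x0 + 1L, py - y0 + 1L)] <- 1L
  oc <- EBImage::ocontour(patch)[[1]]
  perim <- contour_perimeter(oc)

  # convex hull of the boundary-pixel centers; the convex area is the pixel
  # count of the filled hull via Pick's theorem (A = I + B/2 - 1, so
  # pixels = A_polygon + B/2 + 1), consistent with `area` as a pixel count
  bx <- oc[, 1] + x0; by <- oc[, 2] + y0
  hull <- convex_hull(cbind(bx, by))
  b_lattice <- {
    nh <- nrow(hull)
    nxt <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
    dx <- abs(nxt[, 1] - hull[, 1]); dy <- abs(nxt[, 2] - hull[, 2])
    sum(mapply(function(a, b) ifelse(a == 0 && b == 0, 0,
                                     gcd_int(a, b)), dx, dy))
  }
  carea <- if (nrow(hull) < 3) length(px) else poly_area(hull) + b_lattice / 2 + 1
  # Feret diameters over the pixel outer corners of the hull points
  corners <- cbind(c(hull[, 1] - 0.5, hull[, 1] + 0.5, hull[, 1] - 0.5, hull[, 1] + 0.5),
                   c(hull[, 2] - 0.5, hull[, 2] - 0.5, hull[, 2] + 0.5, hull[, 2] + 0.5))
  feret_hull <- convex_hull(corners)

  # second moments of pixel centers, plus the 1/12 per-pixel term so a
  # filled rectangle matches its continuous counterpart exactly
  vxx <- sum((px - mean(px))^2) / n + 1 / 12
  vyy <- sum((py - mean(py))^2) / n + 1 / 12
  vxy <- sum((px - mean(px)) * (py - mean(py))) / n
  v <- matrix(c(vxx, vxy, vxy, vyy), 2, 2)
  ax <- axis_lengths_from_cov(v)

  area <- n
  c(
    area = area,
    perimeter = perim,
    form_factor = 4 * pi * area / perim^2,
    eccentricity = eccentricity_from_cov(v),
    solidity = min(1, area / carea),
    extent = area / (as.numeric(w) * h),
    major_axis_length = ax[["major"]],
    minor_axis_length = ax[["minor"]],
    aspect_ratio = ax[["major"]] / ax[["minor"]],
    equivalent_diameter = 2 * sqrt(area / pi),
    max_feret = feret_max(feret_hull),
    min_feret = feret_min(feret_hull),
    compactness = perim^2 / (4 * pi * area),
    convex_area = carea
  )
}

# Pixel index lists per label of an integer label mask.
label_pixels <- function(mask) {
  idx <- which(mask > 0)
  if (!length(idx)) return(list())
  labs <- mask[idx]
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  split(data.frame(x = cols, y = rows), labs)
}

# Pair nucleus labels with cell labels by maximal pixel overlap; ties go to
# the smaller cell label. Returns tibble(nucleus_label, cell_label, overlap).
pair_labels <- function(cell_mask, nucleus_mask) {
  sel <- nucleus_mask > 0 & cell_mask > 0
  if (!any(sel)) {
    return(tibble::tibble(nucleus_label = integer(), cell_label = integer(),
                          overlap = integer()))
  }
  ov <- dplyr::count(
    tibble::tibble(nucleus_label = nucleus_mask[sel], cell_label = cell_mask[sel]),
    .data$nucleus_label, .data$cell_label, name = "overlap"
  )
  ov |>
    dplyr::arrange(.data$nucleus_label, dplyr::desc(.data$overlap), .data$cell_label) |>
    dplyr::distinct(.data$nucleus_label, .keep_all = TRUE)
}

#' Extract the 33 morphology parameters from paired label masks
#'
#' Computes the per-compartment and cross-compartment size/shape parameters
#' for every nucleus/cell pair found in a pair of integer label masks
#' (`0` = background). Nuclei are paired to cells by maximal pixel overlap
#' (identical labels in synthetic masks); nuclei without any overlapping
#' cell are flagged and excluded, with a message. If an intensity image is
#' supplied, the mean normalized nuclear intensity (`gh2ax`) is appended.
#'
#' Accepts either two label matrices or a `morph_masks` object from
#' [generate_population()] (all fields are processed and ground-truth
#' metadata is carried through).
#'
#' @param cell_mask Integer label matrix, or a `morph_masks` object.
#' @param nucleus_mask Integer label matrix (ignored for `morph_masks`).
#' @param intensity Optional intensity image congruent with the masks.
#' @param bit_depth Bit depth of `intensity` (8, 12 or 16).
#' @param metadata Optional tibble with one row per cell label (must contain
#'   a `label` column) to join onto the result.
#' @return A tibble with one row per measured cell: `label`, the 33
#'   parameters of [morph_feature_names()], and `gh2ax` when `intensity`
#'   is given.
#' @export
extract_features <- function(cell_mask, nucleus_mask = NULL, intensity = NULL,
                             bit_depth = 16L, metadata = NULL) {
  if (inherits(cell_mask, "morph_masks")) {
    msk <- cell_mask
    out <- purrr::map2_dfr(msk$fields, seq_along(msk$fields), function(f, i) {
      ft <- extract_features(f$cell, f$nucleus, intensity = f$damage,
                             bit_depth = 16L)
      ft$field <- i
      ft
    })
    return(dplyr::inner_join(msk$cells, out, by = c("field", "label")))
  }

  stopifnot(is.matrix(cell_mask), is.matrix(nucleus_mask))
  if (!all(dim(cell_mask) == dim(nucleus_mask))) {
    stop("cell and nucleus masks have different dimensions")
  }
  if (!is.null(intensity) && !all(dim(intensity) == dim(cell_mask))) {
    stop("intensity image and masks have different dimensions")
  }

  cells_px <- label_pixels(cell_mask)
  nucs_px <- label_pixels(nucleus_mask)
  pairs <- pair_labels(cell_mask, nucleus_mask)

  orphan <- setdiff(names(nucs_px), as.character(pairs$nucleus_label))
  if (length(orphan)) {
    message(length(orphan), " nucleus label(s) without an overlapping cell ",
            "were flagged and excluded: ", paste(orphan, collapse = ", "))
  }

  rows <- purrr::pmap(pairs, function(nucleus_label, cell_label, overlap) {
    cpx <- cells_px[[as.character(cell_label)]]
    npx <- nucs_px[[as.character(nucleus_label)]]
    if (is.null(cpx) || is.null(npx)) return(NULL)
    fc <- raster_shape_features(cpx$x, cpx$y)
    fn <- raster_shape_features(npx$x, npx$y)
    disp <- sqrt((mean(cpx$x) - mean(npx$x))^2 + (mean(cpx$y) - mean(npx$y))^2)
    vec <- c(
      stats::setNames(fc, paste0("cell_", names(fc))),
      stats::setNames(fn, paste0("nucleus_", names(fn))),
      nucleus_cell_area_ratio = unname(fn["area"] / fc["area"]),
      nucleus_cell_perimeter_ratio = unname(fn["perimeter"] / fc["perimeter"]),
      centroid_displacement = disp,
      normalized_centroid_displacement = disp / unname(fc["equivalent_diameter"]),
      cytoplasm_area = max(0, unname(fc["area"] - fn["area"]))
    )
    row <- tibble::as_tibble_row(vec)
    row$label <- cell_label
    if (!is.null(intensity)) {
      row$gh2ax <- mean(intensity[cbind(npx$y, npx$x)]) / (2^bit_depth - 1)
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("no measurable nucleus/cell pairs found in the masks")
  out <- dplyr::relocate(out, "label")
  if (!is.null(metadata)) out <- dplyr::left_join(metadata, out, by = "label")
  out
}

#' Mean normalized nuclear intensity (gamma-H2AX content)
#'
#' Sums the damage-channel pixel values over the nucleus, normalized to the
#' `[0, 1]` range of the stated bit depth, and divides by the nuclear pixel
#' area — i.e. the mean normalized nuclear intensity.
#'
#' @param intensity Nonnegative integer intensity matrix.
#' @param nucleus_region Logical matrix (or 0/1 matrix) marking nucleus
#'   pixels, congruent with `intensity`.
#' @param bit_depth One of 8, 12, 16.
#' @return A single value in `[0, 1]`.
#' @export
#' @examples
#' img <- matrix(0L, 8, 8); img[3:6, 3:6] <- 65535L
#' nuc <- matrix(FALSE, 8, 8); nuc[3:6, 3:6] <- TRUE
#' quantify_gh2ax(img, nuc)  # 1
quantify_gh2ax <- function(intensity, nucleus_region, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
  if (!all(dim(intensity) == dim(nucleus_region))) {
    stop("intensity image and nucleus mask have different dimensions")
  }
  sel <- nucleus_region > 0
  if (!any(sel)) stop("empty nucleus region")
  vals <- intensity[sel]
  maxval <- 2^bit_depth - 1
  if (any(vals < 0) || any(vals > maxval)) {
    stop("pixel values outside [0, 2^bit_depth - 1]; wrong bit_depth?")
  }
  sum(vals / maxval) / sum(sel)
}
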