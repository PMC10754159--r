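test_that("axis-aligned squares give closed-form pixel counts", {
  cell <- raster_rect(10, 10)
  nuc <- matrix(0L, nrow(cell), ncol(cell))
  nuc[7:10, 7:10] <- 1L  # 4x4 nucleus centered in the 10x10 cell
  ft <- extract_single(cell, nuc)
  expect_equal(nrow(ft), 1)
  expect_setequal(setdiff(names(ft), c("label", "gh2ax")), morph_feature_names())
  expect_equal(ft$cell_area, 100)
  expect_equal(ft$cell_extent, 1.0)
  expect_equal(ft$cell_solidity, 1.0)
  expect_equal(ft$nucleus_area, 16)
  expect_equal(ft$cytoplasm_area, 84)
  expect_equal(ft$nucleus_cell_area_ratio, 0.16)
  expect_equal(ft$centroid_displacement, 0, tolerance = 1e-12)
})

test_that("a rasterized disc has near-unit form factor and aspect ratio", {
  cell <- raster_disc(20)
  nuc <- shrink_mask(cell, 0.4)
  ft <- extract_single(cell, nuc)
  expect_gt(ft$cell_form_factor, 0.95)
  expect_lt(ft$cell_form_factor, 1.05)
  expect_gte(ft$cell_aspect_ratio, 1.0)
  expect_lt(ft$cell_aspect_ratio, 1.05)
  expect_equal(ft$cell_area, oracle_area(cell))
  expect_equal(ft$cell_max_feret, 2 * 20, tolerance = 0.05)
})

test_that("an elongated rectangle recovers its aspect ratio from moments", {
  cell <- raster_rect(40, 10)
  nuc <- raster_rect(40, 10) * 0L
  nuc[6:11, 20:29] <- 1L
  ft <- extract_single(cell, nuc)
  expect_equal(ft$cell_aspect_ratio, 4, tolerance = 0.05)
  ax <- oracle_axes(cell)
  expect_equal(ft$cell_major_axis_length, ax[["major"]], tolerance = 1e-9)
  expect_equal(ft$cell_minor_axis_length, ax[["minor"]], tolerance = 1e-9)
  expect_equal(ft$cell_major_axis_length / ft$cell_minor_axis_length, 4,
               tolerance = 0.05)
  expect_equal(ft$cell_extent, 1.0)
  expect_equal(ft$cell_min_feret, 10, tolerance = 0.1)
  expect_equal(ft$cell_max_feret, sqrt(40^2 + 10^2), tolerance = 0.5)
})

test_that("feature vector has exactly 33 parameters satisfying invariants", {
  set.seed(31)
  for (shape in list(raster_disc(12), raster_ellipse(18, 8, theta = 0.7),
                     raster_rect(25, 14))) {
    nuc <- shrink_mask(shape, 0.4)
    ft <- extract_single(shape, nuc)
    feats <- ft[morph_feature_names()]
    expect_length(feats, 33)
    expect_true(all(is.finite(unlist(feats))))
    for (comp in c("cell_", "nucleus_")) {
      expect_gt(ft[[paste0(comp, "area")]], 0)
      expect_gt(ft[[paste0(comp, "perimeter")]], 0)
      s <- ft[[paste0(comp, "solidity")]]
      expect_true(s > 0 && s <= 1)
      e <- ft[[paste0(comp, "extent")]]
      expect_true(e > 0 && e <= 1)
      expect_gte(ft[[paste0(comp, "aspect_ratio")]], 1)
      expect_lte(ft[[paste0(comp, "form_factor")]], 1.06)
    }
    expect_true(ft$nucleus_cell_area_ratio > 0 && ft$nucleus_cell_area_ratio < 1)
    expect_gte(ft$cytoplasm_area, 0)
  }
})

test_that("area, extent, centroid and moments match the pixel-enumeration oracle", {
  shapes <- list(raster_disc(9), raster_ellipse(15, 6, theta = 0.4),
                 raster_rect(18, 7))
  for (cell in shapes) {
    nuc <- shrink_mask(cell, 0.5)
    ft <- extract_single(cell, nuc)
    expect_identical(ft$cell_area, as.numeric(oracle_area(cell)))
    expect_equal(ft$cell_extent, oracle_extent(cell), tolerance = 1e-12)
    ax <- oracle_axes(cell)
    expect_equal(ft$cell_major_axis_length, ax[["major"]], tolerance = 1e-9)
    cn <- oracle_centroid(nuc); cc <- oracle_centroid(cell)
    expect_equal(ft$centroid_displacement,
                 sqrt(sum((cn - cc)^2)), tolerance = 1e-9)
  }
})

test_that("features are covariant under integer dilation", {
  base_r <- 30
  small <- raster_disc(base_r)
  big <- raster_disc(2L * base_r)
  nuc_s <- shrink_mask(small, 0.4); nuc_b <- shrink_mask(big, 0.4)
  fs <- extract_single(small, nuc_s)
  fb <- extract_single(big, nuc_b)
  expect_equal(fb$cell_area / fs$cell_area, 4, tolerance = 0.02)
  expect_equal(fb$cell_perimeter / fs$cell_perimeter, 2, tolerance = 0.02)
  expect_equal(fb$cell_major_axis_length / fs$cell_major_axis_length, 2,
               tolerance = 0.02)
  for (f in c("cell_form_factor", "cell_solidity", "cell_extent",
              "cell_aspect_ratio")) {
    expect_equal(fb[[f]], fs[[f]], tolerance = 0.02)
  }
})

test_that("features are invariant under rotation", {
  # 90 degree rotation: exact for scale-free descriptors
  cell <- raster_ellipse(16, 7, theta = 0)
  cell90 <- t(cell)[, rev(seq_len(nrow(cell)))]  # rotate the matrix
  f0 <- extract_single(cell, shrink_mask(cell, 0.4))
  f90 <- extract_single(cell90, shrink_mask(cell90, 0.4))
  for (f in c("cell_area", "cell_perimeter", "cell_solidity", "cell_extent",
              "cell_aspect_ratio", "cell_eccentricity", "cell_max_feret")) {
    expect_equal(f0[[f]], f90[[f]], tolerance = 1e-9, label = f)
  }
  # arbitrary rotation: within 3% for shapes >= 30 px across
  big0 <- raster_ellipse(24, 12, theta = 0)
  f0 <- extract_single(big0, shrink_mask(big0, 0.4))
  f45 <- local({
    m <- raster_ellipse(24, 12, theta = pi / 5)
    extract_single(m, shrink_mask(m, 0.4))
  })
  for (f in c("cell_area", "cell_form_factor", "cell_solidity",
              "cell_aspect_ratio", "cell_eccentricity", "cell_major_axis_length")) {
    expect_equal(f45[[f]], f0[[f]], tolerance = 0.03, label = f)
  }
})

test_that("nuclei disjoint from every cell are flagged and excluded", {
  cell <- raster_rect(10, 10, pad = 10)
  nuc <- matrix(0L, nrow(cell), ncol(cell))
  nuc[12:15, 12:15] <- 1L   # inside the cell
  nuc[2:4, 2:4] <- 2L       # in background: no overlapping cell
  expect_message(ft <- extract_features(cell, nuc), "without an overlapping cell")
  expect_equal(nrow(ft), 1)
})

test_that("nucleus-cell pairing follows maximal overlap with smallest-id ties", {
  cell <- matrix(0L, 20, 20)
  cell[2:10, 2:10] <- 1L
  cell[2:10, 12:19] <- 2L
  nuc <- matrix(0L, 20, 20)
  nuc[4:8, 7:14] <- 5L  # overlaps cell 1 by 5x4=20 px, cell 2 by 5x3=15 px
  ft <- extract_single(cell, nuc)
  expect_equal(ft$label, 1)
})

test_that("gamma-H2AX quantification matches its closed-form cases", {
  nuc <- matrix(FALSE, 10, 10); nuc[3:7, 3:6] <- TRUE
  img_sat <- matrix(0L, 10, 10); img_sat[nuc] <- 65535L
  expect_equal(quantify_gh2ax(img_sat, nuc, 16L), 1.0)
  expect_equal(quantify_gh2ax(matrix(0L, 10, 10), nuc, 16L), 0.0)
  img_half <- matrix(0L, 10, 10)
  sel <- which(nuc)
  img_half[sel[seq_len(10)]] <- 65535L  # half of the 20 nucleus pixels
  expect_equal(quantify_gh2ax(img_half, nuc, 16L), 0.5)
  expect_error(quantify_gh2ax(img_sat, nuc, 8L), "bit_depth")
  expect_error(quantify_gh2ax(img_sat, matrix(FALSE, 10, 10)), "empty nucleus")
})
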