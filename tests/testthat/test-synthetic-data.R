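test_that("degenerate mixtures, determinism and fraction validation behave", {
  st <- subtype_template()
  one <- condition_spec("only3", "control", c(0, 0, 1, rep(0, 7)))
  cells <- generate_population(st, one, n_cells = 50, seed = 2)
  expect_true(all(cells$subtype_id == 3L))
  expect_equal(nrow(cells), 50)

  again <- generate_population(st, one, n_cells = 50, seed = 2)
  expect_identical(cells, again)

  expect_error(condition_spec("bad", "low", rep(0.2, 10)), "sum to 1")
  expect_error(condition_spec("bad", "low", c(-0.1, 1.1, rep(0, 8))), "nonnegative")
})

test_that("empirical subtype fractions respect binomial bounds at large n", {
  two <- condition_spec("5050", "control", c(0.5, 0.5, rep(0, 8)))
  cells <- generate_population(subtype_template(), two, n_cells = 10000,
                               seed = 6)
  phat <- mean(cells$subtype_id == 1L)
  half_width <- stats::qnorm(0.995) * sqrt(0.25 / 10000)
  expect_lt(abs(phat - 0.5), half_width)
})

test_that("mask output keeps nuclei inside cells with consistent labels", {
  st <- subtype_template()
  st$cell_area_mean <- st$cell_area_mean / 4
  msk <- generate_population(st, n_cells = 60, seed = 8, output = "masks",
                             field = field_geometry(size = 512))
  for (f in msk$fields) {
    nuc_px <- f$nucleus > 0
    expect_true(all(f$cell[nuc_px] == f$nucleus[nuc_px]))
    labs_cell <- sort(unique(f$cell[f$cell > 0]))
    labs_nuc <- sort(unique(f$nucleus[nuc_px]))
    expect_true(all(labs_nuc %in% labs_cell))
    # non-overlap is implied by single-valued label images; check labels dense
    expect_true(all(diff(labs_cell) >= 1))
  }
  expect_equal(nrow(msk$cells), 60)
})

test_that("feature-mode and mask-mode generation agree on subtype means", {
  st <- subtype_template()[c(5, 9), ]
  st$cell_area_mean <- c(2400, 800)
  cond <- condition_spec("mix", "control", c(0.5, 0.5))
  n <- 1100  # ~550 cells per subtype
  feats <- generate_population(st, cond, n_cells = n, seed = 12)
  msk <- generate_population(st, cond, n_cells = n, seed = 13,
                             output = "masks", field = field_geometry(size = 1400))
  meas <- extract_features(msk)
  for (s in st$subtype_id) {
    fsub <- feats[feats$subtype_id == s, ]
    msub <- meas[meas$subtype_id == s, ]
    expect_gt(nrow(msub), 400)
    for (col in c("cell_area", "cell_aspect_ratio", "cell_solidity",
                  "nucleus_cell_area_ratio", "cell_perimeter",
                  "nucleus_area", "cell_major_axis_length")) {
      rel <- abs(mean(msub[[col]]) - mean(fsub[[col]])) / mean(fsub[[col]])
      expect_lt(rel, 0.1, label = paste("subtype", s, col))
    }
  }
})

test_that("over-dense mask requests fail with a placement error", {
  st <- subtype_template()[1, ]
  cond <- condition_spec("one", "control", 1)
  expect_error(
    generate_population(st, cond, n_cells = 5, seed = 1, output = "masks",
                        field = field_geometry(size = 128)),
    "capacity|larger than field")
})

test_that("clone series plants the promised CG1 trajectory", {
  panel <- clone_panel_template()
  cells <- generate_condition_series(panel, n_cells = 1500, seed = 44)
  truth <- attr(cells, "truth")
  expect_equal(truth$cg1_control, panel$cg1_bias)
  expect_equal(truth$cg1_low, panel$cg1_bias - panel$shift_a)
  expect_equal(truth$cg1_high, panel$cg1_bias - panel$shift_a - panel$shift_b)
  # realized CG1 fractions approach the planted ones
  real <- cells |>
    dplyr::group_by(population, condition) |>
    dplyr::summarise(cg1 = mean(cg_true == 1L), .groups = "drop")
  for (i in seq_len(nrow(panel))) {
    for (d in c("control", "urban_low", "urban_high")) {
      planted <- switch(d, control = truth$cg1_control[i],
                        urban_low = truth$cg1_low[i],
                        urban_high = truth$cg1_high[i])
      got <- real$cg1[real$population == panel$clone_id[i] & real$condition == d]
      expect_lt(abs(got - planted), 0.045)
    }
  }

  # null shift: all three doses share one mixture
  null_panel <- panel[1, ]
  null_panel$shift_a <- 0; null_panel$shift_b <- 0
  null_cells <- generate_condition_series(null_panel, n_cells = 300, seed = 9)
  tt <- attr(null_cells, "truth")
  expect_equal(tt$cg1_control, tt$cg1_low)
  expect_equal(tt$cg1_low, tt$cg1_high)

  bad <- panel[1, ]; bad$shift_a <- 0.5; bad$shift_b <- 0.2
  expect_error(generate_condition_series(bad, n_cells = 10, seed = 1),
               "exceeds baseline CG1")
})

test_that("worked shift-profile arithmetic gives the planted CG1 fractions", {
  p <- tibble::tibble(clone_id = "x", cg1_bias = 0.6, cg2_bias = 0.25,
                      cg3_bias = 0.15, shift_a = 0.3, shift_b = 0.2)
  cells <- generate_condition_series(p, n_cells = 50, seed = 1)
  truth <- attr(cells, "truth")
  expect_equal(c(truth$cg1_control, truth$cg1_low, truth$cg1_high),
               c(0.6, 0.3, 0.1))
  expect_equal(truth$s_sc_true, (0.3 - 0.2) / (0.3 + 0.2))
})
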