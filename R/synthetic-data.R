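#' Default morphological subtype template
#'
#' Ten synthetic morphological subtypes organised into three cluster-groups
#' (CGs) along the axes real airway-cell morphology clusters vary on: cell
#' size, elongation, boundary irregularity (solidity), relative nuclear size,
#' and nuclear gamma-H2AX signal. CG1 holds large, regular "healthy"
#' morphologies (subtypes 1, 2, 5), CG2 intermediate and elongated shapes
#' (3, 4, 6; subtype 4 is large, strongly elongated, lowest damage), and CG3
#' small, round, high-damage shapes (7-10; subtypes 9 and 10 carry the
#' highest gamma-H2AX signal).
#'
#' @return A tibble with one row per subtype: `subtype_id`, `cg_id`,
#'   `cell_area_mean` (px^2), `cell_area_cv`, `aspect_ratio_mean`,
#'   `aspect_ratio_cv`, `solidity_mean`, `nucleus_area_fraction`,
#'   `nucleus_roundness` (0-1; how much of the cell's elongation the nucleus
#'   inherits, 1 = same aspect ratio, near 0 = round nucleus), `jitter_frac`
#'   (nuclear centroid offset as a fraction of the cell's minor semi-axis),
#'   `gh2ax_mean`, `gh2ax_sd`.
#' @export
#' @examples
#' subtype_template()
subtype_template <- function() {
  tibble::tibble(
    subtype_id = 1:10,
    cg_id = c(1L, 1L, 2L, 2L, 1L, 2L, 3L, 3L, 3L, 3L),
    cell_area_mean = c(5600, 5000, 1990, 2230, 4460, 1780, 1060, 1110, 944, 843),
    cell_area_cv = rep(0.045, 10),
    aspect_ratio_mean = c(1.45, 1.65, 2.0, 2.2, 1.15, 1.85, 1.5, 1.6, 1.22, 1.05),
    aspect_ratio_cv = rep(0.025, 10),
    solidity_mean = c(0.869, 0.941, 0.898, 0.970, 0.840, 0.854, 0.956, 0.912, 0.927, 0.883),
    nucleus_area_fraction = c(0.26, 0.17, 0.37, 0.20, 0.33, 0.23, 0.30, 0.44, 0.40, 0.47),
    nucleus_roundness = c(0.55, 0.40, 0.70, 0.55, 0.45, 0.62, 0.25, 0.32, 0.15, 0.20),
    jitter_frac = c(0.152, 0.280, 0.101, 0.229, 0.076, 0.203, 0.050, 0.178, 0.254, 0.127),
    gh2ax_mean = c(0.15, 0.20, 0.30, 0.08, 0.18, 0.25, 0.50, 0.45, 0.75, 0.82),
    gh2ax_sd = rep(0.06, 10)
  )
}

validate_subtypes <- function(subtypes) {
  stopifnot(is.data.frame(subtypes), nrow(subtypes) >= 1)
  req <- c("subtype_id", "cg_id", "cell_area_mean", "cell_area_cv",
           "aspect_ratio_mean", "aspect_ratio_cv", "solidity_mean",
           "nucleus_area_fraction", "gh2ax_mean", "gh2ax_sd")
  missing <- setdiff(req, names(subtypes))
  if (length(missing)) {
    stop("subtype table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(subtypes$cell_area_mean <= 0)) stop("cell_area_mean must be positive")
  if (any(subtypes$aspect_ratio_mean < 1)) stop("aspect_ratio_mean must be >= 1")
  if (any(subtypes$solidity_mean <= 0 | subtypes$solidity_mean > 1)) {
    stop("solidity_mean must lie in (0, 1]")
  }
  if (any(subtypes$nucleus_area_fraction <= 0 | subtypes$nucleus_area_fraction >= 1)) {
    stop("nucleus_area_fraction must lie in (0, 1)")
  }
  if (any(subtypes$gh2ax_mean < 0 | subtypes$gh2ax_mean > 1)) {
    stop("gh2ax_mean must lie in [0, 1]")
  }
  invisible(subtypes)
}

validate_fractions <- function(fractions, n_subtypes, tol = 1e-9) {
  if (length(fractions) != n_subtypes) {
    stop("subtype_fractions must have one entry per subtype")
  }
  if (any(fractions < 0)) stop("subtype_fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > tol) {
    stop("subtype_fractions must sum to 1 (got ", format(sum(fractions)), ")")
  }
  invisible(fractions)
}

#' Construct an exposure-condition specification
#'
#' @param condition_id Condition label.
#' @param dose_level One of `"control"`, `"low"`, `"high"`.
#' @param subtype_fractions Nonnegative vector over the subtypes, summing to 1.
#' @return A list with class `condition_spec`.
#' @export
condition_spec <- function(condition_id, dose_level = c("control", "low", "high"),
                           subtype_fractions) {
  dose_level <- match.arg(dose_level)
  if (any(subtype_fractions < 0)) stop("subtype_fractions must be nonnegative")
  if (abs(sum(subtype_fractions) - 1) > 1e-9) {
    stop("subtype_fractions must sum to 1 (got ", format(sum(subtype_fractions)), ")")
  }
  structure(list(condition_id = as.character(condition_id),
                 dose_level = dose_level,
                 subtype_fractions = as.numeric(subtype_fractions)),
            class = "condition_spec")
}

# Move `amount` of mass out of the `from` subtypes (proportionally) into the
# `to` subtypes (equal split).
shift_fractions <- function(base, from, to, amount) {
  avail <- sum(base[from])
  if (amount > avail + 1e-12) stop("shift exceeds available mass in source subtypes")
  out <- base
  out[from] <- base[from] * (1 - amount / avail)
  out[to] <- out[to] + amount / length(to)
  out
}

#' Default exposure-condition panel
#'
#' Seven conditions emulating an unexposed control plus low/high doses of
#' three particulate-matter mixtures. "Urban" and "fine" doses move cells
#' from the large CG1 subtypes toward the small round subtypes 9 and 10,
#' most strongly at high dose; "diesel" moves cells toward the elongated
#' subtypes 4 and 8.
#'
#' @param subtypes Subtype table, by default [subtype_template()].
#' @return A named list of [condition_spec()] objects.
#' @export
condition_template <- function(subtypes = subtype_template()) {
  validate_subtypes(subtypes)
  base <- rep(0.1, 10)
  cg1 <- which(subtypes$cg_id == 1L)
  specs <- list(
    control     = condition_spec("control", "control", base),
    urban_low   = condition_spec("urban_low", "low",
                                 shift_fractions(base, cg1, c(9, 10), 0.10)),
    urban_high  = condition_spec("urban_high", "high",
                                 shift_fractions(base, cg1, c(9, 10), 0.30)),
    fine_low    = condition_spec("fine_low", "low",
                                 shift_fractions(base, cg1, c(9, 10), 0.08)),
    fine_high   = condition_spec("fine_high", "high",
                                 shift_fractions(base, cg1, c(9, 10), 0.22)),
    diesel_low  = condition_spec("diesel_low", "low",
                                 shift_fractions(base, cg1, c(4, 8), 0.08)),
    diesel_high = condition_spec("diesel_high", "high",
                                 shift_fractions(base, cg1, c(4, 8), 0.20))
  )
  specs
}

#' Default clonal-population panel
#'
#' Four populations (a parental line and three single-cell clones) with
#' CG-biased baseline compositions and planted dose-response shift profiles.
#' `shift_a` and `shift_b` are the CG1-fraction drops at control-to-low and
#' low-to-high dose; the planted susceptibility score is
#' `(shift_a - shift_b) / (shift_a + shift_b)`, so the panel's planted
#' susceptibility ordering is clone8 > clone1 > parental > clone7.
#'
#' @return A tibble with columns `clone_id`, `cg1_bias`, `cg2_bias`,
#'   `cg3_bias`, `shift_a`, `shift_b`, and the planted score `s_sc_true`.
#' @export
clone_panel_template <- function() {
  panel <- tibble::tibble(
    clone_id = c("parental", "clone1", "clone7", "clone8"),
    cg1_bias = c(0.45, 0.55, 0.70, 0.50),
    cg2_bias = c(0.30, 0.35, 0.20, 0.35),
    cg3_bias = c(0.25, 0.10, 0.10, 0.15),
    shift_a  = c(0.15, 0.20, 0.05, 0.35),
    shift_b  = c(0.20, 0.20, 0.45, 0.10)
  )
  panel$s_sc_true <- (panel$shift_a - panel$shift_b) / (panel$shift_a + panel$shift_b)
  panel
}

validate_clone_panel <- function(panel) {
  req <- c("clone_id", "cg1_bias", "cg2_bias", "cg3_bias", "shift_a", "shift_b")
  missing <- setdiff(req, names(panel))
  if (length(missing)) stop("clone panel lacks columns: ", paste(missing, collapse = ", "))
  bias <- panel$cg1_bias + panel$cg2_bias + panel$cg3_bias
  if (any(abs(bias - 1) > 1e-9)) stop("CG biases must sum to 1 for every clone")
  if (any(panel$shift_a < 0 | panel$shift_b < 0)) stop("shift profile entries must be nonnegative")
  if (any(panel$shift_a + panel$shift_b > panel$cg1_bias + 1e-12)) {
    stop("shift profile exceeds baseline CG1 fraction for at least one clone")
  }
  invisible(panel)
}

# ---- latent draws -----------------------------------------------------------

# Per-cell latent shape parameters for a vector of subtype assignments.
# The nucleus is a coaxial ellipse: area a fraction of the cell's, aspect
# ratio interpolated between round and the cell's by `nucleus_roundness`,
# centroid offset `jitter_frac` of the cell's minor semi-axis (capped so the
# nucleus always stays strictly inside the cell outline).
draw_cell_latents <- function(subtypes, subtype_idx, orientation_sd = 0.15) {
  n <- length(subtype_idx)
  if (!"nucleus_roundness" %in% names(subtypes)) subtypes$nucleus_roundness <- 0.5
  if (!"jitter_frac" %in% names(subtypes)) subtypes$jitter_frac <- 0.1
  st <- subtypes[subtype_idx, ]
  sdlog_area <- sqrt(log(1 + st$cell_area_cv^2))
  area <- stats::rlnorm(n, log(st$cell_area_mean) - sdlog_area^2 / 2, sdlog_area)
  # aspect ratio as 1 + lognormal excess: keeps ar > 1 strictly, so the
  # eccentricity never collapses to zero (whose log would be an outlier)
  g_mean <- pmax(st$aspect_ratio_mean - 1, 1e-3)
  g_cv <- pmin(2, st$aspect_ratio_cv * st$aspect_ratio_mean / g_mean)
  sdlog_g <- sqrt(log(1 + g_cv^2))
  ar <- 1 + stats::rlnorm(n, log(g_mean) - sdlog_g^2 / 2, sdlog_g)
  sol <- pmin(0.995, pmax(0.6, stats::rnorm(n, st$solidity_mean, 0.008)))

  # harmonic amplitude from target solidity, calibrated once per subtype
  delta <- numeric(n)
  for (sid in unique(subtype_idx)) {
    sel <- subtype_idx == sid
    delta[sel] <- delta_for_solidity(sol[sel], subtypes$aspect_ratio_mean[sid])
  }

  nucleus_ar <- 1 + (ar - 1) * st$nucleus_roundness
  naf <- pmax(0.05, pmin(0.6, stats::rnorm(n, st$nucleus_area_fraction, 0.012)))
  # containment bound for a coaxial ellipse inside the perturbed outline
  naf <- pmin(naf, (0.92 * (1 - delta))^2 * nucleus_ar / ar)

  a_semi <- sqrt(area * ar / pi)
  b_semi <- sqrt(area / (pi * ar))
  a_nuc <- sqrt(naf * area * nucleus_ar / pi)
  b_nuc <- sqrt(naf * area / (pi * nucleus_ar))
  jmax <- 0.8 * pmax(0, pmin((1 - delta) * a_semi - a_nuc,
                             (1 - delta) * b_semi - b_nuc))
  jitter_r <- pmin(jmax, st$jitter_frac * b_semi * stats::runif(n, 0.93, 1.07))
  jitter_phi <- stats::runif(n, 0, 2 * pi)

  gh2ax <- pmin(1, pmax(0, stats::rnorm(n, st$gh2ax_mean, st$gh2ax_sd)))

  tibble::tibble(
    subtype_id = subtypes$subtype_id[subtype_idx],
    cg_true = subtypes$cg_id[subtype_idx],
    area = area, aspect_ratio = ar, solidity_target = sol, delta = delta,
    theta = (pi / 4 + stats::rnorm(n, 0, orientation_sd)) %% pi,
    phase = stats::runif(n, 0, 2 * pi),
    nucleus_fraction = naf, nucleus_ar = nucleus_ar,
    a_nuc = a_nuc, b_nuc = b_nuc,
    jitter_r = jitter_r, jitter_phi = jitter_phi,
    gh2ax = gh2ax
  )
}

# Closed-form 14 shape parameters of an exact ellipse with semi-axes a >= b
# rotated by theta (Ramanujan's second perimeter approximation).
ellipse_features <- function(a, b, theta) {
  area <- pi * a * b
  h <- ((a - b) / (a + b))^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  w <- 2 * sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2)
  hgt <- 2 * sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2)
  tibble::tibble(
    area = area,
    perimeter = perim,
    form_factor = 4 * pi * area / perim^2,
    eccentricity = sqrt(pmax(0, 1 - (b / a)^2)),
    solidity = 1,
    extent = pmin(1, area / (w * hgt)),
    major_axis_length = 2 * a,
    minor_axis_length = 2 * b,
    aspect_ratio = a / b,
    equivalent_diameter = 2 * sqrt(area / pi),
    max_feret = 2 * a,
    min_feret = 2 * b,
    compactness = perim^2 / (4 * pi * area)
  ) |> dplyr::mutate(convex_area = area)
}

# 33-parameter feature rows from latent shape parameters (no rasterization;
# the cell outline is evaluated as a polygon, the nucleus in closed form).
latents_to_features <- function(lat, n_vertices = 96L) {
  cell_mat <- t(vapply(seq_len(nrow(lat)), function(i) {
    poly <- ellipse_harmonic_polygon(lat$area[i], lat$aspect_ratio[i],
                                     delta = lat$delta[i], phase = lat$phase[i],
                                     theta = lat$theta[i], n_vertices = n_vertices)
    shape_features_polygon(poly)
  }, numeric(14)))
  cell <- tibble::as_tibble(cell_mat)
  names(cell) <- paste0("cell_", names(cell))

  nuc <- ellipse_features(lat$a_nuc, lat$b_nuc, lat$theta)
  names(nuc) <- paste0("nucleus_", names(nuc))

  cross <- tibble::tibble(
    nucleus_cell_area_ratio = nuc$nucleus_area / cell$cell_area,
    nucleus_cell_perimeter_ratio = nuc$nucleus_perimeter / cell$cell_perimeter,
    centroid_displacement = lat$jitter_r,
    normalized_centroid_displacement = lat$jitter_r / cell$cell_equivalent_diameter,
    cytoplasm_area = cell$cell_area - nuc$nucleus_area
  )
  dplyr::bind_cols(cell, nuc, cross)
}

#' Generate a synthetic single-cell population
#'
#' Draws cells from a mixture of morphological subtypes and returns either a
#' per-cell feature table (each cell evaluated as a continuous
#' ellipse-with-harmonic outline) or rendered label-mask images with
#' ground truth. The same seed and arguments always reproduce the same
#' output.
#'
#' @param subtypes Subtype table ([subtype_template()] by default).
#' @param condition A [condition_spec()]; its `subtype_fractions` set the
#'   mixture weights.
#' @param n_cells Number of cells to draw.
#' @param seed Integer seed.
#' @param output `"features"` for a per-cell feature tibble, `"masks"` for
#'   rendered label masks (a `morph_masks` object).
#' @param population_id Population label attached to every cell.
#' @param field Field geometry for mask output; see [field_geometry()].
#' @return For `output = "features"`, a tibble with metadata columns
#'   (`cell_id`, `population`, `condition`, `dose_level`, `subtype_id`,
#'   `cg_true`), the 33 morphology parameters (see [morph_feature_names()])
#'   and `gh2ax`. For `output = "masks"`, a `morph_masks` list with per-field
#'   `cell`, `nucleus` and `damage` images plus a `cells` ground-truth tibble.
#' @export
#' @examples
#' cond <- condition_template()$control
#' cells <- generate_population(n_cells = 50, condition = cond, seed = 1)
#' dplyr::count(cells, subtype_id)
generate_population <- function(subtypes = subtype_template(),
                                condition = condition_template(subtypes)$control,
                                n_cells = 1000,
                                seed = 1L,
                                output = c("features", "masks"),
                                population_id = "population_1",
                                field = field_geometry()) {
  output <- match.arg(output)
  validate_subtypes(subtypes)
  stopifnot(n_cells >= 1)
  fr <- validate_fractions(condition$subtype_fractions, nrow(subtypes))

  withr::with_seed(seed, {
    subtype_idx <- sample.int(nrow(subtypes), n_cells, replace = TRUE, prob = fr)
    lat <- draw_cell_latents(subtypes, subtype_idx)
    cond_id <- condition$condition_id
    dose <- condition$dose_level
    meta <- tibble::tibble(
      cell_id = seq_len(n_cells),
      population = population_id,
      condition = cond_id,
      dose_level = dose
    )
    if (output == "features") {
      feats <- latents_to_features(lat)
      dplyr::bind_cols(meta,
                       lat[, c("subtype_id", "cg_true")],
                       feats,
                       tibble::tibble(gh2ax = lat$gh2ax))
    } else {
      render_masks(lat, meta, field)
    }
  })
}

#' Generate the default multi-condition synthetic fixture
#'
#' Draws cells from every condition in [condition_template()] (equal numbers
#' per condition) using the default subtype template, mirroring a profiling
#' experiment in which cells from all exposure conditions are pooled before
#' embedding and clustering.
#'
#' @param n_cells Total number of cells (split evenly across conditions).
#' @param seed Integer seed.
#' @param subtypes Subtype table.
#' @return A feature tibble with `condition`/`dose_level` metadata, planted
#'   `subtype_id`/`cg_true` labels and `gh2ax` per cell.
#' @export
generate_fixture <- function(n_cells = 10000, seed = 1L,
                             subtypes = subtype_template()) {
  conds <- condition_template(subtypes)
  n_per <- max(1L, round(n_cells / length(conds)))
  cells <- purrr::imap_dfr(conds, function(cond, nm) {
    generate_population(subtypes, cond, n_cells = n_per,
                        seed = seed + match(nm, names(conds)) * 1009L,
                        population_id = "parental")
  })
  cells$cell_id <- seq_len(nrow(cells))
  cells
}

#' Generate a clone-panel dose series with planted CG1 trajectories
#'
#' For every clone in `panel` and each of the three doses (control, low,
#' high), builds a subtype mixture whose CG1 mass follows the planted
#' trajectory `(c, c - a, c - a - b)` — mass lost from CG1 is moved into the
#' CG3 subtypes — and draws a feature table. The attached `truth` attribute
#' records the planted CG1 fractions and the implied susceptibility score
#' `(a - b)/(a + b)`.
#'
#' @param panel Clone panel tibble ([clone_panel_template()] by default).
#' @param subtypes Subtype table.
#' @param n_cells Cells per clone per dose.
#' @param seed Integer seed.
#' @return A feature tibble for all clones and doses (conditions `control`,
#'   `urban_low`, `urban_high`), with attribute `truth`.
#' @export
generate_condition_series <- function(panel = clone_panel_template(),
                                      subtypes = subtype_template(),
                                      n_cells = 2000,
                                      seed = 1L) {
  validate_subtypes(subtypes)
  validate_clone_panel(panel)
  base <- rep(0.1, 10)
  if (nrow(subtypes) != 10L) {
    base <- rep(1 / nrow(subtypes), nrow(subtypes))
  }
  doses <- tibble::tibble(
    condition = c("control", "urban_low", "urban_high"),
    dose_level = c("control", "low", "high")
  )

  out <- vector("list", nrow(panel) * 3L)
  truth <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    cl <- panel[i, ]
    cg1_path <- c(cl$cg1_bias, cl$cg1_bias - cl$shift_a,
                  cl$cg1_bias - cl$shift_a - cl$shift_b)
    for (d in 1:3) {
      fr <- clone_dose_fractions(subtypes, base,
                                 cg_bias = c(cl$cg1_bias, cl$cg2_bias, cl$cg3_bias),
                                 cg1_target = cg1_path[d])
      cond <- condition_spec(doses$condition[d], doses$dose_level[d], fr)
      out[[(i - 1L) * 3L + d]] <- generate_population(
        subtypes, cond, n_cells,
        seed = seed + (i - 1L) * 101L + d,
        population_id = cl$clone_id
      )
    }
    truth[[i]] <- tibble::tibble(
      population = cl$clone_id,
      cg1_control = cg1_path[1], cg1_low = cg1_path[2], cg1_high = cg1_path[3],
      s_sc_true = (cl$shift_a - cl$shift_b) / (cl$shift_a + cl$shift_b)
    )
  }
  cells <- dplyr::bind_rows(out)
  attr(cells, "truth") <- dplyr::bind_rows(truth)
  cells
}

# Subtype fractions for one clone at one dose: within-CG weights follow the
# template mixture, CG masses follow the clone bias, and any CG1 mass below
# baseline is reassigned to the CG3 subtypes.
clone_dose_fractions <- function(subtypes, base, cg_bias, cg1_target) {
  if (cg1_target < -1e-12) stop("shift profile drives the CG1 fraction below zero")
  fr <- numeric(nrow(subtypes))
  for (g in 1:3) {
    sel <- subtypes$cg_id == g
    w <- base[sel] / sum(base[sel])
    fr[sel] <- w * cg_bias[g]
  }
  lost <- cg_bias[1] - cg1_target
  if (lost > 1e-15) {
    cg1 <- which(subtypes$cg_id == 1L)
    cg3 <- which(subtypes$cg_id == 3L)
    fr[cg1] <- fr[cg1] * (cg1_target / cg_bias[1])
    fr[cg3] <- fr[cg3] + lost * (fr[cg3] / sum(fr[cg3]))
  }
  fr / sum(fr)
}
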