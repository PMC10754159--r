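#' Field geometry for synthetic mask rendering
#'
#' @param size Square field side length in pixels.
#' @param max_packing Maximum total bounding-circle area per field, as a
#'   fraction of the field area; cells beyond it spill into further fields.
#' @param margin Margin in pixels kept free along the field border.
#' @return A list of settings used by [generate_population()] with
#'   `output = "masks"`.
#' @export
field_geometry <- function(size = 2048L, max_packing = 0.35, margin = 4L) {
  stopifnot(size >= 64L, max_packing > 0, max_packing <= 0.5, margin >= 0L)
  list(size = as.integer(size), max_packing = max_packing, margin = as.integer(margin))
}

# Render latent cells into per-field 16-bit label masks plus a damage
# (gamma-H2AX) intensity image. Cells are placed by rejection sampling on
# bounding circles, so masks never overlap and each nucleus is strictly
# inside its cell.
render_masks <- function(lat, meta, field = field_geometry()) {
  n <- nrow(lat)
  a_semi <- sqrt(lat$area * lat$aspect_ratio / pi)
  r_bound <- a_semi * (1 + lat$delta) + 1

  field_area <- as.numeric(field$size)^2
  circle_area <- pi * r_bound^2
  if (max(circle_area) > field$max_packing * field_area) {
    stop("requested density exceeds field capacity: a single cell's bounding ",
         "circle exceeds the per-field packing budget")
  }

  # greedy assignment of cells to fields under the packing budget
  field_id <- integer(n)
  acc <- 0; fid <- 1L
  for (i in seq_len(n)) {
    if (acc + circle_area[i] > field$max_packing * field_area) {
      fid <- fid + 1L; acc <- 0
    }
    field_id[i] <- fid
    acc <- acc + circle_area[i]
  }

  fields <- vector("list", max(field_id))
  cells <- vector("list", max(field_id))
  for (f in seq_len(max(field_id))) {
    idx <- which(field_id == f)
    placed <- place_cells(r_bound[idx], field$size, field$margin)
    imgs <- rasterize_field(lat[idx, ], placed, field$size)
    fields[[f]] <- imgs
    cells[[f]] <- dplyr::bind_cols(
      meta[idx, ],
      tibble::tibble(field = f, label = seq_along(idx),
                     center_x = placed[, 1], center_y = placed[, 2]),
      dplyr::rename(lat[idx, c("subtype_id", "cg_true", "gh2ax")],
                    gh2ax_true = "gh2ax")
    )
  }

  structure(list(fields = fields, cells = dplyr::bind_rows(cells),
                 field_size = field$size),
            class = "morph_masks")
}

#' @export
print.morph_masks <- function(x, ...) {
  cat("<morph_masks> ", length(x$fields), " field(s) of ",
      x$field_size, "x", x$field_size, " px, ",
      nrow(x$cells), " cells\n", sep = "")
  invisible(x)
}

# Rejection-sampled non-overlapping centers for bounding circles.
place_cells <- function(r, size, margin, max_tries = 500L) {
  n <- length(r)
  centers <- matrix(NA_real_, n, 2)
  ord <- order(r, decreasing = TRUE)  # place big cells first
  for (i in ord) {
    lo <- r[i] + margin; hi <- size - r[i] - margin
    if (hi <= lo) stop("cell larger than field: increase field size")
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- stats::runif(2, lo, hi)
      prev <- !is.na(centers[, 1])
      if (!any(prev)) { ok <- TRUE }
      else {
        d2 <- (centers[prev, 1] - cand[1])^2 + (centers[prev, 2] - cand[2])^2
        ok <- all(d2 > (r[prev] + r[i] + 2)^2)
      }
      if (ok) { centers[i, ] <- cand; break }
    }
    if (!ok) stop("cell placement failed: requested density exceeds field capacity")
  }
  centers
}

# Paint cell/nucleus/damage images for one field. Pixel centers are tested
# against the continuous outlines, so the nucleus pixel set is a subset of
# the cell pixel set by construction.
rasterize_field <- function(lat, centers, size) {
  cell_img <- matrix(0L, size, size)     # [row, col] = (y, x)
  nuc_img <- matrix(0L, size, size)
  dam_img <- matrix(0L, size, size)
  for (i in seq_len(nrow(lat))) {
    a <- sqrt(lat$area[i] * lat$aspect_ratio[i] / pi)
    b <- sqrt(lat$area[i] / (pi * lat$aspect_ratio[i]))
    delta <- lat$delta[i]; phase <- lat$phase[i]; theta <- lat$theta[i]
    cx <- centers[i, 1]; cy <- centers[i, 2]
    rb <- ceiling(a * (1 + delta)) + 1L
    xs <- max(1L, floor(cx - rb)):min(size, ceiling(cx + rb))
    ys <- max(1L, floor(cy - rb)):min(size, ceiling(cy + rb))
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    # rotate into the cell frame
    dx <- px - cx; dy <- py - cy
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    q <- sqrt((u / a)^2 + (v / b)^2)
    tt <- atan2(v / b, u / a)
    inside_cell <- q <= 1 + delta * cos(5 * tt + phase)
    # nucleus: coaxial ellipse with jittered centre (cell frame)
    ju <- lat$jitter_r[i] * cos(lat$jitter_phi[i])
    jv <- lat$jitter_r[i] * sin(lat$jitter_phi[i])
    inside_nuc <- ((u - ju) / lat$a_nuc[i])^2 + ((v - jv) / lat$b_nuc[i])^2 <= 1
    inside_nuc <- inside_nuc & inside_cell
    ic <- cbind(py[inside_cell], px[inside_cell])
    inn <- cbind(py[inside_nuc], px[inside_nuc])
    cell_img[ic] <- i
    nuc_img[inn] <- i
    dam_img[inn] <- as.integer(round(lat$gh2ax[i] * 65535))
  }
  list(cell = cell_img, nucleus = nuc_img, damage = dam_img)
}
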